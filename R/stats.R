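# Group-level inference for SWA composition studies: event-count-weighted
# two-sample t-tests, clustered negative-binomial count ratios, and
# repeated-measures ROI power contrasts. No multiple-testing adjustment is
# applied; each comparison is reported at face value.

new_group_comparison <- function(estimate, ci_lo, ci_hi, p_value, n_a, n_b,
                                 method, extra = list()) {
  structure(c(list(estimate = estimate, ci_lo = ci_lo, ci_hi = ci_hi,
                   p_value = p_value, n_a = n_a, n_b = n_b, method = method),
              extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n  estimate %.4g [95%% CI %.4g, %.4g], p = %.4g (n = %d vs %d)\n",
              x$method, x$estimate, x$ci_lo, x$ci_hi, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

# Weighted mean and variance with frequency-weight semantics: weights are
# rescaled to sum to the group size n, so multiplying all weights by a
# constant changes nothing.
wstats <- function(x, w) {
  n <- length(x)
  w <- w / sum(w) * n
  m <- sum(w * x) / n
  v <- if (n > 1L) sum(w * (x - m)^2) / (n - 1L) else NA_real_
  list(n = n, mean = m, var = v)
}

#' Event-count-weighted two-sample t-test
#'
#' Welch-style two-sided t-test where each participant's value is weighted by
#' the number of detected events (frequency-weight semantics: weights are
#' rescaled within each group to sum to the group size). With equal weights
#' this reduces exactly to the unweighted Welch t-test. Degenerate
#' zero-variance inputs return the exact estimate with p reported as 0 (or 1
#' when the estimate is also 0) and a warning, rather than an error.
#'
#' @param values_a,values_b Per-participant values.
#' @param weights_a,weights_b Positive weights (event counts).
#' @param conf_level Confidence level of the interval.
#' @return A `group_comparison` (estimate = mean(a) - mean(b)).
#' @export
weighted_ttest <- function(values_a, weights_a, values_b, weights_b,
                           conf_level = 0.95) {
  stopifnot(length(values_a) == length(weights_a),
            length(values_b) == length(weights_b))
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 observations")
  if (any(weights_a <= 0) || any(weights_b <= 0))
    stop("weights must be positive")
  a <- wstats(values_a, weights_a)
  b <- wstats(values_b, weights_b)
  est <- a$mean - b$mean
  se2 <- a$var / a$n + b$var / b$n
  method <- "weighted two-sample two-sided t-test (Welch df, frequency weights)"
  if (se2 <= 0 || !is.finite(se2)) {
    warning("zero variance in weighted t-test; p degenerate")
    p <- if (est == 0) 1 else 0
    return(new_group_comparison(est, est, est, p, a$n, b$n, method))
  }
  se <- sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  tstat <- est / se
  p <- 2 * pt(-abs(tstat), df)
  q <- qt(1 - (1 - conf_level) / 2, df)
  new_group_comparison(est, est - q * se, est + q * se, p, a$n, b$n, method,
                       extra = list(t = tstat, df = df))
}

#' Clustered negative-binomial count-ratio comparison
#'
#' Marginal log-link count regression of event counts on condition with
#' cluster-robust inference: the negative-binomial dispersion is estimated by
#' method of moments and held fixed, the mean model is fit by maximum
#' likelihood under working independence, and the standard error of the
#' condition coefficient comes from a cluster-robust (sandwich) covariance
#' with `t(G - 1)` reference. The exponentiated coefficient is the b:a
#' count ratio; swapping the condition labels inverts it. The percent
#' difference quoted alongside is `100 * (ratio - 1)`.
#'
#' @param counts Non-negative integer event counts.
#' @param condition Two-level factor (or coercible); the ratio is
#'   second-level / first-level.
#' @param cluster_id Cluster identifier (e.g. subject).
#' @param conf_level Confidence level.
#' @return A `group_comparison` on the ratio scale, with `percent_diff` and
#'   `dispersion` attached.
#' @export
clustered_nb_count_ratio <- function(counts, condition, cluster_id,
                                     conf_level = 0.95) {
  stopifnot(length(counts) == length(condition),
            length(counts) == length(cluster_id))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all counts are zero")
  condition <- factor(condition)
  if (nlevels(condition) != 2L) stop("condition must have exactly two levels")
  dat <- data.frame(y = counts, g = condition, cl = as.character(cluster_id))

  pois <- glm(y ~ g, family = poisson(), data = dat)
  mu <- fitted(pois)
  # Cameron-Trivedi method-of-moments overdispersion: Var = mu + alpha mu^2
  alpha <- sum((dat$y - mu)^2 - mu) / sum(mu^2)
  fam <- if (is.finite(alpha) && alpha > 1e-8)
    MASS::negative.binomial(theta = 1 / alpha)
  else poisson()
  fit <- glm(y ~ g, family = fam, data = dat)
  beta <- coef(fit)[2L]
  V <- sandwich::vcovCL(fit, cluster = dat$cl)
  # near-exact fits can yield a tiny negative variance; treat as degenerate
  se <- sqrt(max(V[2L, 2L], 0))
  G <- length(unique(dat$cl))
  df <- max(G - 1L, 1L)
  method <- sprintf(
    "negative-binomial count regression (MoM dispersion %.4g held fixed), working independence, cluster-robust SE, t(%d)",
    if (is.finite(alpha)) max(alpha, 0) else 0, df)
  n_a <- sum(condition == levels(condition)[1L])
  n_b <- sum(condition == levels(condition)[2L])
  if (!is.finite(se) || se <= 0) {
    warning("degenerate variance in clustered count model; p degenerate")
    p <- if (abs(beta) < 1e-12) 1 else 0
    r <- exp(unname(beta))
    return(new_group_comparison(r, r, r, p, n_a, n_b, method,
                                extra = list(percent_diff = 100 * (r - 1),
                                             dispersion = alpha)))
  }
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  q <- qt(1 - (1 - conf_level) / 2, df)
  new_group_comparison(exp(unname(beta)),
                       exp(unname(beta - q * se)), exp(unname(beta + q * se)),
                       unname(p), n_a, n_b, method,
                       extra = list(percent_diff = 100 * (exp(unname(beta)) - 1),
                                    dispersion = alpha))
}

#' Repeated-measures ROI power contrast
#'
#' Within-subject comparison of normalized ROI power between two conditions
#' (e.g. channels), with subject as the repeated factor. With one pair of
#' observations per subject this is the paired t contrast of a
#' subject-blocked repeated-measures regression. Reported alongside the raw
#' difference is the percent-difference parameterization
#' `100 * mean(a - b) / mean((a + b) / 2)`.
#'
#' @param power_a,power_b ROI power per subject, aligned by position.
#' @param subject_id Subject identifiers (must be unique; pairs `power_a` and
#'   `power_b`).
#' @param conf_level Confidence level.
#' @return A `group_comparison` (estimate = mean within-subject a - b
#'   difference), with `percent_diff` attached.
#' @export
repeated_measures_roi <- function(power_a, power_b, subject_id,
                                  conf_level = 0.95) {
  if (length(power_a) != length(power_b) ||
      length(power_a) != length(subject_id))
    stop("power_a, power_b and subject_id must be aligned")
  if (anyDuplicated(subject_id)) stop("subjects must pair a and b uniquely")
  n <- length(power_a)
  if (n < 2L) stop("need at least 2 subjects")
  d <- power_a - power_b
  est <- mean(d)
  pct <- 100 * est / mean((power_a + power_b) / 2)
  sdd <- sd(d)
  method <- "repeated-measures (subject-blocked) paired t contrast"
  if (sdd == 0) {
    warning("zero within-subject variance; p degenerate")
    p <- if (est == 0) 1 else 0
    return(new_group_comparison(est, est, est, p, n, n, method,
                                extra = list(percent_diff = pct)))
  }
  se <- sdd / sqrt(n)
  tstat <- est / se
  p <- 2 * pt(-abs(tstat), n - 1L)
  q <- qt(1 - (1 - conf_level) / 2, n - 1L)
  new_group_comparison(est, est - q * se, est + q * se, p, n, n, method,
                       extra = list(percent_diff = pct, t = tstat, df = n - 1L))
}
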