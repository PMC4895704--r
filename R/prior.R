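# Empirical-Bayes estimation of the two-component mixture prior on
# log-odds-ratio effect sizes:  mu ~ pi0 * delta_0 + (1 - pi0) * N(0, sigma0^2).

#' Two-component mixture prior on effect sizes
#'
#' A point mass at zero with weight `pi0` (null SNPs) plus a centred
#' Gaussian with variance `sigma0_sq` for associated SNPs.  `sigma0_sq`
#' may be `Inf`: the flat-prior sentinel under which shrinkage disappears
#' (shrinkage factor 1).
#'
#' @param pi0 Proportion of null SNPs, in \[0, 1\].
#' @param sigma0_sq Variance of non-null effect sizes, >= 0 or `Inf`.
#' @param m Optional number of SNPs the prior was fitted from.
#' @return An object of class `mixture_prior`.
#' @seealso [fit_prior()]
#' @export
mixture_prior <- function(pi0, sigma0_sq, m = NA_integer_) {
  if (!is.numeric(pi0) || length(pi0) != 1L || is.na(pi0) ||
      pi0 < 0 || pi0 > 1) {
    stop("pi0 must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(sigma0_sq) || length(sigma0_sq) != 1L || is.na(sigma0_sq) ||
      sigma0_sq < 0) {
    stop("sigma0_sq must be a single number >= 0 (Inf allowed)", call. = FALSE)
  }
  structure(list(pi0 = pi0, sigma0_sq = sigma0_sq, m = m),
            class = "mixture_prior")
}

#' @export
print.mixture_prior <- function(x, ...) {
  cat("Two-component mixture prior on log odds ratios\n")
  cat(sprintf("  pi0       = %.4f   (null proportion)\n", x$pi0))
  cat(sprintf("  sigma0_sq = %s   (non-null effect variance)\n",
              format(x$sigma0_sq, digits = 4)))
  if (!is.na(x$m)) cat(sprintf("  fitted from m = %d SNPs\n", x$m))
  invisible(x)
}

#' Two-sided p-values from Wald statistics
#'
#' `p = 2 * (1 - Phi(|z|))`, in (0, 1].
#'
#' @param z Numeric vector of Wald statistics.
#' @return Numeric vector of two-sided p-values.
#' @export
two_sided_pvalues <- function(z) {
  if (any(!is.finite(z))) stop("z values must be finite", call. = FALSE)
  2 * pnorm(abs(z), lower.tail = FALSE)
}

#' Estimate the null proportion at a fixed threshold
#'
#' Storey-type estimator: `pi0_hat = #\{p_i > gamma\} / (m (1 - gamma))`,
#' clamped into \[1/m, 1\] (a zero estimate would make the non-null
#' variance estimator undefined downstream).
#'
#' @param pvalues Vector of two-sided p-values.
#' @param gamma Tuning threshold in (0, 1).
#' @return Estimated null proportion.
#' @export
estimate_pi0_fixed_gamma <- function(pvalues, gamma) {
  if (length(pvalues) == 0L) stop("empty p-value vector", call. = FALSE)
  stop_if_not_prob(gamma, "gamma")
  m <- length(pvalues)
  est <- sum(pvalues > gamma) / (m * (1 - gamma))
  clamp_pi0(est, m)
}

clamp_pi0 <- function(est, m, quiet = FALSE) {
  if (est < 1 / m) {
    if (!quiet) {
      warning(sprintf("pi0 estimate %.3g clamped to floor 1/m = %.3g",
                      est, 1 / m), call. = FALSE)
    }
    est <- 1 / m
  }
  min(est, 1)
}

#' Automatic spline-based estimate of the null proportion
#'
#' Evaluates the fixed-threshold estimator over the grid
#' `gamma = 0, 0.05, ..., 0.90`, fits a natural cubic smoothing spline
#' (3 equivalent degrees of freedom) of the estimates against `gamma`, and
#' returns the spline extrapolated to `gamma = 1`, clamped into
#' \[1/m, 1\].  This is the standard automatic procedure trading off the
#' bias (small `gamma`) against the variance (large `gamma`) of the
#' fixed-threshold estimator.
#'
#' With fewer than `min_m` p-values the spline is unstable; the function
#' falls back to the fixed estimator at `gamma = 0.5` with a warning.
#'
#' @inheritParams estimate_pi0_fixed_gamma
#' @param gamma_grid Thresholds at which the fixed estimator is evaluated.
#' @param df Equivalent degrees of freedom of the smoothing spline.
#' @param min_m Minimal number of p-values for a spline fit.
#' @return Estimated null proportion.
#' @export
estimate_pi0_spline <- function(pvalues, gamma_grid = seq(0, 0.90, by = 0.05),
                                df = 3, min_m = 100L) {
  m <- length(pvalues)
  if (m == 0L) stop("empty p-value vector", call. = FALSE)
  if (m < min_m) {
    warning(sprintf(
      "only %d p-values (< %d); falling back to fixed gamma = 0.5", m, min_m),
      call. = FALSE)
    return(estimate_pi0_fixed_gamma(pvalues, 0.5))
  }
  raw <- vapply(gamma_grid,
                function(g) sum(pvalues > g) / (m * (1 - g)),
                numeric(1))
  fit <- smooth.spline(gamma_grid, raw, df = df)
  est <- predict(fit, x = 1)$y
  clamp_pi0(est, m)
}

#' Moment estimator of the non-null effect-size variance
#'
#' Under the mixture prior the marginal Wald statistic of SNP i is
#' `pi0 N(0,1) + (1-pi0) N(0, 1 + sigma0^2 / se_i^2)`, so
#' `E(sum z_i^2) = m pi0 + (1-pi0)(m + sigma0^2 sum(1/se_i^2))`.
#' Inverting gives
#' `sigma0_sq_hat = max(0, ((sum z^2 - m pi0)/(1 - pi0) - m) / sum(1/se^2))`.
#'
#' Two degenerate regimes are handled explicitly: when the empirical mean
#' of `z^2` is at most 1 (no excess dispersion over the global null) the
#' estimate is 0; when `pi0 = 1` yet the mean of `z^2` exceeds 1 the
#' estimate is `Inf`, the flat-prior sentinel under which shrinkage
#' disappears.
#'
#' @param z Wald statistics of all m SNPs.
#' @param se Their primary-study standard errors.
#' @param pi0 Null proportion, in \[0, 1\].
#' @return Estimated variance (possibly 0 or `Inf`).
#' @export
estimate_sigma0_sq <- function(z, se, pi0) {
  m <- length(z)
  if (m == 0L || length(se) != m) {
    stop("z and se must be nonempty vectors of equal length", call. = FALSE)
  }
  if (pi0 < 0 || pi0 > 1) stop("pi0 must be in [0, 1]", call. = FALSE)
  if (mean(z^2) <= 1) return(0)
  if (pi0 >= 1) return(Inf)
  max(0, ((sum(z^2) - m * pi0) / (1 - pi0) - m) / sum(1 / se^2))
}

#' Fit the mixture prior from genome-wide summary statistics
#'
#' Estimates `pi0` from the two-sided p-values (spline procedure by
#' default, or a fixed threshold via `gamma`), then plugs it into the
#' moment estimator of `sigma0_sq`.
#'
#' @param summaries Summary data frame (columns `mu_hat`, `se`, and
#'   optionally `z`, `snp_id`) for all genotyped SNPs, e.g. from
#'   [wald_summary()].
#' @param gamma If non-`NULL`, use the fixed-threshold `pi0` estimator at
#'   this value instead of the spline procedure.
#' @param pi0 If non-`NULL`, bypass `pi0` estimation entirely and use this
#'   value (an external override).
#' @param quiet Suppress clamping warnings (used inside bootstrap loops).
#' @return A [mixture_prior()] object.
#' @examples
#' set.seed(1)
#' z <- c(rnorm(900), rnorm(100, sd = sqrt(5)))
#' s <- data.frame(mu_hat = z * 0.1, se = 0.1)
#' fit_prior(s)
#' @export
fit_prior <- function(summaries, gamma = NULL, pi0 = NULL, quiet = FALSE) {
  s <- as_assoc_summary(summaries)
  m <- nrow(s)
  if (m < 2L) {
    stop("at least 2 SNPs are required to fit the prior", call. = FALSE)
  }
  if (is.null(pi0)) {
    p <- two_sided_pvalues(s$z)
    fitter <- function() {
      if (is.null(gamma)) estimate_pi0_spline(p)
      else estimate_pi0_fixed_gamma(p, gamma)
    }
    pi0 <- if (quiet) suppressWarnings(fitter()) else fitter()
  }
  sigma0_sq <- estimate_sigma0_sq(s$z, s$se, pi0)
  mixture_prior(pi0, sigma0_sq, m = m)
}
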