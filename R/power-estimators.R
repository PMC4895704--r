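# Per-SNP estimators of replication-study power: naive plug-in, CMLE
# plug-in, EB effect-size plug-in and the closed-form Bayesian predictive
# power, plus the conjugate-normal posterior machinery behind them.

#' Shrinkage factor of the conjugate-normal posterior
#'
#' `lambda = 1 / (1 + se1^2 / sigma0_sq)`, the fraction of the observed
#' effect retained in the posterior mean under the Gaussian prior
#' component.  Equals 0 at `sigma0_sq = 0` and 1 at the `Inf` sentinel.
#'
#' @param se1 Primary-study standard error (> 0).
#' @param sigma0_sq Prior variance of non-null effects (>= 0 or `Inf`).
#' @return Shrinkage factor in \[0, 1\].
#' @export
shrinkage_lambda <- function(se1, sigma0_sq) {
  if (any(se1 <= 0)) stop("se1 must be > 0", call. = FALSE)
  if (any(sigma0_sq < 0)) stop("sigma0_sq must be >= 0", call. = FALSE)
  ratio <- se1^2 / sigma0_sq       # Inf at sigma0_sq = 0, 0 at Inf sentinel
  ifelse(is.infinite(sigma0_sq), 1, 1 / (1 + ratio))
}

#' Posterior distribution of the effect size under the non-null component
#'
#' Conjugate-normal update: given `mu_hat ~ N(mu, se^2)` and
#' `mu ~ N(0, sigma0_sq)` under the alternative, the posterior is
#' `N(lambda * mu_hat, lambda * se^2)` with `lambda` the shrinkage factor.
#'
#' @param summaries Summary data frame (columns `mu_hat`, `se`).
#' @param prior A [mixture_prior()].
#' @return A `data.frame` with columns `mean`, `variance`, `lambda`,
#'   one row per input SNP.
#' @export
posterior_effect <- function(summaries, prior) {
  s <- as_assoc_summary(summaries)
  lam <- shrinkage_lambda(s$se, prior$sigma0_sq)
  data.frame(mean = lam * s$mu_hat, variance = lam * s$se^2, lambda = lam)
}

#' Empirical Bayes shrinkage estimator of the effect size
#'
#' The posterior mean `lambda * mu_hat`.
#'
#' @inheritParams posterior_effect
#' @return Numeric vector of shrunken log odds ratios.
#' @export
eb_effect <- function(summaries, prior) {
  posterior_effect(summaries, prior)$mean
}

#' Bayesian predictive power of the replication study
#'
#' The posterior-averaged replication power (assurance) of an association
#' identified in the primary study, in closed form:
#' `Phi( (sgn(z) z* - z_{alpha2}) / sigma* )` with
#' `z* = lambda mu_hat / sigma2` and
#' `sigma* = sqrt(1 + lambda (se / sigma2)^2)`.
#' It equals the average of the replication power function over the
#' posterior of the effect size given the primary statistic, and so is
#' immune to the winner's curse in a mean-squared-error (Bayes-risk)
#' sense.  With `sigma0_sq = 0` (shrinkage factor 0) it degenerates to
#' `alpha2`; with the `Inf` sentinel the shrinkage disappears entirely.
#'
#' @inheritParams posterior_effect
#' @param sigma2 Replication-study standard error(s), e.g. from
#'   [replication_se()].
#' @param alpha2 One-sided replication significance level.
#' @return Numeric vector of predictive power values in (0, 1).
#' @examples
#' s <- data.frame(mu_hat = 0.3, se = 0.07)
#' eb_predictive_power(s, mixture_prior(0.9, 0.04), sigma2 = 0.1, alpha2 = 5e-3)
#' @export
eb_predictive_power <- function(summaries, prior, sigma2, alpha2) {
  stop_if_not_prob(alpha2, "alpha2", upper = 0.5)
  s <- as_assoc_summary(summaries)
  if (any(s$z == 0)) {
    stop("predictive power undefined for z = 0 (sign of the effect unknown)",
         call. = FALSE)
  }
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0", call. = FALSE)
  lam <- shrinkage_lambda(s$se, prior$sigma0_sq)
  zstar <- lam * s$mu_hat / sigma2
  sstar <- sqrt(1 + lam * (s$se / sigma2)^2)
  pnorm((sign(s$z) * zstar - z_upper(alpha2)) / sstar)
}

#' Conditional maximum likelihood estimate of the effect size
#'
#' Corrects the winner's curse by maximizing the likelihood of the
#' primary statistic conditioned on having passed the two-sided
#' significance threshold: the conditional density of `z` given
#' `|Z| > z_{alpha1/2}` is
#' `phi(z - mu/se) / (Phi(-c + mu/se) + Phi(-c - mu/se))` with
#' `c = z_{alpha1/2}`.  Maximization is by bounded scalar optimization on
#' the standardized effect, restarted over sub-intervals of
#' `[-2|z|, 2|z|]` to guard against flat stretches near zero; ties
#' resolve toward the sign of `z`.
#'
#' @inheritParams posterior_effect
#' @param alpha1 Two-sided primary significance level; every row must be
#'   significant at this level.
#' @return Numeric vector of bias-corrected log odds ratios.
#' @export
cmle_effect <- function(summaries, alpha1) {
  stop_if_not_prob(alpha1, "alpha1", upper = 0.5)
  s <- as_assoc_summary(summaries)
  crit <- z_upper(alpha1 / 2)
  if (any(abs(s$z) <= crit)) {
    stop("cmle_effect requires summaries significant at alpha1", call. = FALSE)
  }
  vapply(seq_len(nrow(s)), function(i) {
    sgn <- sign(s$z[i])
    za <- abs(s$z[i])
    # negative conditional log-likelihood in the standardized effect theta
    nll <- function(theta) {
      0.5 * (za - theta)^2 +
        log(pnorm(theta - crit) + pnorm(-theta - crit))
    }
    ivs <- list(c(-2 * za, 0), c(0, za), c(za, 2 * za))
    cand_t <- c(0, za / 2, za)
    cand_v <- vapply(cand_t, nll, numeric(1))
    for (iv in ivs) {
      opt <- optimize(nll, interval = iv, tol = 1e-10)
      cand_t <- c(cand_t, opt$minimum)
      cand_v <- c(cand_v, opt$objective)
    }
    # tie-break toward the sign of z: among near-optimal candidates take
    # the one with the largest standardized effect
    best <- which(cand_v <= min(cand_v) + 1e-12)
    theta <- max(cand_t[best])
    sgn * theta * s$se[i]
  }, numeric(1))
}

#' Plug-in power estimate from an effect-size estimate
#'
#' Thin wrapper over [replication_power()] used with the observed effect
#' (naive), the CMLE-corrected effect, or the EB-shrunken effect.
#'
#' @param mu_estimate Effect-size estimate(s) to plug in.
#' @inheritParams replication_power
#' @return Numeric vector of power estimates.
#' @export
plugin_power <- function(mu_estimate, sign1, sigma2, alpha2) {
  replication_power(mu_estimate, sign1, sigma2, alpha2)
}
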