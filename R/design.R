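# Local true discovery rate, ltdr-weighted average power, and replication
# sample-size determination.

#' Local true discovery rate
#'
#' Posterior probability that a SNP is truly associated given its primary
#' Wald statistic, under the two-component marginal
#' `z ~ pi0 N(0,1) + pi1 N(0, s^2)` with `s^2 = 1 + sigma0_sq / se^2`:
#' `ltdr = pi1 f1(z) / (pi0 phi(z) + pi1 f1(z))`.
#'
#' By default `f1` is the properly normalized non-null density
#' `phi(z/s)/s` (Bayes-consistent with the marginal model).  Some
#' published formulations drop the `1/s` normalization; set
#' `normalized = FALSE` to reproduce that convention.  With the
#' `sigma0_sq = Inf` sentinel the non-null component is flat and the
#' shrinkage-free limit `f1 = phi(0)` of the unnormalized form is used in
#' both modes, so identified SNPs keep positive weight.
#'
#' @inheritParams posterior_effect
#' @param normalized Use the normalized non-null component density
#'   (default) or the unnormalized compatibility form.
#' @return Numeric vector of probabilities, increasing in `|z|`.
#' @examples
#' s <- data.frame(mu_hat = 0.3, se = 0.1)
#' ltdr(s, mixture_prior(0.9, 0.04))
#' @export
ltdr <- function(summaries, prior, normalized = TRUE) {
  s <- as_assoc_summary(summaries)
  pi0 <- prior$pi0
  if (pi0 >= 1) return(rep(0, nrow(s)))
  if (pi0 <= 0) return(rep(1, nrow(s)))
  if (is.infinite(prior$sigma0_sq)) {
    f1 <- rep(dnorm(0), nrow(s))
  } else {
    ssq <- 1 + prior$sigma0_sq / s$se^2
    f1 <- dnorm(s$z / sqrt(ssq))
    if (normalized) f1 <- f1 / sqrt(ssq)
  }
  num <- (1 - pi0) * f1
  num / (pi0 * dnorm(s$z) + num)
}

#' ltdr-weighted average predictive power of the identified SNPs
#'
#' `sum(ltdr_i * eta_i) / sum(ltdr_i)` over the identified set, where
#' `eta_i` is the Bayesian predictive power of SNP i.  Weighting by the
#' local true discovery rate discounts identified SNPs that are likely
#' false positives, so the set may safely include them.
#'
#' @param summaries Summary rows of the identified SNPs (all significant
#'   in the primary study).
#' @inheritParams eb_predictive_power
#' @param normalized Passed to [ltdr()].
#' @return The estimated average power, between the minimal and maximal
#'   per-SNP predictive power.
#' @export
average_power_eb <- function(summaries, prior, sigma2, alpha2,
                             normalized = TRUE) {
  s <- as_assoc_summary(summaries)
  if (nrow(s) == 0L) stop("empty identified set", call. = FALSE)
  w <- ltdr(s, prior, normalized = normalized)
  if (sum(w) == 0) {
    stop("all ltdr weights are zero; cannot average", call. = FALSE)
  }
  eta <- eb_predictive_power(s, prior, sigma2, alpha2)
  sum(w * eta) / sum(w)
}

#' True average replication power (simulation oracle)
#'
#' Unweighted mean of the replication power function over SNPs whose true
#' effect sizes are known -- only meaningful in simulation, where it is the
#' target every estimator is judged against.
#'
#' @param mu_true True log odds ratios of the identified truly associated
#'   SNPs.
#' @param sign1 Signs of their primary statistics.
#' @param sigma2 Replication standard errors.
#' @inheritParams replication_power
#' @return Mean power over the set.
#' @export
true_average_power <- function(mu_true, sign1, sigma2, alpha2) {
  if (length(mu_true) == 0L) stop("empty identified-true set", call. = FALSE)
  mean(replication_power(mu_true, sign1, sigma2, alpha2))
}

#' Determine the replication sample size for a target average power
#'
#' Finds the smallest number of replication cases (controls = `ratio` x
#' cases, rounded up) at which the ltdr-weighted average Bayesian
#' predictive power of the identified SNPs reaches `target_power`.  The
#' per-SNP replication standard error is recomputed from the primary
#' allele counts at every candidate size, and the search is integer
#' bisection exploiting monotonicity of power in the sample size.
#'
#' @param counts Primary-study allele counts ([allele_counts()] rows) of
#'   the identified SNPs.
#' @param prior A [mixture_prior()] fitted from the genome-wide summaries.
#' @param target_power Required average power, in (0, 1); conventionally
#'   0.80.
#' @param ratio Control-to-case ratio of the replication study.
#' @param alpha2 One-sided replication significance level.
#' @param n_max Largest case count considered; the search errors (and
#'   reports the power reached at `n_max`) if the target is unattainable.
#' @param curve_points Number of sizes at which the returned power curve
#'   is evaluated.
#' @param normalized Passed to [ltdr()].
#' @return An object of class `design_result`: a list with `n_cases`,
#'   `n_controls`, `n_total`, `target_power`, `achieved_power` and a
#'   `curve` data frame (`n_cases`, `n_controls`, `n_total`,
#'   `average_power`).
#' @export
required_sample_size <- function(counts, prior, target_power = 0.80,
                                 ratio = 1, alpha2 = 5e-6, n_max = 1e6,
                                 curve_points = 25L, normalized = TRUE) {
  stop_if_not_prob(target_power, "target_power")
  if (ratio <= 0) stop("ratio must be > 0", call. = FALSE)
  s <- wald_summary(counts)
  w <- ltdr(s, prior, normalized = normalized)
  if (sum(w) == 0) stop("all ltdr weights are zero", call. = FALSE)

  avg_at <- function(n_cases) {
    sig2 <- replication_se(counts, n0_rep = ceiling(ratio * n_cases),
                           n1_rep = n_cases)
    eta <- eb_predictive_power(s, prior, sig2, alpha2)
    sum(w * eta) / sum(w)
  }

  if (avg_at(n_max) < target_power) {
    stop(sprintf(
      "target power %.3f unreachable below n_max = %d cases (power there: %.4f)",
      target_power, as.integer(n_max), avg_at(n_max)), call. = FALSE)
  }
  lo <- 1L; hi <- as.integer(n_max)
  if (avg_at(1) >= target_power) {
    hi <- 1L
  } else {
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (avg_at(mid) >= target_power) hi <- mid else lo <- mid
    }
  }
  n_cases <- hi
  n_controls <- as.integer(ceiling(ratio * n_cases))

  sizes <- unique(pmax(1L, as.integer(round(
    exp(seq(log(max(1, n_cases / 10)), log(max(2 * n_cases, 10)),
            length.out = curve_points))))))
  curve <- data.frame(
    n_cases = sizes,
    n_controls = as.integer(ceiling(ratio * sizes)),
    average_power = vapply(sizes, avg_at, numeric(1)))
  curve$n_total <- curve$n_cases + curve$n_controls

  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_total = n_cases + n_controls,
                 target_power = target_power,
                 achieved_power = avg_at(n_cases),
                 ratio = ratio, alpha2 = alpha2, curve = curve),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Replication study design (ltdr-weighted average predictive power)\n")
  cat(sprintf("  target average power : %.2f\n", x$target_power))
  cat(sprintf("  cases / controls     : %d / %d  (ratio %.2f)\n",
              x$n_cases, x$n_controls, x$ratio))
  cat(sprintf("  total sample size    : %d\n", x$n_total))
  cat(sprintf("  achieved power       : %.4f at alpha2 = %.2g\n",
              x$achieved_power, x$alpha2))
  invisible(x)
}
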