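# Credible intervals for per-SNP and average replication power, by Monte
# Carlo sampling from the effect-size posterior, optionally combined with
# bootstrap re-estimation of the prior hyperparameters.

# n_mc x k matrix of posterior power draws for the k rows of `s`.
draw_power_matrix <- function(s, prior, sigma2, alpha2, n_mc) {
  k <- nrow(s)
  lam <- shrinkage_lambda(s$se, prior$sigma0_sq)
  mu <- matrix(rnorm(n_mc * k,
                     mean = rep(lam * s$mu_hat, each = n_mc),
                     sd = rep(sqrt(lam) * s$se, each = n_mc)),
               nrow = n_mc, ncol = k)
  zq <- z_upper(alpha2)
  pnorm(sweep(mu, 2, sign(s$z) / sigma2, `*`) - zq)
}

#' Monte Carlo draws from the posterior power distribution of one SNP
#'
#' Draws effect sizes from the conjugate posterior
#' `N(lambda mu_hat, lambda se^2)` and maps each through the replication
#' power function.  The sample mean converges to the closed-form Bayesian
#' predictive power; the sample distribution is typically skewed, which is
#' why interval estimation is sampling-based rather than normal-theory.
#'
#' @param summary A single summary row (columns `mu_hat`, `se`).
#' @inheritParams eb_predictive_power
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Optional integer seed (global RNG state is restored).
#' @return Numeric vector of `n_draws` power values.
#' @export
power_posterior_samples <- function(summary, prior, sigma2, alpha2,
                                    n_draws = 1000L, seed = NULL) {
  s <- as_assoc_summary(summary)
  if (nrow(s) != 1L) stop("expected a single summary row", call. = FALSE)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  with_seed(seed, as.vector(draw_power_matrix(s, prior, sigma2, alpha2,
                                              n_draws)))
}

# Fit a prior from a bootstrap resample, counting clamp events silently.
refit_prior_resample <- function(reference, idx) {
  suppressWarnings(fit_prior(reference[idx, , drop = FALSE], quiet = TRUE))
}

#' Credible intervals for per-SNP replication power
#'
#' Equal-tailed credible intervals of the replication power of each SNP in
#' `summaries`.  Without bootstrap, `n_mc` power values are drawn from the
#' effect-size posterior under the fitted prior and their sample quantiles
#' taken; this ignores hyperparameter uncertainty and under-covers.  With
#' bootstrap (default), the genome-wide `reference` summaries are
#' resampled with replacement `n_boot` times, the prior (`pi0` and
#' `sigma0_sq`) re-fitted per resample, `n_mc` power values drawn per
#' resample, and the quantiles taken over all `n_boot * n_mc` pooled
#' draws.  One bootstrap resample sequence is shared by all SNPs in the
#' call.  The point estimate is always the closed-form Bayesian predictive
#' power under the original prior.
#'
#' @param summaries Summary rows of the SNPs whose intervals are wanted
#'   (typically those significant in the primary study).
#' @inheritParams eb_predictive_power
#' @param reference Genome-wide summary data frame used to (re-)fit the
#'   prior; required when `bootstrap = TRUE`.  Defaults to `summaries`.
#' @param prior Prior for the point estimate and the no-bootstrap draws;
#'   fitted from `reference` when `NULL`.
#' @param level Nominal coverage of the equal-tailed interval.
#' @param n_boot Number of bootstrap resamples (N1).
#' @param n_mc Number of Monte Carlo draws per resample (N2).
#' @param bootstrap Combine Monte Carlo sampling with bootstrap
#'   re-estimation of the hyperparameters.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `snp_id`, `point`, `lower`,
#'   `upper`, `level`, `n_samples`.
#' @export
credible_interval_power <- function(summaries, prior = NULL, sigma2, alpha2,
                                    reference = summaries, level = 0.95,
                                    n_boot = 100L, n_mc = 100L,
                                    bootstrap = TRUE, seed = NULL) {
  if (level < 0 || level >= 1) {
    stop("level must be in [0, 1)", call. = FALSE)
  }
  s <- as_assoc_summary(summaries)
  if (is.null(prior)) prior <- fit_prior(as_assoc_summary(reference))
  point <- eb_predictive_power(s, prior, sigma2, alpha2)
  sigma2 <- rep_len(sigma2, nrow(s))

  draws <- with_seed(seed, {
    if (!bootstrap) {
      draw_power_matrix(s, prior, sigma2, alpha2, n_mc)
    } else {
      ref <- as_assoc_summary(reference)
      m <- nrow(ref)
      n_clamped <- 0L
      out <- vector("list", n_boot)
      for (b in seq_len(n_boot)) {
        pb <- refit_prior_resample(ref, sample.int(m, m, replace = TRUE))
        if (pb$pi0 <= 1 / pb$m) n_clamped <- n_clamped + 1L
        out[[b]] <- draw_power_matrix(s, pb, sigma2, alpha2, n_mc)
      }
      if (n_clamped > 0L) {
        message(n_clamped, " bootstrap resample(s) hit the pi0 clamp floor; ",
                "resamples retained")
      }
      do.call(rbind, out)
    }
  })

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q <- apply(draws, 2, quantile, probs = probs, names = FALSE, type = 7)
  data.frame(snp_id = s$snp_id, point = point,
             lower = q[1, ], upper = q[2, ], level = level,
             n_samples = nrow(draws), stringsAsFactors = FALSE)
}

#' Credible interval for the average replication power
#'
#' Combined Monte Carlo / bootstrap interval for the ltdr-weighted average
#' power of the identified SNPs.  Per bootstrap resample of the
#' genome-wide reference summaries the prior is re-fitted and the ltdr
#' weights recomputed; `n_mc` coherent sets of per-SNP power draws are
#' generated and each set is collapsed to its weighted average, giving
#' `n_boot * n_mc` pooled average-power values from which equal-tailed
#' quantiles are taken.  The point estimate is [average_power_eb()] under
#' the original prior.
#'
#' @param summaries Summary rows of the identified SNPs.
#' @inheritParams credible_interval_power
#' @param normalized Passed to [ltdr()].
#' @return A one-row `data.frame` with columns `point`, `lower`, `upper`,
#'   `level`, `n_samples`.
#' @export
credible_interval_average_power <- function(summaries, prior = NULL, sigma2,
                                            alpha2, reference = summaries,
                                            level = 0.95, n_boot = 100L,
                                            n_mc = 100L, seed = NULL,
                                            normalized = TRUE) {
  if (level < 0 || level >= 1) stop("level must be in [0, 1)", call. = FALSE)
  s <- as_assoc_summary(summaries)
  if (nrow(s) == 0L) stop("empty identified set", call. = FALSE)
  ref <- as_assoc_summary(reference)
  if (is.null(prior)) prior <- fit_prior(ref)
  sigma2 <- rep_len(sigma2, nrow(s))
  point <- average_power_eb(s, prior, sigma2, alpha2, normalized = normalized)

  avgs <- with_seed(seed, {
    m <- nrow(ref)
    out <- vector("list", n_boot)
    n_degenerate <- 0L
    for (b in seq_len(n_boot)) {
      pb <- refit_prior_resample(ref, sample.int(m, m, replace = TRUE))
      w <- ltdr(s, pb, normalized = normalized)
      if (sum(w) == 0) {   # resample with a fully-null refitted prior
        n_degenerate <- n_degenerate + 1L
        next
      }
      pw <- draw_power_matrix(s, pb, sigma2, alpha2, n_mc)
      out[[b]] <- as.vector(pw %*% w) / sum(w)
    }
    if (n_degenerate > 0L) {
      message(n_degenerate, " bootstrap resample(s) gave all-zero ltdr ",
              "weights (refitted pi0 = 1); skipped")
    }
    if (n_degenerate == n_boot) {
      stop("every bootstrap resample produced all-zero ltdr weights",
           call. = FALSE)
    }
    unlist(out)
  })

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q <- quantile(avgs, probs = probs, names = FALSE, type = 7)
  data.frame(point = point, lower = q[1], upper = q[2], level = level,
             n_samples = length(avgs))
}
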