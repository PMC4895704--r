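# Experiment harness: bias/RMSE comparison of the power estimators,
# credible-interval coverage, average-power estimation, and a direct look
# at the winner's curse in effect-size estimation.  All experiments work
# on data from simulate_two_stage() and know the simulation truth.

# One simulated run analysed: summaries, prior fit, identified sets and
# the design-phase replication SE / true power of identified true SNPs.
analyse_run <- function(config, quiet_prior = TRUE) {
  sim <- simulate_two_stage(config)
  summ <- wald_summary(sim$primary)
  prior <- fit_prior(summ, quiet = quiet_prior)
  ident <- is_primary_significant(summ$z, config$alpha1)
  true_nonnull <- sim$truth$mu != 0
  eval_idx <- which(ident & true_nonnull)
  out <- list(sim = sim, summaries = summ, prior = prior,
              identified = which(ident), eval_idx = eval_idx)
  if (length(eval_idx) > 0L) {
    counts_eval <- sim$primary[eval_idx, , drop = FALSE]
    out$sigma2 <- replication_se(counts_eval, config$n0_rep, config$n1_rep)
    out$sign1 <- sign(summ$z[eval_idx])
    out$true_power <- replication_power(sim$truth$mu[eval_idx], out$sign1,
                                        out$sigma2, config$alpha2)
  }
  out
}

# Power estimates of the four implemented estimators for the rows `idx`
# of a run, as an (n x 4) matrix.
estimate_power_matrix <- function(run, idx, config) {
  s <- run$summaries[idx, , drop = FALSE]
  counts <- run$sim$primary[idx, , drop = FALSE]
  sigma2 <- replication_se(counts, config$n0_rep, config$n1_rep)
  sgn <- sign(s$z)
  cbind(
    naive = plugin_power(s$mu_hat, sgn, sigma2, config$alpha2),
    cmle = plugin_power(cmle_effect(s, config$alpha1), sgn, sigma2,
                        config$alpha2),
    eb_plugin = plugin_power(eb_effect(s, run$prior), sgn, sigma2,
                             config$alpha2),
    eb_predictive = eb_predictive_power(s, run$prior, sigma2, config$alpha2))
}

#' Bias and RMSE of the power estimators on simulated two-stage data
#'
#' Repeats the full pipeline `n_runs` times: simulate, identify SNPs
#' significant in the primary study, fit the prior from all m summaries,
#' and compare each power estimator against the true replication power
#' (computed from the known effect size, with the design-phase replication
#' standard error projected from the primary counts) over the identified
#' truly associated SNPs.  Reports per-run and averaged mean error (bias)
#' and root-mean-square error per estimator.
#'
#' @param config A [simulation_config()].
#' @param n_runs Number of independent simulation runs.
#' @param seed Optional integer seed for the whole experiment.
#' @return A list of class `bias_rmse_experiment`: `per_run` (data frame
#'   with `run`, `estimator`, `bias`, `rmse`, `n_snps`), `summary`
#'   (averages across runs), `priors` (per-run fitted hyperparameters).
#' @export
run_bias_rmse_experiment <- function(config, n_runs = 5L, seed = NULL) {
  stopifnot(n_runs >= 1)
  with_seed(seed, {
    rows <- list(); priors <- list()
    for (r in seq_len(n_runs)) {
      run <- analyse_run(config)
      if (length(run$eval_idx) == 0L) {
        warning(sprintf("run %d: no identified true association; dropped", r),
                call. = FALSE)
        next
      }
      est <- estimate_power_matrix(run, run$eval_idx, config)
      err <- est - run$true_power
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, estimator = colnames(est),
        bias = colMeans(err), rmse = sqrt(colMeans(err^2)),
        n_snps = length(run$eval_idx), row.names = NULL,
        stringsAsFactors = FALSE)
      priors[[length(priors) + 1L]] <- data.frame(
        run = r, pi0 = run$prior$pi0, sigma0_sq = run$prior$sigma0_sq)
    }
    if (length(rows) == 0L) {
      stop("all runs dropped (no identified true associations)",
           call. = FALSE)
    }
    per_run <- do.call(rbind, rows)
    summary <- aggregate(cbind(bias, rmse) ~ estimator, data = per_run, mean)
    structure(list(per_run = per_run, summary = summary,
                   priors = do.call(rbind, priors), config = config),
              class = "bias_rmse_experiment")
  })
}

#' @export
print.bias_rmse_experiment <- function(x, ...) {
  cat(sprintf("Power-estimator bias/RMSE over %d run(s), %d-%d identified true SNPs per run\n",
              max(x$per_run$run), min(x$per_run$n_snps), max(x$per_run$n_snps)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Coverage of the per-SNP credible intervals on simulated data
#'
#' Per run, builds credible intervals for the power of every identified
#' truly associated SNP both by pure Monte Carlo sampling (prior held at
#' its point estimate) and by the combined Monte Carlo + bootstrap method,
#' and reports the fraction of SNPs whose true power falls inside the
#' interval.
#'
#' @inheritParams run_bias_rmse_experiment
#' @param level Nominal coverage.
#' @param n_boot,n_mc Bootstrap resamples (N1) and Monte Carlo draws per
#'   resample (N2).
#' @return A list of class `coverage_experiment`: `per_run` (data frame
#'   with `run`, `method`, `coverage`, `n_snps`) and `summary` (mean
#'   coverage per method).
#' @export
run_coverage_experiment <- function(config, level = 0.95, n_boot = 50L,
                                    n_mc = 100L, n_runs = 3L, seed = NULL) {
  stopifnot(n_runs >= 1)
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_runs)) {
      run <- analyse_run(config)
      if (length(run$eval_idx) == 0L) {
        warning(sprintf("run %d: no identified true association; dropped", r),
                call. = FALSE)
        next
      }
      s_eval <- run$summaries[run$eval_idx, , drop = FALSE]
      for (boot in c(FALSE, TRUE)) {
        ci <- suppressMessages(credible_interval_power(
          s_eval, prior = run$prior, sigma2 = run$sigma2,
          alpha2 = config$alpha2, reference = run$summaries, level = level,
          n_boot = n_boot, n_mc = n_mc, bootstrap = boot))
        rows[[length(rows) + 1L]] <- data.frame(
          run = r, method = if (boot) "bootstrap" else "monte_carlo",
          coverage = mean(ci$lower <= run$true_power &
                          run$true_power <= ci$upper),
          n_snps = length(run$eval_idx), stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) stop("all runs dropped", call. = FALSE)
    per_run <- do.call(rbind, rows)
    structure(list(per_run = per_run,
                   summary = aggregate(coverage ~ method, per_run, mean),
                   level = level, config = config),
              class = "coverage_experiment")
  })
}

#' @export
print.coverage_experiment <- function(x, ...) {
  cat(sprintf("Realized coverage of nominal %.0f%% credible intervals\n",
              100 * x$level))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Average-power estimation and its credible interval on simulated data
#'
#' Per run, computes the true average replication power over the
#' identified truly associated SNPs, the ltdr-weighted average of each
#' power estimator over all identified SNPs, and the combined Monte
#' Carlo + bootstrap credible interval of the average power.
#'
#' @inheritParams run_coverage_experiment
#' @return A data frame with one row per run: `true_avg`, the four
#'   weighted estimator averages, interval bounds and a `covered` flag.
#' @export
run_average_power_experiment <- function(config, level = 0.95, n_boot = 50L,
                                         n_mc = 100L, n_runs = 5L,
                                         seed = NULL) {
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_runs)) {
      run <- analyse_run(config)
      if (length(run$eval_idx) == 0L || length(run$identified) == 0L) {
        warning(sprintf("run %d dropped", r), call. = FALSE)
        next
      }
      true_avg <- mean(run$true_power)
      est <- estimate_power_matrix(run, run$identified, config)
      w <- ltdr(run$summaries[run$identified, , drop = FALSE], run$prior)
      wavg <- colSums(est * w) / sum(w)
      sigma2_ident <- replication_se(
        run$sim$primary[run$identified, , drop = FALSE],
        config$n0_rep, config$n1_rep)
      ci <- suppressMessages(credible_interval_average_power(
        run$summaries[run$identified, , drop = FALSE], prior = run$prior,
        sigma2 = sigma2_ident, alpha2 = config$alpha2,
        reference = run$summaries, level = level,
        n_boot = n_boot, n_mc = n_mc))
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, true_avg = true_avg,
        naive = wavg[["naive"]], cmle = wavg[["cmle"]],
        eb_plugin = wavg[["eb_plugin"]],
        eb_predictive = wavg[["eb_predictive"]],
        lower = ci$lower, upper = ci$upper,
        covered = ci$lower <= true_avg & true_avg <= ci$upper,
        n_identified = length(run$identified),
        n_identified_true = length(run$eval_idx),
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) stop("all runs dropped", call. = FALSE)
    do.call(rbind, rows)
  })
}

#' Winner's curse in effect-size estimation on simulated data
#'
#' Among identified truly associated SNPs, reports the mean estimation
#' error `mu_hat - mu` separately for SNPs with positive and negative true
#' effects.  Selection on significance exaggerates the magnitude of the
#' observed effect, so the positive-effect group mean is positive and the
#' negative-effect group mean negative.
#'
#' @inheritParams run_bias_rmse_experiment
#' @return A data frame with columns `effect_sign`, `n_snps`,
#'   `mean_error`; groups with no SNPs are absent.
#' @export
winners_curse_summary <- function(config, seed = NULL) {
  with_seed(seed, {
    run <- analyse_run(config)
    if (length(run$eval_idx) == 0L) {
      stop("no identified true associations in this run", call. = FALSE)
    }
    err <- run$summaries$mu_hat[run$eval_idx] - run$sim$truth$mu[run$eval_idx]
    sgn <- ifelse(run$sim$truth$mu[run$eval_idx] > 0, "positive", "negative")
    out <- aggregate(err, list(effect_sign = sgn),
                     function(e) c(n = length(e), mean = mean(e)))
    data.frame(effect_sign = out$effect_sign,
               n_snps = as.integer(out$x[, "n"]),
               mean_error = out$x[, "mean"], stringsAsFactors = FALSE)
  })
}
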