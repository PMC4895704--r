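# Association statistics for allele-based 2x2 case-control tables and the
# power function of a sign-consistent one-sided replication test.

#' Construct a table of allele-based case-control counts
#'
#' One row per SNP, with the allele-based 2x2 contingency table of a
#' case-control study: `n00` control non-effect alleles, `n01` control
#' effect alleles, `n10` case non-effect alleles, `n11` case effect
#' alleles.  Row margins are twice the number of control (`n00 + n01`)
#' and case (`n10 + n11`) individuals, so both must be even.
#'
#' @param n00,n01,n10,n11 Non-negative integer vectors of equal length.
#' @param snp_id Optional character vector of SNP identifiers; defaults to
#'   `snp1`, `snp2`, ...
#' @return A `data.frame` with columns `snp_id`, `n00`, `n01`, `n10`, `n11`.
#' @examples
#' allele_counts(100, 50, 50, 100, snp_id = "rs1")
#' @export
allele_counts <- function(n00, n01, n10, n11, snp_id = NULL) {
  n <- length(n00)
  if (!all(lengths(list(n01, n10, n11)) == n)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  cells <- cbind(n00, n01, n10, n11)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("allele counts must be non-negative integers", call. = FALSE)
  }
  if (any((n00 + n01) %% 2 != 0) || any((n10 + n11) %% 2 != 0)) {
    stop("margins n00+n01 and n10+n11 must be even (two alleles per individual)",
         call. = FALSE)
  }
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(n))
  data.frame(snp_id = as.character(snp_id),
             n00 = as.numeric(n00), n01 = as.numeric(n01),
             n10 = as.numeric(n10), n11 = as.numeric(n11),
             stringsAsFactors = FALSE)
}

# Extract the four cell columns, applying the Haldane-Anscombe +0.5
# continuity correction to every cell of rows containing a zero.
prep_cells <- function(counts, zero_cell_correction = TRUE) {
  cells <- as.matrix(counts[, c("n00", "n01", "n10", "n11")])
  zero_rows <- rowSums(cells == 0) > 0
  if (any(zero_rows)) {
    ids <- if ("snp_id" %in% names(counts)) {
      counts$snp_id[zero_rows]
    } else {
      which(zero_rows)
    }
    if (!zero_cell_correction) {
      stop("zero cell(s) in table(s): ", paste(ids, collapse = ", "),
           "; enable `zero_cell_correction` to apply the +0.5 correction",
           call. = FALSE)
    }
    warning("zero cell(s); +0.5 continuity correction applied to: ",
            paste(utils::head(ids, 5L), collapse = ", "),
            if (sum(zero_rows) > 5L) ", ..." else "", call. = FALSE)
    cells[zero_rows, ] <- cells[zero_rows, , drop = FALSE] + 0.5
  }
  cells
}

#' Log odds ratio of an allele-count table
#'
#' `log n00 - log n01 - log n10 + log n11`, the logarithm of the observed
#' allele-based odds ratio for the effect allele.  Antisymmetric under
#' swapping the effect/non-effect allele columns.
#'
#' @param counts A data frame as returned by [allele_counts()].
#' @param zero_cell_correction Apply the +0.5 continuity correction to all
#'   four cells of any row containing a zero (with a warning).  If `FALSE`,
#'   zero cells are an error.
#' @return Numeric vector of log odds ratios.
#' @export
log_odds_ratio <- function(counts, zero_cell_correction = TRUE) {
  x <- prep_cells(counts, zero_cell_correction)
  unname(log(x[, "n00"]) - log(x[, "n01"]) - log(x[, "n10"]) +
           log(x[, "n11"]))
}

#' Woolf standard error of the log odds ratio
#'
#' `sqrt(1/n00 + 1/n01 + 1/n10 + 1/n11)`.
#'
#' @inheritParams log_odds_ratio
#' @return Numeric vector of standard errors.
#' @export
woolf_se <- function(counts, zero_cell_correction = TRUE) {
  x <- prep_cells(counts, zero_cell_correction)
  unname(sqrt(1 / x[, "n00"] + 1 / x[, "n01"] + 1 / x[, "n10"] +
                1 / x[, "n11"]))
}

#' Wald association summary per SNP
#'
#' Bundles the log odds ratio, its Woolf standard error and the Wald
#' statistic `z = mu_hat / se` for each table row.  This summary
#' data frame (columns `snp_id`, `mu_hat`, `se`, `z`) is the unit record
#' consumed by every estimator in the package.
#'
#' @inheritParams log_odds_ratio
#' @return A `data.frame` with columns `snp_id`, `mu_hat`, `se`, `z`.
#' @examples
#' wald_summary(allele_counts(100, 50, 50, 100))
#' @export
wald_summary <- function(counts, zero_cell_correction = TRUE) {
  x <- prep_cells(counts, zero_cell_correction)
  mu_hat <- log(x[, "n00"]) - log(x[, "n01"]) - log(x[, "n10"]) + log(x[, "n11"])
  se <- sqrt(1 / x[, "n00"] + 1 / x[, "n01"] + 1 / x[, "n10"] + 1 / x[, "n11"])
  id <- if ("snp_id" %in% names(counts)) as.character(counts$snp_id) else
    paste0("snp", seq_len(nrow(x)))
  data.frame(snp_id = id, mu_hat = unname(mu_hat), se = unname(se),
             z = unname(mu_hat / se), stringsAsFactors = FALSE)
}

# Validate a summary data frame (mu_hat/se/z coherent, se > 0).
as_assoc_summary <- function(x) {
  need <- c("mu_hat", "se")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("expected a summary data frame with columns mu_hat, se", call. = FALSE)
  }
  if (any(x$se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  if (!"z" %in% names(x)) x$z <- x$mu_hat / x$se
  bad <- abs(x$z - x$mu_hat / x$se) >
    1e-12 * pmax(1, abs(x$z))
  if (any(bad)) stop("z inconsistent with mu_hat / se", call. = FALSE)
  if (!"snp_id" %in% names(x)) x$snp_id <- paste0("snp", seq_len(nrow(x)))
  x
}

#' Primary-study significance at level alpha1
#'
#' Two-sided Wald test: significant iff `|z| > z_{alpha1/2}` (strict).
#'
#' @param z Wald statistics.
#' @param alpha1 Two-sided significance level of the primary study,
#'   in (0, 0.5).
#' @return Logical vector.
#' @export
is_primary_significant <- function(z, alpha1) {
  stop_if_not_prob(alpha1, "alpha1", upper = 0.5)
  abs(z) > z_upper(alpha1 / 2)
}

#' Power of the sign-consistent replication test
#'
#' Probability that the replication Wald statistic exceeds `z_{alpha2}` in
#' the direction of the primary-study effect, for a true log odds ratio
#' `mu` and replication standard error `sigma2`:
#' `Phi(sign1 * mu / sigma2 - z_{alpha2})`.
#' At `mu = 0` this equals `alpha2`, the one-sided type-I error rate.
#'
#' @param mu True (or plugged-in) log odds ratio.
#' @param sign1 Sign (+1 or -1) of the primary-study statistic.
#' @param sigma2 Standard error of the log odds ratio in the replication
#'   study (> 0).
#' @param alpha2 One-sided significance level of the replication study.
#' @return Numeric vector of power values in (0, 1).
#' @examples
#' replication_power(0.15, +1, 0.05, 5e-3)
#' @export
replication_power <- function(mu, sign1, sigma2, alpha2) {
  stop_if_not_prob(alpha2, "alpha2", upper = 0.5)
  if (any(sign1 == 0)) {
    stop("sign1 must be +1 or -1 (replication is defined for identified, ",
         "nonzero-z associations)", call. = FALSE)
  }
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0", call. = FALSE)
  pnorm(sign(sign1) * mu / sigma2 - z_upper(alpha2))
}

#' Projected replication-study standard error from primary counts
#'
#' Approximates the replication-stage Woolf standard error by substituting
#' the primary study's observed allele frequencies, rescaled to the
#' replication group sizes:
#' `sqrt( (n0_1/n0_rep)(1/n00 + 1/n01) + (n1_1/n1_rep)(1/n10 + 1/n11) )`
#' where `n0_1`, `n1_1` are the primary control and case counts implied by
#' the table margins.
#'
#' @inheritParams log_odds_ratio
#' @param n0_rep,n1_rep Planned number of control and case individuals in
#'   the replication study (>= 1).
#' @return Numeric vector of projected standard errors.
#' @export
replication_se <- function(counts, n0_rep, n1_rep, zero_cell_correction = TRUE) {
  if (any(n0_rep < 1) || any(n1_rep < 1)) {
    stop("replication group sizes must be >= 1", call. = FALSE)
  }
  x <- prep_cells(counts, zero_cell_correction)
  n0_1 <- (x[, "n00"] + x[, "n01"]) / 2
  n1_1 <- (x[, "n10"] + x[, "n11"]) / 2
  unname(sqrt((n0_1 / n0_rep) * (1 / x[, "n00"] + 1 / x[, "n01"]) +
              (n1_1 / n1_rep) * (1 / x[, "n10"] + 1 / x[, "n11"])))
}
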