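# Synthetic two-stage case-control GWAS generator: mixture effect-size
# models, an allele-level disease model converting (MAF, log OR,
# prevalence) into case/control allele frequencies, and binomial sampling
# of allele-count tables for both stages.

#' Mixture model for SNP effect sizes
#'
#' An ordered list of components, each a point mass at zero
#' (`kind = "point"`), a centred Gaussian (`kind = "normal"`, with
#' `variance`), or a scaled t distribution (`kind = "t"`, with `df` and
#' `scale`).  Weights must be non-negative and sum to 1.
#'
#' @param components List of lists; each needs `kind`, `weight` and the
#'   kind-specific parameters described above.
#' @return An object of class `effect_size_model`.
#' @seealso [gaussian_effect_model()], [t_effect_model()],
#'   [gaussian_mixture_effect_model()]
#' @export
effect_size_model <- function(components) {
  w <- vapply(components, function(cp) cp$weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    stop("component weights must be non-negative and sum to 1", call. = FALSE)
  }
  for (cp in components) {
    switch(cp$kind,
      point = NULL,
      normal = if (is.null(cp$variance) || cp$variance < 0)
        stop("normal component needs a non-negative variance", call. = FALSE),
      t = if (is.null(cp$df) || cp$df <= 0 || is.null(cp$scale))
        stop("t component needs df > 0 and a scale", call. = FALSE),
      stop("unknown component kind: ", cp$kind, call. = FALSE))
  }
  structure(list(components = components), class = "effect_size_model")
}

#' Standard point-mass + Gaussian effect model
#'
#' `pi0 * delta_0 + (1 - pi0) * N(0, variance)`; the defaults are the
#' canonical sparse-polygenic scenario with 10 % associated SNPs of
#' log-odds-ratio variance 0.04 (sd 0.2).
#'
#' @param pi0 Weight of the point mass at zero.
#' @param variance Variance of the non-null Gaussian component.
#' @export
gaussian_effect_model <- function(pi0 = 0.9, variance = 0.04) {
  effect_size_model(list(
    list(kind = "point", weight = pi0),
    list(kind = "normal", weight = 1 - pi0, variance = variance)))
}

#' Point-mass + scaled-t effect model (heavy tails)
#'
#' `pi0 * delta_0 + (1 - pi0) * scale * t_df`.
#'
#' @inheritParams gaussian_effect_model
#' @param df Degrees of freedom of the t component.
#' @param scale Scale factor applied to the t draws.
#' @export
t_effect_model <- function(pi0 = 0.9, df = 5, scale = 0.2) {
  effect_size_model(list(
    list(kind = "point", weight = pi0),
    list(kind = "t", weight = 1 - pi0, df = df, scale = scale)))
}

#' Point-mass + two-Gaussian effect model
#'
#' `pi0 * delta_0 + w1 N(0, v1) + w2 N(0, v2)`; defaults give a
#' Gaussian-mixture alternative with a minority of larger effects.
#'
#' @inheritParams gaussian_effect_model
#' @param weights Weights of the two Gaussian components.
#' @param variances Their variances.
#' @export
gaussian_mixture_effect_model <- function(pi0 = 0.9,
                                          weights = c(0.07, 0.03),
                                          variances = c(0.04, 0.16)) {
  effect_size_model(c(
    list(list(kind = "point", weight = pi0)),
    mapply(function(w, v) list(kind = "normal", weight = w, variance = v),
           weights, variances, SIMPLIFY = FALSE)))
}

#' Draw i.i.d. effect sizes from a mixture model
#'
#' @param model An [effect_size_model()].
#' @param m Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of log odds ratios; the point-mass component
#'   yields exact zeros.
#' @export
draw_effect_sizes <- function(model, m, seed = NULL) {
  stopifnot(inherits(model, "effect_size_model"), m >= 1)
  with_seed(seed, {
    w <- vapply(model$components, function(cp) cp$weight, numeric(1))
    comp <- sample.int(length(w), m, replace = TRUE, prob = w)
    mu <- numeric(m)
    for (j in seq_along(model$components)) {
      cp <- model$components[[j]]
      idx <- which(comp == j)
      if (length(idx) == 0L) next
      mu[idx] <- switch(cp$kind,
        point = 0,
        normal = rnorm(length(idx), 0, sqrt(cp$variance)),
        t = cp$scale * rt(length(idx), df = cp$df))
    }
    mu
  })
}

#' Case and control allele frequencies implied by (MAF, log OR, prevalence)
#'
#' Allele-level logistic disease model: each allele carries disease risk
#' `logit P(D | allele) = c + mu * 1[effect allele]`, with the intercept
#' `c` solved in closed form so that the allele-marginal prevalence equals
#' `prevalence`.  Under this model the allele-based odds ratio of the
#' expected 2x2 table is exactly `exp(mu)`, and
#' `prevalence * f_case + (1 - prevalence) * f_control` returns the
#' population frequency exactly (law of total probability).
#'
#' @param maf Population frequency of the effect allele, in (0, 1).
#' @param mu Log odds ratio of the effect allele.
#' @param prevalence Population disease probability, in (0, 1).
#' @return A `data.frame` with columns `f_case`, `f_control`.
#' @export
allele_frequencies_by_status <- function(maf, mu, prevalence) {
  if (any(maf <= 0) || any(maf >= 1)) {
    stop("maf must be in (0, 1)", call. = FALSE)
  }
  stop_if_not_prob(prevalence, "prevalence")
  a <- exp(mu)
  K <- prevalence
  # Solve for x = odds of disease on the non-effect allele:
  #   maf * a*x/(1+a*x) + (1-maf) * x/(1+x) = K
  # which is the positive root of  a(1-K) x^2 + B x - K = 0.
  B <- maf * a + 1 - maf - K - K * a
  x <- (-B + sqrt(B^2 + 4 * a * (1 - K) * K)) / (2 * a * (1 - K))
  p0 <- x / (1 + x)
  p1 <- a * x / (1 + a * x)
  f_case <- maf * p1 / K
  f_control <- maf * (1 - p1) / (1 - K)
  if (any(!is.finite(f_case)) || any(f_case >= 1) || any(f_control >= 1)) {
    stop("effect size too extreme for the configured prevalence",
         call. = FALSE)
  }
  data.frame(f_case = f_case, f_control = f_control)
}

#' Configuration of a two-stage simulated GWAS
#'
#' Defaults reproduce the canonical simulation design used throughout the
#' package's experiments: m = 10^4 independent SNPs, effect-allele
#' frequency U(0.05, 0.5), disease prevalence 1 %, primary study of 1000
#' cases and 1000 controls, replication study of 500 and 500, two-sided
#' primary level 5e-5 and one-sided replication level 5e-3, with 90 % null
#' SNPs and Gaussian non-null effects of variance 0.04.
#'
#' @param m Number of SNPs.
#' @param maf_range Lower and upper bound of the uniform effect-allele
#'   frequency distribution.
#' @param prevalence Population disease probability.
#' @param n0_primary,n1_primary Primary-study controls and cases.
#' @param n0_rep,n1_rep Replication-study controls and cases.
#' @param alpha1 Two-sided primary significance level.
#' @param alpha2 One-sided replication significance level.
#' @param effect_model An [effect_size_model()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(m = 10000L, maf_range = c(0.05, 0.5),
                              prevalence = 0.01,
                              n0_primary = 1000L, n1_primary = 1000L,
                              n0_rep = 500L, n1_rep = 500L,
                              alpha1 = 5e-5, alpha2 = 5e-3,
                              effect_model = gaussian_effect_model()) {
  stopifnot(m >= 1, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[1] < maf_range[2],
            maf_range[2] <= 0.5,
            n0_primary >= 1, n1_primary >= 1, n0_rep >= 1, n1_rep >= 1,
            inherits(effect_model, "effect_size_model"))
  stop_if_not_prob(prevalence, "prevalence")
  stop_if_not_prob(alpha1, "alpha1", upper = 0.5)
  stop_if_not_prob(alpha2, "alpha2", upper = 0.5)
  structure(list(m = as.integer(m), maf_range = maf_range,
                 prevalence = prevalence,
                 n0_primary = as.integer(n0_primary),
                 n1_primary = as.integer(n1_primary),
                 n0_rep = as.integer(n0_rep), n1_rep = as.integer(n1_rep),
                 alpha1 = alpha1, alpha2 = alpha2,
                 effect_model = effect_model),
            class = "simulation_config")
}

#' Simulate a two-stage case-control GWAS
#'
#' Per SNP: draw the effect-allele frequency and true effect size, convert
#' to case/control allele frequencies under the prevalence-constrained
#' allele-level disease model, then draw effect-allele counts binomially
#' and independently for the primary and replication stages:
#' `n01 ~ Bin(2 n0, f_control)`, `n11 ~ Bin(2 n1, f_case)`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; fixed seeds give bit-identical
#'   output.
#' @return A list with elements `primary` and `replication` (allele-count
#'   data frames as from [allele_counts()]), `truth` (a data frame with
#'   `snp_id`, `maf`, `mu`, `f_case`, `f_control`) and `config`.
#' @export
simulate_two_stage <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    m <- config$m
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    mu <- draw_effect_sizes(config$effect_model, m)
    fq <- allele_frequencies_by_status(maf, mu, config$prevalence)
    id <- sprintf("snp%05d", seq_len(m))

    draw_stage <- function(n0, n1) {
      n01 <- rbinom(m, 2 * n0, fq$f_control)
      n11 <- rbinom(m, 2 * n1, fq$f_case)
      data.frame(snp_id = id,
                 n00 = 2 * n0 - n01, n01 = n01,
                 n10 = 2 * n1 - n11, n11 = n11,
                 stringsAsFactors = FALSE)
    }
    list(primary = draw_stage(config$n0_primary, config$n1_primary),
         replication = draw_stage(config$n0_rep, config$n1_rep),
         truth = data.frame(snp_id = id, maf = maf, mu = mu,
                            f_case = fq$f_case, f_control = fq$f_control,
                            stringsAsFactors = FALSE),
         config = config)
  })
}
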