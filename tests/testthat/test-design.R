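# Local true discovery rate, average power and sample-size determination.

test_that("ltdr matches an independent mixture-posterior computation", {
  s <- data.frame(mu_hat = 0.3, se = 0.1)  # z = 3, (sigma0/se)^2 = 4
  pr <- mixture_prior(0.9, 0.04)
  expect_equal(ltdr(s, pr), 0.645, tolerance = 1e-3)
  set.seed(23)
  for (i in 1:30) {
    z <- rnorm(1, 0, 3); se <- runif(1, 0.05, 0.2)
    pi0 <- runif(1, 0.5, 0.99); s0sq <- runif(1, 1e-3, 0.3)
    s <- data.frame(mu_hat = z * se, se = se, z = z)
    # oracle: Bayes' rule on the marginal with dnorm(., sd) densities
    f0 <- dnorm(z, 0, 1)
    f1 <- dnorm(z, 0, sqrt(1 + s0sq / se^2))
    oracle <- (1 - pi0) * f1 / (pi0 * f0 + (1 - pi0) * f1)
    expect_equal(ltdr(s, mixture_prior(pi0, s0sq)), oracle,
                 tolerance = 1e-10)
  }
})

test_that("ltdr handles degenerate priors and is increasing in |z|", {
  s <- toy_summaries()
  expect_equal(ltdr(s, mixture_prior(1, 0.04)), rep(0, 4))
  expect_equal(ltdr(s, mixture_prior(0, 0.04)), rep(1, 4))
  # flat-prior sentinel keeps identified SNPs at positive weight
  sent <- ltdr(s, mixture_prior(0.9, Inf))
  expect_true(all(sent > 0 & sent < 1))
  zs <- seq(0, 6, by = 0.5)
  grid <- data.frame(mu_hat = zs * 0.1, se = 0.1, z = zs)
  expect_true(all(diff(ltdr(grid, mixture_prior(0.9, 0.04))) > 0))
  # unnormalized compatibility form matches the printed-density convention
  s1 <- data.frame(mu_hat = 0.3, se = 0.1)
  ssq <- 1 + 0.04 / 0.01
  raw <- 0.1 * dnorm(3 / sqrt(ssq)) /
    (0.9 * dnorm(3) + 0.1 * dnorm(3 / sqrt(ssq)))
  expect_equal(ltdr(s1, mixture_prior(0.9, 0.04), normalized = FALSE), raw)
})

test_that("weighted average power reduces correctly and stays bounded", {
  pr <- mixture_prior(0.9, 0.04)
  s <- toy_summaries()
  sigma2 <- c(0.09, 0.08, 0.11, 0.07)
  eta <- eb_predictive_power(s, pr, sigma2, 5e-3)
  avg <- average_power_eb(s, pr, sigma2, 5e-3)
  expect_gte(avg, min(eta)); expect_lte(avg, max(eta))
  w <- ltdr(s, pr)
  expect_equal(avg, sum(w * eta) / sum(w))
  # single SNP: its own predictive power
  expect_equal(average_power_eb(s[1, ], pr, sigma2[1], 5e-3), eta[1])
  # identical summaries: equal weights, plain mean
  twin <- s[c(1, 1), ]
  expect_equal(average_power_eb(twin, pr, 0.1, 5e-3),
               mean(eb_predictive_power(twin, pr, 0.1, 5e-3)))
  expect_error(average_power_eb(s[0, ], pr, 0.1, 5e-3), "empty")
})

test_that("true average power is the elementwise mean of the power function", {
  mu <- c(0.2, -0.15, 0.3)
  sgn <- c(1, -1, 1)
  expect_equal(true_average_power(mu, sgn, 0.08, 5e-3),
               mean(replication_power(mu, sgn, 0.08, 5e-3)))
  expect_equal(true_average_power(0.2, 1, 0.08, 5e-3),
               replication_power(0.2, 1, 0.08, 5e-3))
  expect_equal(true_average_power(c(0, 0), c(1, -1), 0.08, 5e-3), 5e-3)
  expect_error(true_average_power(numeric(0), 1, 0.08, 5e-3), "empty")
})

test_that("sample-size search matches closed-form single-SNP inversion to one case", {
  pr <- mixture_prior(0.9, 0.04)
  set.seed(24)
  for (i in 1:5) {
    # tables with a real association, so the primary scan identifies them
    cells <- 2 * (rpois(4, c(450, 250, 300, 420)) + 20)
    tab <- allele_counts(cells[1], cells[2], cells[3], cells[4])
    s <- wald_summary(tab)
    expect_true(is_primary_significant(s$z, 5e-5))
    target <- runif(1, 0.5, 0.9)
    res <- required_sample_size(tab, pr, target_power = target, ratio = 1,
                                alpha2 = 5e-6, n_max = 1e6)
    # closed-form: sigma2(n) = sqrt(C/n); solve eta(n) = target on real n
    lam <- shrinkage_lambda(s$se, pr$sigma0_sq)
    C <- (cells[1] + cells[2]) / 2 * (1 / cells[1] + 1 / cells[2]) +
      (cells[3] + cells[4]) / 2 * (1 / cells[3] + 1 / cells[4])
    eta_n <- function(n) {
      s2 <- sqrt(C / n)
      pnorm((abs(lam * s$mu_hat) / s2 - qnorm(1 - 5e-6)) /
              sqrt(1 + lam * (s$se / s2)^2))
    }
    root <- uniroot(function(n) eta_n(n) - target, c(1, 1e6), tol = 1e-8)
    expect_lte(abs(res$n_cases - ceiling(root$root)), 1)
    expect_gte(res$achieved_power, target)
  }
})

test_that("sample-size search respects boundaries and monotonicity", {
  pr <- mixture_prior(0.9, 0.04)
  tab <- allele_counts(700, 300, 300, 700)  # very strong effect
  expect_equal(required_sample_size(tab, pr, target_power = 0.01,
                                    alpha2 = 5e-3)$n_cases, 1)
  lo <- required_sample_size(tab, pr, target_power = 0.4, alpha2 = 5e-6)
  hi <- required_sample_size(tab, pr, target_power = 0.8, alpha2 = 5e-6)
  expect_gte(hi$n_cases, lo$n_cases)
  expect_true(all(diff(hi$curve$average_power) >= 0))
  # unreachable target reports the power at n_max
  weak <- allele_counts(1000, 980, 980, 1000)
  expect_error(
    required_sample_size(weak, mixture_prior(0.9, 1e-4),
                         target_power = 0.99, alpha2 = 5e-8, n_max = 1e4),
    "unreachable")
  # stricter replication level never lowers the required size
  easy <- required_sample_size(tab, pr, target_power = 0.8, alpha2 = 5e-3)
  strict <- required_sample_size(tab, pr, target_power = 0.8, alpha2 = 5e-6)
  expect_gte(strict$n_cases, easy$n_cases)
})
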