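# Per-SNP power estimators and the conjugate posterior behind them.

test_that("shrinkage factor covers its limits", {
  expect_equal(shrinkage_lambda(0.1, 0), 0)
  expect_equal(shrinkage_lambda(0.1, Inf), 1)
  expect_equal(shrinkage_lambda(0.2, 0.04), 0.5)  # equal scales
  expect_error(shrinkage_lambda(0, 0.04), "se1")
})

test_that("posterior matches an independent precision-weighted Bayes update", {
  set.seed(10)
  for (i in 1:50) {
    mu_hat <- rnorm(1, 0, 0.4); se <- runif(1, 0.02, 0.3)
    sigma0_sq <- runif(1, 1e-4, 0.5)
    s <- data.frame(mu_hat = mu_hat, se = se)
    post <- posterior_effect(s, mixture_prior(0.9, sigma0_sq))
    prec <- 1 / se^2 + 1 / sigma0_sq   # independent route
    expect_equal(post$mean, (mu_hat / se^2) / prec, tolerance = 1e-12)
    expect_equal(post$variance, 1 / prec, tolerance = 1e-12)
  }
  # degenerate prior: point mass at zero
  d <- posterior_effect(toy_summaries(), mixture_prior(0.9, 0))
  expect_true(all(d$mean == 0) && all(d$variance == 0))
  # flat-prior sentinel: posterior equals the sampling distribution
  f <- posterior_effect(toy_summaries(), mixture_prior(0.9, Inf))
  expect_equal(f$mean, toy_summaries()$mu_hat)
  expect_equal(f$variance, toy_summaries()$se^2)
})

test_that("closed-form predictive power equals posterior-averaged power", {
  set.seed(11)
  for (i in 1:100) {
    mu_hat <- rnorm(1, 0, 0.3)
    if (abs(mu_hat) < 1e-3) mu_hat <- 0.1
    se <- runif(1, 0.03, 0.2); sigma0_sq <- runif(1, 1e-3, 0.3)
    sigma2 <- runif(1, 0.03, 0.2); alpha2 <- runif(1, 1e-4, 0.1)
    s <- data.frame(mu_hat = mu_hat, se = se)
    cf <- eb_predictive_power(s, mixture_prior(0.9, sigma0_sq), sigma2, alpha2)
    lam <- shrinkage_lambda(se, sigma0_sq)
    quad <- integrate(function(mu) {
      replication_power(mu, sign(mu_hat), sigma2, alpha2) *
        dnorm(mu, lam * mu_hat, sqrt(lam) * se)
    }, -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(cf, quad, tolerance = 1e-9)
  }
})

test_that("predictive power degenerates to alpha2 under the point-mass prior", {
  s <- toy_summaries()
  expect_equal(eb_predictive_power(s, mixture_prior(0.9, 0), 0.1, 5e-3),
               rep(5e-3, nrow(s)))
  expect_error(
    eb_predictive_power(data.frame(mu_hat = 0, se = 0.1),
                        mixture_prior(0.9, 0.04), 0.1, 5e-3), "z = 0")
})

test_that("predictive power converges to the plug-in as the posterior degenerates", {
  # lambda = 1 and a vanishing primary SE: posterior is a point at mu_hat
  s <- data.frame(mu_hat = 0.2, se = 1e-6)
  pr <- mixture_prior(0.9, Inf)
  expect_equal(eb_predictive_power(s, pr, 0.08, 5e-3),
               plugin_power(0.2, +1, 0.08, 5e-3), tolerance = 1e-6)
})

test_that("CMLE matches a dense grid search and shrinks toward zero", {
  set.seed(12)
  crit <- qnorm(1 - 2.5e-5)
  for (i in 1:12) {
    z <- sample(c(-1, 1), 1) * runif(1, crit + 0.1, 9)
    se <- runif(1, 0.05, 0.15)
    s <- data.frame(mu_hat = z * se, se = se)
    est <- cmle_effect(s, 5e-5)
    step <- 1e-4 * se
    grid <- seq(-2 * abs(s$mu_hat), 2 * abs(s$mu_hat), by = step)
    theta <- grid / se
    ll <- dnorm(z - theta, log = TRUE) -
      log(pnorm(theta - crit) + pnorm(-theta - crit))
    expect_lt(abs(est - grid[which.max(ll)]), 1.5 * step)
    expect_lte(abs(est), abs(s$mu_hat) + 1e-9)
  }
  # slightly above threshold: strong shrinkage toward zero
  s <- data.frame(mu_hat = (crit + 0.05) * 0.1, se = 0.1)
  expect_lt(abs(cmle_effect(s, 5e-5)), abs(s$mu_hat))
  # far above threshold: selection negligible
  s2 <- data.frame(mu_hat = 3 * crit * 0.1, se = 0.1)
  expect_equal(cmle_effect(s2, 5e-5), s2$mu_hat, tolerance = 0.01)
  expect_error(cmle_effect(data.frame(mu_hat = 0.1, se = 0.1), 5e-5),
               "significant")
})

test_that("EB effect estimator is the posterior mean", {
  s <- data.frame(mu_hat = 0.3, se = 0.1)
  expect_equal(eb_effect(s, mixture_prior(0.9, Inf)), 0.3)
  expect_equal(eb_effect(s, mixture_prior(0.9, 0)), 0)
  expect_equal(eb_effect(s, mixture_prior(0.9, 0.01)), 0.15)  # lambda = 1/2
})

test_that("plug-in power: naive dominates the EB plug-in when shrinkage is active", {
  set.seed(13)
  for (i in 1:20) {
    mu_hat <- runif(1, 0.05, 0.5); se <- runif(1, 0.05, 0.2)
    pr <- mixture_prior(0.9, runif(1, 1e-3, 0.2))
    s <- data.frame(mu_hat = mu_hat, se = se)
    naive <- plugin_power(mu_hat, +1, 0.1, 5e-3)
    shrunk <- plugin_power(eb_effect(s, pr), +1, 0.1, 5e-3)
    expect_gte(naive, shrunk)
  }
  expect_equal(plugin_power(0, +1, 0.1, 5e-3), 5e-3)
})
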