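test_that("model data constructor validates responses and nesting", {
  expect_error(ml_data(integer(0), integer(0), integer(0), integer(0)),
               "empty")
  expect_error(ml_data(c(0, 2), c(1, 1), c(1, 1), c(1, 1)), "binary")
  expect_error(ml_data(c(0, 1), c("c1", "c1"), c("d1", "d2"),
                       c("s1", "s1")), "more than one district")
  expect_error(ml_data(c(0, 1), c("c1", "c2"), c("d1", "d1"),
                       c("s1", "s2")), "more than one state")
  md <- ml_data(c(0, 1, 1), c("c1", "c1", "c2"), c("d1", "d1", "d1"),
                rep("s1", 3))
  expect_equal(md$J, 2L)
  expect_equal(md$n, 3L)
})

test_that("starting values follow the documented rules", {
  md <- ml_data(rep(c(0, 1), 10), rep(1:4, 5), rep(1, 20), rep(1, 20))
  st <- hlogit4_init(md)
  expect_equal(st$beta0, 0)
  expect_equal(st$sigma2_u, 0.1)

  md10 <- ml_data(rep(c(1, rep(0, 9)), 5), rep(1:5, 10), rep(1, 50),
                  rep(1, 50))
  expect_equal(hlogit4_init(md10)$beta0, qlogis(0.1), tolerance = 1e-12)

  zz <- hlogit4_init(md, "zeros")
  expect_equal(zz$beta0, 0)
  expect_true(all(zz$u == 0))

  # degenerate all-one response: clamped intercept with a warning
  md1 <- ml_data(rep(1, 9), rep(1:3, 3), rep(1, 9), rep(1, 9))
  expect_warning(st1 <- hlogit4_init(md1), "clamped")
  expect_equal(st1$beta0, -qlogis(1 / 10), tolerance = 1e-12)
})

test_that("Polya-Gamma draws match the closed-form mean", {
  set.seed(20)
  for (z in c(0, 0.5, 2, 6)) {
    x <- districtsae:::rpolyagamma(rep(z, 40000))
    m <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(x) - m), 3 * sd(x) / sqrt(length(x)))
    expect_true(all(x > 0))
  }
})

test_that("seeded fits are bit-reproducible and order-invariant", {
  cfg <- sim_config(n_states = 3, districts_per_state = 2,
                    clusters_per_district = 4,
                    mean_persons_per_cluster = 15, seed = 21)
  sv <- simulate_survey(cfg)
  tab <- build_outcome_table(sv$persons, "hypertension")
  fit1 <- hlogit4(status ~ state / district / cluster, data = tab,
                  burn_in = 50, n_iter = 300, seed = 77)
  fit2 <- hlogit4(status ~ state / district / cluster, data = tab,
                  burn_in = 50, n_iter = 300, seed = 77)
  expect_identical(fit1$draws, fit2$draws)

  # permuting person rows leaves the seeded fit identical
  perm <- tab[sample(nrow(tab)), ]
  fit3 <- hlogit4(status ~ state / district / cluster, data = perm,
                  burn_in = 50, n_iter = 300, seed = 77)
  expect_identical(fit3$draws, fit1$draws)

  # variance draws strictly positive at every iteration
  expect_true(all(fit1$draws$sigma2_u > 0))
  expect_true(all(fit1$draws$sigma2_v > 0))
  expect_true(all(fit1$draws$sigma2_f > 0))
})

test_that("posterior matches the quadrature reference on a tiny instance", {
  # one state > one district > one cluster, y = (1, 0): by symmetry the
  # flat-prior posterior mean of beta0 is 0; the grid oracle confirms it
  q <- quad_reference(c(1, 0), prior_a = 3, prior_b = 2)
  expect_lt(abs(q$beta0), 1e-8)
  md <- ml_data(c(1, 0), c(1, 1), c(1, 1), c(1, 1))
  fit <- hlogit4(md, burn_in = 1000, n_iter = 50000, prior_a = 3,
                 prior_b = 2, seed = 30, keep_effects = FALSE)
  for (p in c("beta0", "sigma2_u", "sigma2_v", "sigma2_f")) {
    ch <- fit$draws[[p]]
    mcse <- sd(ch) / sqrt(ess(ch))
    expect_lt(abs(mean(ch) - q[[p]]), 3 * mcse)
  }
})

test_that("degenerate grouping recovers the Bernoulli intercept posterior", {
  # every person its own cluster, one district, one state; variance
  # components pinned near zero by a tight prior, so the intercept
  # posterior is the plain logistic-intercept posterior
  y <- rep(c(1, 0, 0, 0, 0), 8)
  md <- ml_data(y, cluster = seq_along(y), district = rep(1, 40),
                state = rep(1, 40))
  fit <- hlogit4(md, burn_in = 1000, n_iter = 30000, prior_a = 101,
                 prior_b = 0.1, seed = 31, keep_effects = FALSE)
  oracle <- bernoulli_intercept_mean(y)
  ch <- fit$draws$beta0
  mcse <- sd(ch) / sqrt(ess(ch))
  # 0.01 allowance for the ~0.003 residual latent variance the tight
  # prior leaves in the model
  expect_lt(abs(mean(ch) - oracle), 3 * mcse + 0.01)
})

test_that("effective sample size estimator behaves on known chains", {
  set.seed(32)
  x <- rnorm(4000)
  expect_gt(ess(x), 3000)
  expect_lt(ess(x), 5000)

  expect_true(is.na(ess(rep(1, 100))))
  d <- mcmc_diagnostics(list(const = rep(1, 100)))
  expect_equal(d$flag, "constant")
  expect_error(mcmc_diagnostics(list(x = 1)), "at least 2")

  # AR(1), rho = 0.9: ESS ~= n (1 - rho) / (1 + rho) = 526; the bound
  # below is +-3 empirical SEs of the estimator at this n
  set.seed(33)
  e <- replicate(20, ess(ar1_chain(10000, 0.9)))
  expect_lt(abs(mean(e) - 10000 * 0.1 / 1.9), 3 * sd(e) / sqrt(20))
})

test_that("summary and diagnostics expose converged scalar parameters", {
  cfg <- sim_config(n_states = 3, districts_per_state = 2,
                    clusters_per_district = 4, seed = 22)
  sv <- simulate_survey(cfg)
  tab <- build_outcome_table(sv$persons, "hypertension")
  fit <- hlogit4(status ~ state / district / cluster, data = tab,
                 burn_in = 200, n_iter = 1000, seed = 23)
  s <- summary(fit)
  expect_equal(s$parameter, c("beta0", "sigma2_u", "sigma2_v", "sigma2_f"))
  expect_true(all(s$ess > 0))
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  d <- mcmc_diagnostics(fit)
  expect_true(all(d$mcse > 0))
  expect_output(print(fit), "Polya-Gamma")
})
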