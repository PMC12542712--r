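# minimal hand-built fit object for prediction arithmetic
fake_fit <- function(beta0, u, v, f, md) {
  structure(list(post_mean = list(beta0 = beta0, u = u, v = v, f = f),
                 draws = list(beta0 = beta0), data = md),
            class = "hlogit4")
}

test_that("plug-in predictions invert the summed posterior means", {
  md <- ml_data(c(0, 1, 0, 1), c("c1", "c1", "c2", "c2"),
                rep("d1", 4), rep("s1", 4))
  fit0 <- fake_fit(0, setNames(c(0, 0), c("c1", "c2")),
                   setNames(0, "d1"), setNames(0, "s1"), md)
  pr0 <- predict(fit0)
  expect_equal(pr0$prob, c(0.5, 0.5))
  expect_equal(pr0$n_persons, c(2L, 2L))

  fit1 <- fake_fit(-2.2, setNames(c(0, 0.5), c("c1", "c2")),
                   setNames(0, "d1"), setNames(0, "s1"), md)
  pr1 <- predict(fit1)
  expect_equal(pr1$prob[1], plogis(-2.2), tolerance = 1e-12)
  expect_equal(pr1$prob[2], plogis(-1.7), tolerance = 1e-12)
})

test_that("larger clusters are shrunk less at equal raw deviation", {
  # one district holds a 5-person and a 50-person cluster, both with
  # empirical prevalence far above the rest; the posterior-mean residual
  # (precision-weighted estimate) of the small cluster is pulled harder
  # toward zero
  set.seed(40)
  bg <- data.frame(cluster = rep(sprintf("bg%02d", 1:20), each = 30),
                   district = "d1", state = "s1",
                   status = rbinom(600, 1, 0.15))
  small <- data.frame(cluster = "small", district = "d1", state = "s1",
                      status = rbinom(5, 1, 0.6))
  big <- data.frame(cluster = "big", district = "d1", state = "s1",
                    status = rbinom(50, 1, 0.6))
  dat <- rbind(bg, small, big)
  fit <- hlogit4(status ~ state / district / cluster, data = dat,
                 burn_in = 300, n_iter = 2000, seed = 41,
                 keep_effects = FALSE)
  u <- residuals(fit, "cluster")
  expect_lt(abs(u["small"]), abs(u["big"]))
  expect_gt(u["big"], 0)
})

test_that("district prevalence is the simple cluster average", {
  preds <- data.frame(cluster = c("c1", "c2", "c3", "c4"),
                      district = c("d1", "d1", "d1", "d2"),
                      prob = c(0.10, 0.20, 0.30, 0.07),
                      n_persons = c(10L, 20L, 30L, 5L))
  est <- district_prevalence(preds, wave = 1, sex = "female",
                             outcome = "hypertension")
  expect_equal(est$prevalence[est$district == "d1"], 20.0)
  expect_equal(est$prevalence[est$district == "d2"], 7.0)
  expect_equal(est$n_clusters, c(3L, 1L))
  expect_equal(est$n_persons, c(60L, 5L))

  # permutation invariance
  est2 <- district_prevalence(preds[sample(4), ], wave = 1,
                              sex = "female", outcome = "hypertension")
  expect_equal(est2, est)

  # prevalence bounded by the member clusters' probabilities
  set.seed(42)
  pr <- data.frame(cluster = sprintf("c%03d", 1:300),
                   district = sample(sprintf("d%02d", 1:30), 300, TRUE),
                   prob = runif(300, 0.01, 0.4))
  e <- district_prevalence(pr)
  rng <- do.call(rbind, lapply(split(pr$prob, pr$district), range))
  expect_true(all(e$prevalence >= 100 * rng[e$district, 1] - 1e-9))
  expect_true(all(e$prevalence <= 100 * rng[e$district, 2] + 1e-9))

  expect_error(district_prevalence(transform(preds, prob = prob * 10)),
               "inside")
})

test_that("plug-in and draw-averaged predictions agree for tight posteriors", {
  # large clusters and modest between-cluster variance keep the
  # cluster-level posteriors tight, the regime the agreement refers to
  cfg <- sim_config(n_states = 3, districts_per_state = 3,
                    clusters_per_district = 5,
                    mean_persons_per_cluster = 50,
                    sigma2_u = 0.1, seed = 43)
  sv <- simulate_survey(cfg)
  tab <- build_outcome_table(sv$persons, "hypertension")
  fit <- hlogit4(status ~ state / district / cluster, data = tab,
                 burn_in = 500, n_iter = 4000, seed = 44)
  plug <- predict(fit, type = "plugin")
  avg <- predict(fit, type = "draws")
  expect_lt(max(abs(plug$prob - avg$prob)), 0.005)
})

test_that("distribution summaries follow the box-plot conventions", {
  s <- distribution_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3.0)
  expect_equal(s$iqr, 2.0)

  s0 <- distribution_summary(rep(7, 10))
  expect_equal(s0$iqr, 0)
  expect_equal(s0$n_outliers, 0L)

  # median of 720 uniform(5, 15) draws within 3 order-statistic SEs of 10
  set.seed(45)
  x <- runif(720, 5, 15)
  se_med <- 1 / (2 * 0.1 * sqrt(720))      # 1 / (2 f(m) sqrt(n))
  expect_lt(abs(distribution_summary(x)$median - 10), 3 * se_med)

  expect_error(distribution_summary(numeric(0)), "empty")
})
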