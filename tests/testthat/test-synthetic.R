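test_that("frame generation respects configured counts and seeding", {
  cfg <- sim_config(n_states = 2, districts_per_state = 2,
                    clusters_per_district = 2, seed = 3)
  fr <- generate_frame(cfg)
  expect_equal(nrow(fr), 8L)
  expect_equal(length(unique(fr$district)), 4L)
  expect_true(all(fr$size >= 10 & fr$size <= 60))
  expect_identical(generate_frame(cfg), fr)

  cfg2 <- sim_config(n_states = 15, districts_per_state = 8, seed = 4)
  fr2 <- generate_frame(cfg2)
  expect_equal(length(unique(fr2$district)), 120L)
  # every district has exactly one parent state
  expect_equal(anyDuplicated(unique(fr2[c("district", "state")])$district), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_states = 0), "counts")
  expect_error(sim_config(sigma2_u = -1), "variance")
  expect_error(sim_config(missing_rate = 1.5), "0, 1")
})

test_that("random effects have the configured variances, and vanish at zero", {
  cfg0 <- sim_config(n_states = 2, districts_per_state = 2,
                     clusters_per_district = 3, sigma2_u = 0,
                     sigma2_v = 0, sigma2_f = 0, seed = 5)
  fr0 <- generate_frame(cfg0)
  ef0 <- draw_random_effects(fr0, cfg0)
  expect_identical(unname(ef0$u), rep(0, nrow(fr0)))
  expect_identical(unname(ef0$v), rep(0, 4))
  expect_identical(unname(ef0$f), rep(0, 2))

  # 10,000 clusters: sample variance inside the 99% chi-square band
  cfg <- sim_config(n_states = 10, districts_per_state = 10,
                    clusters_per_district = 100, sigma2_u = 0.3, seed = 6)
  fr <- generate_frame(cfg)
  ef <- draw_random_effects(fr, cfg)
  n <- length(ef$u)
  band <- 0.3 * qchisq(c(0.005, 0.995), n - 1) / (n - 1)
  expect_gt(var(ef$u), band[1])
  expect_lt(var(ef$u), band[2])
  # seeded determinism
  expect_identical(draw_random_effects(fr, cfg), ef)
})

test_that("person probabilities follow the inverse-logit of the linear predictor", {
  cfg <- sim_config(n_states = 2, districts_per_state = 2,
                    clusters_per_district = 2, beta0 = 0,
                    sigma2_u = 0, sigma2_v = 0, sigma2_f = 0, seed = 7)
  fr <- generate_frame(cfg)
  ef <- draw_random_effects(fr, cfg)
  pp <- simulate_individuals(fr, ef, cfg)
  expect_true(all(pp$true_p == 0.5))
  expect_true(all(pp$age >= 15 & pp$age <= 49))
  expect_true(all(pp$weight > 0))
  expect_equal(nrow(pp), sum(fr$size))

  cfg2 <- sim_config(n_states = 2, districts_per_state = 2,
                     clusters_per_district = 2, beta0 = -2.2,
                     sigma2_u = 0, sigma2_v = 0, sigma2_f = 0, seed = 7)
  pp2 <- simulate_individuals(fr, draw_random_effects(fr, cfg2), cfg2)
  expect_equal(unique(pp2$true_p), plogis(-2.2), tolerance = 1e-12)

  # no missingness at rate zero, biomarker mode
  cfgb <- sim_config(n_states = 2, districts_per_state = 2,
                     clusters_per_district = 2, biomarker_mode = TRUE,
                     missing_rate = 0, seed = 8)
  frb <- generate_frame(cfgb)
  ppb <- simulate_individuals(frb, draw_random_effects(frb, cfgb), cfgb)
  bio <- c(paste0("sbp", 1:3), paste0("dbp", 1:3), "glucose")
  expect_false(anyNA(ppb[bio]))
  # effects drawn for a structurally different frame are rejected
  cfg3 <- sim_config(n_states = 2, districts_per_state = 2,
                     clusters_per_district = 3, seed = 8)
  fr3 <- generate_frame(cfg3)
  expect_error(simulate_individuals(frb, draw_random_effects(fr3, cfg3),
                                    cfgb), "misaligned")
})

test_that("biomarker calibration recovers the model probability at scale", {
  # >= 100,000 persons; classified prevalence within 3 Monte-Carlo
  # standard errors of the mean true probability
  cfg <- sim_config(n_states = 10, districts_per_state = 10,
                    clusters_per_district = 25,
                    mean_persons_per_cluster = 45,
                    biomarker_mode = TRUE, missing_rate = 0, seed = 9)
  sv <- simulate_survey(cfg)
  expect_gte(nrow(sv$persons), 1e5)
  tab <- build_outcome_table(sv$persons, "hypertension")
  p_true <- mean(sv$persons$true_p)
  mcse <- sqrt(mean(sv$persons$true_p * (1 - sv$persons$true_p)) /
                 nrow(sv$persons))
  expect_lt(abs(mean(tab$status) - p_true), 3 * mcse)

  cfgd <- sim_config(n_states = 10, districts_per_state = 10,
                     clusters_per_district = 25,
                     mean_persons_per_cluster = 45, outcome = "diabetes",
                     biomarker_mode = TRUE, missing_rate = 0, seed = 10)
  svd <- simulate_survey(cfgd)
  tabd <- build_outcome_table(svd$persons, "diabetes")
  p_trued <- mean(svd$persons$true_p)
  mcsed <- sqrt(mean(svd$persons$true_p * (1 - svd$persons$true_p)) /
                  nrow(svd$persons))
  expect_lt(abs(mean(tabd$status) - p_trued), 3 * mcsed)
})

test_that("zero variance components leave only binomial district noise", {
  cfg <- sim_config(n_states = 5, districts_per_state = 6,
                    clusters_per_district = 10, beta0 = -2.2,
                    sigma2_u = 0, sigma2_v = 0, sigma2_f = 0, seed = 11)
  sv <- simulate_survey(cfg)
  tab <- build_outcome_table(sv$persons, "hypertension")
  counts <- table(tab$district, tab$status)
  expect_gt(suppressWarnings(chisq.test(counts))$p.value, 0.01)
})

test_that("two-wave generation conserves clusters and splits districts", {
  cfg <- sim_config(n_states = 1, districts_per_state = 13,
                    clusters_per_district = 4, split_fraction = 1, seed = 12)
  tw <- simulate_two_waves(cfg)
  # 13 districts split in two -> 26 target districts
  expect_equal(nrow(tw$target_districts), 26L)
  # every wave-1 cluster appears exactly once in the crosswalk
  w1cl <- tw$wave1$frame$cluster
  xw1 <- tw$crosswalk[tw$crosswalk$wave == 1, ]
  expect_setequal(xw1$cluster, w1cl)
  expect_equal(anyDuplicated(xw1$cluster), 0L)
  # person conservation
  expect_equal(nrow(tw$wave1$persons), sum(tw$wave1$frame$size))

  # split_fraction = 0: crosswalk is the identity on district IDs
  cfg0 <- sim_config(n_states = 2, districts_per_state = 3,
                     clusters_per_district = 2, split_fraction = 0,
                     seed = 13)
  tw0 <- simulate_two_waves(cfg0)
  xw0 <- tw0$crosswalk[tw0$crosswalk$wave == 1, ]
  expect_identical(xw0$district,
                   tw0$wave1$frame$district[match(xw0$cluster,
                                                  tw0$wave1$frame$cluster)])
  # bit-identical reruns under the same config
  tw0b <- simulate_two_waves(cfg0)
  expect_identical(tw0b$wave1$persons, tw0$wave1$persons)
  expect_identical(tw0b$crosswalk, tw0$crosswalk)
})
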