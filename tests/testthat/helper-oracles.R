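# Independent oracles and shared fixtures for the test suite.

# 1-D quadrature posterior mean of the intercept of a plain Bernoulli
# logistic model (flat prior); independent of the Gibbs sampler.
bernoulli_intercept_mean <- function(y, lim = 30, step = 0.005) {
  g <- seq(-lim, lim, by = step)
  loglik <- sum(y) * g - length(y) * log1p(exp(g))
  w <- exp(loglik - max(loglik))
  sum(g * w) / sum(w)
}

# AR(1) chain with known autocorrelation time (1 + rho) / (1 - rho)
ar1_chain <- function(n, rho) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, 0, sqrt(1 - rho^2))
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  x
}

# Parameter-recovery study at the package's validation design, shared
# between the sampler-recovery and end-to-end acceptance checks.
# Memoized so the replicates are fitted once per test run.
.recovery_cache <- new.env(parent = emptyenv())

recovery_design <- function() {
  list(n_states = 15, districts_per_state = 8, clusters_per_district = 10,
       mean_persons_per_cluster = 30, beta0 = -2.2,
       sigma2_u = 0.3, sigma2_v = 0.2, sigma2_f = 0.1)
}

recovery_study <- function(n_rep = 20, base_seed = 42,
                           burn_in = 500, n_iter = 5000) {
  key <- paste("rs", n_rep, base_seed, sep = "_")
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  truth <- c(beta0 = -2.2, sigma2_u = 0.3, sigma2_v = 0.2, sigma2_f = 0.1)
  des <- recovery_design()
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- do.call(sim_config, c(des, list(seed = base_seed + r)))
    sv <- simulate_survey(cfg)
    tab <- build_outcome_table(sv$persons, "hypertension")
    md <- ml_data(tab$status, tab$cluster, tab$district, tab$state,
                  person_id = tab$person_id)
    fit <- hlogit4(md, burn_in = burn_in, n_iter = n_iter,
                   seed = base_seed + 1000 + r, keep_effects = FALSE)
    pm <- coef(fit)
    ci <- sapply(c("beta0", "sigma2_u", "sigma2_v", "sigma2_f"),
                 function(p) quantile(fit$draws[[p]], c(0.025, 0.975)))
    rec <- list(post_mean = pm,
                covered = ci[1, ] <= truth & truth <= ci[2, ])
    if (r == 1L) {
      # keep the first replicate's district estimates for the
      # end-to-end truth-recovery check
      preds <- predict(fit)
      est <- district_prevalence(preds)
      tr <- sv$truth$district_prev
      rec$district_cor <- cor(
        est$prevalence[match(tr$district, est$district)], tr$prevalence)
    }
    reps[[r]] <- rec
  }
  out <- list(truth = truth,
              post_mean = do.call(rbind, lapply(reps, `[[`, "post_mean")),
              covered = do.call(rbind, lapply(reps, `[[`, "covered")),
              district_cor = reps[[1]]$district_cor)
  .recovery_cache[[key]] <- out
  out
}
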