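# Synthetic two-wave cluster-survey generator with known variance
# components.  Emulates the NFHS-style design: states > districts >
# clusters > individuals, clusters of unequal size (PPS-like), biomarker
# readings calibrated so WHO-cutoff classification recovers the model
# probability, sampling weights, MCAR item missingness, and a wave-2
# district split with a cluster-to-district crosswalk.

# biomarker population constants (mmHg, mg/dL); see the methods vignette
.bio <- list(mu_sbp = 118, tau_sbp = 12, mu_dbp = 76, tau_dbp = 9,
             rho = 0.7,           # latent SBP-DBP correlation
             read_sd = 4,         # per-reading measurement noise
             first_shift = 3,     # first-reading elevation artifact
             dbp_slope = 0.6,     # DBP shift per mmHg of SBP shift
             mu_lgluc = log(105), sd_lgluc = 0.35)

#' Configuration for the synthetic survey generator
#'
#' Defaults reproduce the validation design used throughout the package:
#' 15 states x 8 districts x 10 clusters x ~30 persons, with true
#' variance components \eqn{\sigma^2_u = 0.3} (cluster),
#' \eqn{\sigma^2_v = 0.2} (district), \eqn{\sigma^2_f = 0.1} (state) and
#' wave intercepts on the log-odds scale calibrated to women's
#' hypertension prevalence in the two survey rounds (9.2\% and 9.8\%).
#'
#' @param n_states number of states.
#' @param districts_per_state districts per state.
#' @param clusters_per_district clusters per district.
#' @param mean_persons_per_cluster target mean cluster size; realized
#'   sizes are log-normal truncated to [10, 60], mimicking
#'   probability-proportional-to-size heterogeneity.
#' @param beta0 log-odds intercept(s): a single value, or length 2 for
#'   (wave 1, wave 2).
#' @param sigma2_u,sigma2_v,sigma2_f true variance components on the
#'   log-odds scale (cluster, district, state).
#' @param biomarker_mode if \code{TRUE}, generate SBP/DBP/glucose
#'   readings calibrated to the model probability; if \code{FALSE}
#'   (fast default) draw the binary outcome directly.
#' @param outcome which outcome the intercept and (in biomarker mode)
#'   the calibration refer to.
#' @param sex sex stratum label attached to every person (the study
#'   fits sexes separately, so one run is one stratum).
#' @param missing_rate MCAR missingness probability per biomarker item.
#' @param split_fraction fraction of wave-1 districts split in two in
#'   wave 2 (default matches the study: 13 of ~707).
#' @param seed integer seed; all generator output is a deterministic
#'   function of the config.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_states = 15, districts_per_state = 8,
                       clusters_per_district = 10,
                       mean_persons_per_cluster = 30,
                       beta0 = c(-2.29, -2.22),
                       sigma2_u = 0.3, sigma2_v = 0.2, sigma2_f = 0.1,
                       biomarker_mode = FALSE,
                       outcome = c("hypertension", "diabetes"),
                       sex = c("female", "male"),
                       missing_rate = 0.02, split_fraction = 0.02,
                       seed = 1) {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  counts <- c(n_states = n_states, districts_per_state = districts_per_state,
              clusters_per_district = clusters_per_district,
              mean_persons_per_cluster = mean_persons_per_cluster)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("all counts must be integers >= 1: ",
         paste(names(counts)[counts < 1 | counts != floor(counts)],
               collapse = ", "), call. = FALSE)
  if (any(c(sigma2_u, sigma2_v, sigma2_f) < 0))
    stop("variance components must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1 ||
      split_fraction < 0 || split_fraction > 1)
    stop("missing_rate and split_fraction must lie in [0, 1]",
         call. = FALSE)
  if (!length(beta0) %in% 1:2 || anyNA(beta0))
    stop("beta0 must be one value or one per wave", call. = FALSE)
  if (length(beta0) == 1L) beta0 <- rep(beta0, 2)
  structure(list(n_states = as.integer(n_states),
                 districts_per_state = as.integer(districts_per_state),
                 clusters_per_district = as.integer(clusters_per_district),
                 mean_persons_per_cluster = as.integer(mean_persons_per_cluster),
                 beta0 = as.numeric(beta0),
                 sigma2_u = sigma2_u, sigma2_v = sigma2_v,
                 sigma2_f = sigma2_f,
                 biomarker_mode = isTRUE(biomarker_mode),
                 outcome = outcome, sex = sex,
                 missing_rate = missing_rate,
                 split_fraction = split_fraction,
                 seed = as.integer(seed)), class = "sim_config")
}

# log-normal cluster-size measure truncated to [10, 60]
.draw_cluster_sizes <- function(n, mean_size) {
  sdlog <- 0.35
  s <- round(rlnorm(n, meanlog = log(mean_size) - sdlog^2 / 2,
                    sdlog = sdlog))
  pmin(pmax(s, 10L), 60L)
}

#' Generate the nested sampling frame
#'
#' States, districts, clusters and per-cluster target sizes, fully
#' determined by the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param districts optional explicit district table (data frame with
#'   \code{state}, \code{district}) overriding the regular
#'   states-by-districts grid; used internally for the wave-2 frame.
#' @param id_prefix prefix for cluster IDs (keeps the two waves' cluster
#'   IDs distinct).
#' @param seed seed for the cluster-size draws (defaults to
#'   \code{config$seed}).
#' @return Data frame of class \code{"survey_frame"}: one row per
#'   cluster with \code{state}, \code{district}, \code{cluster},
#'   \code{size}.
#' @export
generate_frame <- function(config, districts = NULL, id_prefix = "W1",
                           seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(districts)) {
    st <- sprintf("S%02d", seq_len(config$n_states))
    districts <- data.frame(
      state = rep(st, each = config$districts_per_state),
      district = paste0(rep(st, each = config$districts_per_state),
                        sprintf("D%02d",
                                seq_len(config$districts_per_state))),
      stringsAsFactors = FALSE)
  }
  cpd <- config$clusters_per_district
  frame <- data.frame(
    state = rep(districts$state, each = cpd),
    district = rep(districts$district, each = cpd),
    stringsAsFactors = FALSE)
  frame$cluster <- paste0(id_prefix, "_", frame$district,
                          sprintf("C%03d", seq_len(cpd)))
  set.seed(seed)
  frame$size <- .draw_cluster_sizes(nrow(frame),
                                    config$mean_persons_per_cluster)
  class(frame) <- c("survey_frame", "data.frame")
  frame
}

#' Draw the random intercepts for a frame
#'
#' Independent zero-mean normal draws per cluster, district and state
#' with the config's variance components; zero variance yields exactly
#' zero effects.
#'
#' @param frame a \code{\link{generate_frame}} result.
#' @param config the \code{\link{sim_config}}.
#' @param seed seed for the effect draws (defaults to
#'   \code{config$seed + 1}).
#' @return List of class \code{"effect_set"} with named vectors
#'   \code{u} (clusters), \code{v} (districts), \code{f} (states) and
#'   the generating variances.
#' @export
draw_random_effects <- function(frame, config, seed = config$seed + 1L) {
  stopifnot(inherits(frame, "survey_frame"), inherits(config, "sim_config"))
  set.seed(seed)
  cl <- frame$cluster
  di <- unique(frame$district)
  st <- unique(frame$state)
  structure(list(
    u = setNames(rnorm(length(cl), 0, sqrt(config$sigma2_u)), cl),
    v = setNames(rnorm(length(di), 0, sqrt(config$sigma2_v)), di),
    f = setNames(rnorm(length(st), 0, sqrt(config$sigma2_f)), st),
    sigma2_u = config$sigma2_u, sigma2_v = config$sigma2_v,
    sigma2_f = config$sigma2_f), class = "effect_set")
}

# P(mean of readings 2-3 crosses 140 SBP and/or 90 DBP) as a function of
# the common mean shift delta, under the generator's biomarker model
.p_hyper_given_shift <- function(delta) {
  b <- .bio
  s_sd <- sqrt(b$tau_sbp^2 + b$read_sd^2 / 2)
  d_sd <- sqrt(b$tau_dbp^2 + b$read_sd^2 / 2)
  rho2 <- b$rho * b$tau_sbp * b$tau_dbp / (s_sd * d_sd)
  vapply(delta, function(dl) {
    za <- (140 - (b$mu_sbp + dl)) / s_sd
    zb <- (90 - (b$mu_dbp + b$dbp_slope * dl)) / d_sd
    # P(S < za, D < zb) for standard bivariate normal, via 1-D integral
    pr <- integrate(function(t)
      dnorm(t) * pnorm((zb - rho2 * t) / sqrt(1 - rho2^2)),
      -Inf, za, rel.tol = 1e-10)$value
    1 - pr
  }, 0)
}

# monotone shift grid -> probability lookup, built once per call
.hyper_shift_for_p <- function(p) {
  grid <- seq(-90, 70, by = 0.5)
  pg <- .p_hyper_given_shift(grid)
  if (any(p < min(pg) | p > max(pg)))
    stop("target probability outside calibratable range", call. = FALSE)
  approx(pg, grid, xout = p, ties = "ordered")$y
}

#' Simulate person records for a frame
#'
#' Each person's true outcome probability is
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + u + v + f)}.  In binary mode the
#' outcome indicator is drawn directly.  In biomarker mode, latent blood
#' pressure (or log-glucose, for the diabetes outcome) is mean-shifted
#' per person so that the probability of crossing the WHO classification
#' cutoffs -- applied to the mean of readings 2-3 for blood pressure --
#' equals the model probability exactly; three readings are then
#' generated as latent value plus independent noise (sd 4 mmHg) with a
#' +3 mmHg first-reading elevation.  Ages are uniform on 15-49, weights
#' log-normal with mean 1, and each biomarker item is set missing
#' completely at random at \code{missing_rate}.
#'
#' @param frame a \code{\link{generate_frame}} result.
#' @param effects the matching \code{\link{draw_random_effects}} result.
#' @param config the \code{\link{sim_config}}.
#' @param wave which wave's intercept to use (1 or 2).
#' @param seed seed for the person-level draws (defaults to
#'   \code{config$seed + 2}).
#' @return Data frame with one row per person: IDs, \code{age},
#'   \code{sex}, \code{weight}, biomarkers or \code{status}, and the
#'   generator-truth column \code{true_p}.
#' @export
simulate_individuals <- function(frame, effects, config, wave = 1L,
                                 seed = config$seed + 2L) {
  stopifnot(inherits(frame, "survey_frame"), inherits(effects, "effect_set"),
            inherits(config, "sim_config"))
  if (!identical(names(effects$u), frame$cluster))
    stop("frame and effects are misaligned", call. = FALSE)
  set.seed(seed)
  n <- sum(frame$size)
  idx <- rep(seq_len(nrow(frame)), frame$size)
  cluster <- frame$cluster[idx]
  district <- frame$district[idx]
  state <- frame$state[idx]
  eta <- config$beta0[wave] + effects$u[cluster] + effects$v[district] +
    effects$f[state]
  true_p <- plogis(unname(eta))

  persons <- data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    cluster = cluster, district = district, state = state,
    age = sample(15:49, n, replace = TRUE),
    sex = config$sex,
    weight = rlnorm(n, meanlog = -0.3^2 / 2, sdlog = 0.3),
    stringsAsFactors = FALSE)

  if (!config$biomarker_mode) {
    persons$status <- rbinom(n, 1, true_p)
    persons$true_p <- true_p
    return(persons)
  }

  b <- .bio
  if (config$outcome == "hypertension") {
    delta <- .hyper_shift_for_p(true_p)
    z1 <- rnorm(n); z2 <- rnorm(n)
    sbp_lat <- b$mu_sbp + delta + b$tau_sbp * z1
    dbp_lat <- b$mu_dbp + b$dbp_slope * delta +
      b$tau_dbp * (b$rho * z1 + sqrt(1 - b$rho^2) * z2)
    gluc <- rlnorm(n, b$mu_lgluc, b$sd_lgluc)      # uncalibrated marginal
  } else {
    delta <- log(200) - b$mu_lgluc - b$sd_lgluc * qnorm(1 - true_p)
    gluc <- exp(b$mu_lgluc + delta + b$sd_lgluc * rnorm(n))
    z1 <- rnorm(n); z2 <- rnorm(n)
    sbp_lat <- b$mu_sbp + b$tau_sbp * z1           # uncalibrated marginal
    dbp_lat <- b$mu_dbp + b$tau_dbp * (b$rho * z1 + sqrt(1 - b$rho^2) * z2)
  }
  persons$sbp1 <- sbp_lat + b$first_shift + rnorm(n, 0, b$read_sd)
  persons$sbp2 <- sbp_lat + rnorm(n, 0, b$read_sd)
  persons$sbp3 <- sbp_lat + rnorm(n, 0, b$read_sd)
  persons$dbp1 <- dbp_lat + b$first_shift + rnorm(n, 0, b$read_sd)
  persons$dbp2 <- dbp_lat + rnorm(n, 0, b$read_sd)
  persons$dbp3 <- dbp_lat + rnorm(n, 0, b$read_sd)
  persons$glucose <- gluc

  if (config$missing_rate > 0) {
    for (r in 1:3) {
      miss <- runif(n) < config$missing_rate
      persons[[paste0("sbp", r)]][miss] <- NA_real_
      persons[[paste0("dbp", r)]][miss] <- NA_real_
    }
    persons$glucose[runif(n) < config$missing_rate] <- NA_real_
  }
  persons$true_p <- true_p
  persons
}

#' Simulate one complete survey wave
#'
#' Convenience wrapper: frame, effects and persons for a single wave,
#' plus the generator truth at cluster and district level (the district
#' truth is the simple average of its clusters' mean true
#' probabilities, matching the estimand of
#' \code{\link{district_prevalence}}).
#'
#' @param config a \code{\link{sim_config}}.
#' @param wave wave number (selects the intercept).
#' @param id_prefix cluster ID prefix.
#' @param districts optional explicit district table (see
#'   \code{\link{generate_frame}}).
#' @param seed_offset offset added to the config seed for this wave's
#'   effect and person draws.
#' @return List with \code{frame}, \code{effects}, \code{persons},
#'   \code{truth} (data frames \code{cluster_p} and \code{district_prev},
#'   the latter in percent).
#' @export
simulate_survey <- function(config, wave = 1L, id_prefix = "W1",
                            districts = NULL, seed_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  frame <- generate_frame(config, districts = districts,
                          id_prefix = id_prefix,
                          seed = config$seed + seed_offset)
  effects <- draw_random_effects(frame, config,
                                 seed = config$seed + 1L + seed_offset)
  persons <- simulate_individuals(frame, effects, config, wave = wave,
                                  seed = config$seed + 2L + seed_offset)
  cl_p <- aggregate(true_p ~ cluster + district + state, persons, mean)
  di_p <- aggregate(true_p ~ district, cl_p, mean)
  truth <- list(cluster_p = cl_p,
                district_prev = data.frame(district = di_p$district,
                                           prevalence = 100 * di_p$true_p,
                                           stringsAsFactors = FALSE))
  list(frame = frame, effects = effects, persons = persons, truth = truth)
}

#' Simulate a two-wave survey with a district split and crosswalk
#'
#' Wave 1 uses the original district frame.  A fraction of wave-1
#' districts is split into two districts for wave 2, mirroring a
#' boundary change between survey rounds; wave 2 is drawn on the
#' resulting target frame (fresh clusters, fresh random effects, the
#' wave-2 intercept).  The returned crosswalk maps every cluster of both
#' waves to its target-frame district, allocating the clusters of a
#' split wave-1 district alternately to the two successor districts.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{wave1} and \code{wave2}
#'   (\code{\link{simulate_survey}} results), the \code{crosswalk} data
#'   frame (\code{wave}, \code{cluster}, \code{district}, \code{state}),
#'   and \code{target_districts}.
#' @export
simulate_two_waves <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w1 <- simulate_survey(config, wave = 1L, id_prefix = "W1")

  d1 <- unique(w1$frame[c("state", "district")])
  n_split <- round(config$split_fraction * nrow(d1))
  set.seed(config$seed + 100L)
  split_ids <- if (n_split > 0)
    sort(sample(d1$district, n_split)) else character(0)

  # target frame: split districts replaced by two successor districts
  tgt <- do.call(rbind, lapply(seq_len(nrow(d1)), function(i) {
    if (d1$district[i] %in% split_ids) {
      data.frame(state = d1$state[i],
                 district = paste0(d1$district[i], c("a", "b")),
                 parent = d1$district[i], stringsAsFactors = FALSE)
    } else {
      data.frame(state = d1$state[i], district = d1$district[i],
                 parent = d1$district[i], stringsAsFactors = FALSE)
    }
  }))

  w2 <- simulate_survey(config, wave = 2L, id_prefix = "W2",
                        districts = tgt[c("state", "district")],
                        seed_offset = 1000L)

  # wave-1 clusters: alternate the clusters of a split district between
  # its two successors; all others keep their district
  xw1 <- w1$frame[c("state", "district", "cluster")]
  xw1$target <- xw1$district
  for (sd in split_ids) {
    rows <- which(xw1$district == sd)
    xw1$target[rows] <- paste0(sd, c("a", "b"))[1 + (seq_along(rows) + 1) %% 2]
  }
  xw <- rbind(
    data.frame(wave = 1L, cluster = xw1$cluster, district = xw1$target,
               state = xw1$state, stringsAsFactors = FALSE),
    data.frame(wave = 2L, cluster = w2$frame$cluster,
               district = w2$frame$district, state = w2$frame$state,
               stringsAsFactors = FALSE))
  list(wave1 = w1, wave2 = w2, crosswalk = xw,
       target_districts = tgt)
}
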