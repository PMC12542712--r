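#' Fixed person-level variance of the logistic model
#'
#' In a latent-response formulation of logistic regression the
#' person-level residual is standard-logistic with fixed variance
#' \eqn{\pi^2 / 3 \approx 3.29}; every variance component in the model is
#' interpreted against this constant.
#'
#' @return \eqn{\pi^2/3}.
#' @export
level1_variance <- function() pi^2 / 3

#' Assemble model data for the four-level logistic model
#'
#' Validates and indexes person-level binary outcomes against the
#' cluster / district / state nesting.  Rows are put into a canonical
#' order (sorted by \code{person_id}) before any random draws are made,
#' so that fits are invariant to the input row order.
#'
#' @param y binary response vector (0/1).
#' @param cluster,district,state grouping identifiers, one per person.
#'   Each cluster must belong to exactly one district and each district
#'   to exactly one state.
#' @param person_id unique person identifiers; defaults to the row
#'   position.  Used only to fix the canonical ordering.
#'
#' @return An object of class \code{"ml_data"}: a list with the response,
#'   0-based dense index vectors \code{cl}, \code{di}, \code{st}, the
#'   level label vectors, and the cluster-to-district / district-to-state
#'   maps.
#' @export
ml_data <- function(y, cluster, district, state, person_id = seq_along(y)) {
  n <- length(y)
  if (n == 0L) stop("empty response", call. = FALSE)
  if (length(cluster) != n || length(district) != n || length(state) != n ||
      length(person_id) != n)
    stop("y, cluster, district, state and person_id must have equal length",
         call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("response must be binary 0/1 with no missing values", call. = FALSE)
  if (anyDuplicated(person_id))
    stop("person_id must be unique", call. = FALSE)

  ord <- order(person_id)
  y <- as.integer(y[ord])
  cluster <- as.character(cluster[ord])
  district <- as.character(district[ord])
  state <- as.character(state[ord])

  # nesting consistency
  cd <- unique(data.frame(cluster, district, stringsAsFactors = FALSE))
  if (anyDuplicated(cd$cluster))
    stop("some clusters appear in more than one district", call. = FALSE)
  ds <- unique(data.frame(district, state, stringsAsFactors = FALSE))
  if (anyDuplicated(ds$district))
    stop("some districts appear in more than one state", call. = FALSE)

  cl_lev <- sort(unique(cluster))
  di_lev <- sort(unique(district))
  st_lev <- sort(unique(state))

  structure(list(
    y = y,
    cl = match(cluster, cl_lev) - 1L,
    di = match(district, di_lev) - 1L,
    st = match(state, st_lev) - 1L,
    person_id = person_id[ord],
    clusters = cl_lev, districts = di_lev, states = st_lev,
    district_of_cluster = setNames(cd$district[match(cl_lev, cd$cluster)],
                                   cl_lev),
    state_of_district = setNames(ds$state[match(di_lev, ds$district)],
                                 di_lev),
    n = n, J = length(cl_lev), K = length(di_lev), L = length(st_lev)
  ), class = "ml_data")
}

#' @export
print.ml_data <- function(x, ...) {
  cat("Four-level model data:", x$n, "persons in", x$J, "clusters,",
      x$K, "districts,", x$L, "states\n")
  cat("  response mean:", signif(mean(x$y), 4), "\n")
  invisible(x)
}

#' Starting values for the Gibbs sampler
#'
#' The default mode (\code{"empirical"}) places the intercept at the
#' empirical log-odds of the response, all residuals at zero, and all
#' variance components at 0.1 -- an approximate-mode start in the spirit
#' of a quasi-likelihood pass.  Starting values affect only the burn-in,
#' not the stationary distribution.
#'
#' @param data an \code{\link{ml_data}} object.
#' @param init \code{"empirical"}, \code{"zeros"}, or a named list with
#'   elements \code{beta0}, \code{u}, \code{v}, \code{f},
#'   \code{sigma2_u}, \code{sigma2_v}, \code{sigma2_f} (missing elements
#'   fall back to the empirical defaults).
#' @return A named list of starting values.
#' @export
hlogit4_init <- function(data, init = "empirical") {
  stopifnot(inherits(data, "ml_data"))
  base <- list(beta0 = 0, u = rep(0, data$J), v = rep(0, data$K),
               f = rep(0, data$L),
               sigma2_u = 0.1, sigma2_v = 0.1, sigma2_f = 0.1)
  if (is.list(init)) return(modifyList(base, init))
  init <- match.arg(init, c("empirical", "zeros"))
  if (init == "empirical") {
    ybar <- mean(data$y)
    if (ybar == 0 || ybar == 1) {
      clamp <- qlogis(1 / (data$n + 1))
      base$beta0 <- if (ybar == 0) clamp else -clamp
      warning("all responses identical; intercept start clamped to ",
              signif(base$beta0, 4), call. = FALSE)
    } else {
      base$beta0 <- qlogis(ybar)
    }
  }
  base
}

#' Fit a four-level random-intercept Bayesian logistic model
#'
#' Fits \deqn{\mathrm{logit}\, P(y_{ijkl}=1) = \beta_0 + u_{jkl} + v_{kl}
#' + f_l,} with persons \eqn{i} nested in clusters \eqn{j}, districts
#' \eqn{k} and states \eqn{l}, and independent zero-mean normal random
#' intercepts \eqn{u \sim N(0,\sigma^2_u)}, \eqn{v \sim N(0,\sigma^2_v)},
#' \eqn{f \sim N(0,\sigma^2_f)}.  The person-level variation is the
#' standard-logistic residual with fixed variance \eqn{\pi^2/3 \approx
#' 3.29}.
#'
#' Sampling is exact Gibbs via Polya-Gamma data augmentation: one
#' auxiliary \eqn{\omega_i \sim PG(1, \psi_i)} per person makes every
#' full conditional Gaussian (intercept and residual blocks) or
#' inverse-gamma (variance components).  The update order is fixed
#' (\eqn{\omega}, \eqn{\beta_0}, \eqn{u}, \eqn{v}, \eqn{f}, variances) so
#' seeded runs are bit-reproducible.  The intercept carries an improper
#' flat prior; each variance component an Inv-Gamma(\code{prior_a},
#' \code{prior_b}) prior.
#'
#' @param x an \code{\link{ml_data}} object, a formula of the form
#'   \code{status ~ state / district / cluster} (grouping factors listed
#'   from the top level down), or the binary response vector itself.
#' @param ... passed on between methods.
#' @param data a data frame, for the formula method.
#' @param cluster,district,state grouping vectors, for the default method.
#' @param burn_in discarded initial iterations (default 500).
#' @param n_iter monitored iterations after burn-in (default 5000).
#' @param thin keep every \code{thin}-th monitored draw.
#' @param prior_a,prior_b inverse-gamma prior hyperparameters for each
#'   variance component; default \code{c(0.001, 0.001)}, the conventional
#'   diffuse default of multilevel MCMC software.
#' @param init starting values; see \code{\link{hlogit4_init}}.
#' @param seed if non-NULL, \code{set.seed(seed)} is called before
#'   sampling.
#' @param keep_effects keep the full per-iteration draws of the residual
#'   blocks (needed for draw-averaged prediction); posterior means are
#'   always kept.
#'
#' @return An object of class \code{"hlogit4"} with components
#'   \code{draws} (vectors \code{beta0}, \code{sigma2_u}, \code{sigma2_v},
#'   \code{sigma2_f} and, if kept, matrices \code{u}, \code{v}, \code{f}
#'   with one row per retained draw), \code{post_mean}, the
#'   \code{\link{ml_data}} used, and the sampler settings.
#'
#' @seealso \code{\link{predict.hlogit4}} for precision-weighted cluster
#'   probabilities, \code{\link{district_prevalence}},
#'   \code{\link{mcmc_diagnostics}}.
#'
#' @examples
#' sim <- simulate_survey(sim_config(n_states = 3, districts_per_state = 2,
#'                                   clusters_per_district = 4, seed = 7))
#' fit <- hlogit4(status ~ state / district / cluster, data = sim$persons,
#'                burn_in = 50, n_iter = 200, seed = 1)
#' coef(fit)
#' @export
hlogit4 <- function(x, ...) UseMethod("hlogit4")

#' @rdname hlogit4
#' @export
hlogit4.formula <- function(x, data, ...) {
  vars <- all.vars(x)
  if (length(vars) != 4L)
    stop("formula must name the response and three grouping factors, ",
         "e.g. status ~ state / district / cluster", call. = FALSE)
  resp <- data[[vars[1]]]
  md <- ml_data(resp, cluster = data[[vars[4]]], district = data[[vars[3]]],
                state = data[[vars[2]]],
                person_id = if ("person_id" %in% names(data))
                  data[["person_id"]] else seq_along(resp))
  fit <- hlogit4.ml_data(md, ...)
  fit$call <- match.call()
  fit
}

#' @rdname hlogit4
#' @export
hlogit4.default <- function(x, cluster, district, state, ...) {
  md <- ml_data(x, cluster, district, state)
  fit <- hlogit4.ml_data(md, ...)
  fit$call <- match.call()
  fit
}

#' @rdname hlogit4
#' @export
hlogit4.ml_data <- function(x, burn_in = 500, n_iter = 5000, thin = 1,
                            prior_a = 0.001, prior_b = 0.001,
                            init = "empirical", seed = NULL,
                            keep_effects = TRUE, ...) {
  stopifnot(burn_in >= 0, n_iter >= 1, thin >= 1,
            prior_a > 0, prior_b > 0)
  start <- hlogit4_init(x, init)
  if (!is.null(seed)) set.seed(seed)
  raw <- gibbs4_cpp(x$y, x$cl, x$di, x$st, x$J, x$K, x$L,
                    as.integer(burn_in), as.integer(n_iter),
                    as.integer(thin), prior_a, prior_b,
                    start$beta0, start$u, start$v, start$f,
                    start$sigma2_u, start$sigma2_v, start$sigma2_f,
                    isTRUE(keep_effects))
  draws <- list(beta0 = raw$beta0, sigma2_u = raw$sigma2_u,
                sigma2_v = raw$sigma2_v, sigma2_f = raw$sigma2_f)
  if (isTRUE(keep_effects)) {
    draws$u <- raw$u; colnames(draws$u) <- x$clusters
    draws$v <- raw$v; colnames(draws$v) <- x$districts
    draws$f <- raw$f; colnames(draws$f) <- x$states
  }
  structure(list(
    draws = draws,
    post_mean = list(beta0 = mean(raw$beta0),
                     sigma2_u = mean(raw$sigma2_u),
                     sigma2_v = mean(raw$sigma2_v),
                     sigma2_f = mean(raw$sigma2_f),
                     u = setNames(as.numeric(raw$mean_u), x$clusters),
                     v = setNames(as.numeric(raw$mean_v), x$districts),
                     f = setNames(as.numeric(raw$mean_f), x$states)),
    data = x,
    settings = list(burn_in = burn_in, n_iter = n_iter, thin = thin,
                    prior_a = prior_a, prior_b = prior_b, init = init,
                    seed = seed),
    call = match.call()
  ), class = "hlogit4")
}
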