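#' @export
print.hlogit4 <- function(x, ...) {
  cat("Four-level random-intercept logistic model (Polya-Gamma Gibbs)\n")
  d <- x$data
  cat(sprintf("  %d persons | %d clusters | %d districts | %d states\n",
              d$n, d$J, d$K, d$L))
  cat(sprintf("  %d retained draws (burn-in %d, thin %d)\n",
              length(x$draws$beta0), x$settings$burn_in, x$settings$thin))
  cat("Posterior means:\n")
  print(signif(coef(x), 4))
  invisible(x)
}

#' @export
coef.hlogit4 <- function(object, ...) {
  with(object$post_mean,
       c(beta0 = beta0, sigma2_u = sigma2_u, sigma2_v = sigma2_v,
         sigma2_f = sigma2_f))
}

#' Posterior summary of a fitted four-level logistic model
#'
#' @param object a \code{\link{hlogit4}} fit.
#' @param prob central credible-interval mass (default 0.95).
#' @param ... unused.
#' @return A data frame with posterior mean, sd, interval bounds, median,
#'   effective sample size, Monte-Carlo standard error, and split-chain
#'   convergence statistic per scalar parameter.
#' @export
summary.hlogit4 <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  pars <- c("beta0", "sigma2_u", "sigma2_v", "sigma2_f")
  rows <- lapply(pars, function(p) {
    ch <- object$draws[[p]]
    es <- ess(ch)
    data.frame(parameter = p, mean = mean(ch), sd = sd(ch),
               lower = unname(quantile(ch, a)),
               median = unname(quantile(ch, 0.5)),
               upper = unname(quantile(ch, 1 - a)),
               ess = es, mcse = if (is.na(es)) NA_real_ else sd(ch) / sqrt(es),
               rhat = split_rhat(ch))
  })
  out <- do.call(rbind, rows)
  attr(out, "prob") <- prob
  class(out) <- c("summary.hlogit4", "data.frame")
  out
}

#' @export
print.summary.hlogit4 <- function(x, digits = 4, ...) {
  cat(sprintf("Posterior summary (%d%% central intervals)\n",
              round(100 * attr(x, "prob"))))
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Precision-weighted cluster-level predicted probabilities
#'
#' The posterior means of the random intercepts are the precision-weighted
#' (shrunken) residual estimates: each cluster's raw deviation is pulled
#' toward zero in proportion to its sampling imprecision.  The default
#' plug-in prediction is the inverse-logit of the summed posterior means,
#' \eqn{\hat p_{jkl} = \mathrm{logit}^{-1}(\bar\beta_0 + \bar u_{jkl} +
#' \bar v_{kl} + \bar f_l)}; \code{type = "draws"} instead averages the
#' per-draw inverse-logit over the chain (requires
#' \code{keep_effects = TRUE} in the fit).
#'
#' @param object a \code{\link{hlogit4}} fit.
#' @param type \code{"plugin"} (default) or \code{"draws"}.
#' @param ... unused.
#' @return A data frame with one row per cluster: \code{cluster},
#'   \code{district}, \code{state}, \code{prob}, \code{n_persons}.
#' @export
predict.hlogit4 <- function(object, type = c("plugin", "draws"), ...) {
  type <- match.arg(type)
  d <- object$data
  pm <- object$post_mean
  di_of_cl <- d$district_of_cluster            # cluster -> district label
  st_of_cl <- d$state_of_district[di_of_cl]    # cluster -> state label
  if (type == "plugin") {
    eta <- pm$beta0 + pm$u + pm$v[di_of_cl] + pm$f[st_of_cl]
    prob <- plogis(unname(eta))
  } else {
    dr <- object$draws
    if (is.null(dr$u))
      stop("draw-averaged prediction needs keep_effects = TRUE", call. = FALSE)
    eta <- dr$beta0 + dr$u + dr$v[, di_of_cl, drop = FALSE] +
      dr$f[, st_of_cl, drop = FALSE]
    prob <- unname(colMeans(plogis(eta)))
  }
  data.frame(cluster = d$clusters, district = unname(di_of_cl),
             state = unname(st_of_cl), prob = prob,
             n_persons = as.integer(tabulate(d$cl + 1L, d$J)),
             stringsAsFactors = FALSE)
}

#' Posterior-mean (shrunken) residuals
#'
#' @param object a \code{\link{hlogit4}} fit.
#' @param level which residual block to return.
#' @param ... unused.
#' @return Named numeric vector of posterior-mean random intercepts.
#' @export
residuals.hlogit4 <- function(object,
                              level = c("cluster", "district", "state"),
                              ...) {
  level <- match.arg(level)
  switch(level, cluster = object$post_mean$u,
         district = object$post_mean$v, state = object$post_mean$f)
}

#' Trace plots for the scalar parameters
#'
#' @param x a \code{\link{hlogit4}} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.hlogit4 <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lab <- c(beta0 = expression(beta[0]), sigma2_u = expression(sigma[u]^2),
           sigma2_v = expression(sigma[v]^2), sigma2_f = expression(sigma[f]^2))
  for (p in c("beta0", "sigma2_u", "sigma2_v", "sigma2_f")) {
    plot(x$draws[[p]], type = "l", xlab = "iteration", ylab = lab[[p]], ...)
  }
  invisible(x)
}

#' Simulate binary outcomes from the fitted model
#'
#' Each simulation picks one retained posterior draw and generates a
#' Bernoulli outcome per person from its implied probability, i.e. draws
#' from the posterior predictive distribution at the observed nesting.
#'
#' @param object a \code{\link{hlogit4}} fit with \code{keep_effects = TRUE}.
#' @param nsim number of simulated response vectors.
#' @param seed if non-NULL, passed to \code{set.seed}.
#' @param ... unused.
#' @return A data frame with \code{nsim} columns, one row per person (in
#'   canonical \code{person_id} order).
#' @export
simulate.hlogit4 <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dr <- object$draws
  if (is.null(dr$u))
    stop("simulate needs keep_effects = TRUE", call. = FALSE)
  d <- object$data
  ndr <- length(dr$beta0)
  out <- matrix(NA_integer_, d$n, nsim)
  for (s in seq_len(nsim)) {
    i <- sample.int(ndr, 1)
    eta <- dr$beta0[i] + dr$u[i, d$cl + 1L] + dr$v[i, d$di + 1L] +
      dr$f[i, d$st + 1L]
    out[, s] <- rbinom(d$n, 1, plogis(eta))
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
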