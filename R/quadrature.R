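#' Brute-force posterior reference for a single-cluster instance
#'
#' Deterministic numerical-integration reference for the smallest
#' four-level model: one state containing one district containing one
#' cluster with responses \code{y}.  The latent posterior is then
#' four-dimensional, \eqn{(\beta_0, u, v, f)}, and each variance
#' component can be integrated out analytically: under an
#' Inv-Gamma(\eqn{a}, \eqn{b}) prior, the marginal prior of a residual
#' \eqn{e} is proportional to \eqn{(b + e^2/2)^{-(a + 1/2)}} (a scaled
#' Student-t), and \eqn{E[\sigma^2 \mid e] = (b + e^2/2)/(a - 1/2)}.
#'
#' The implementation exploits that the likelihood depends on the latent
#' variables only through \eqn{\psi = \beta_0 + u + v + f}: the prior
#' density of \eqn{s = u + v + f} and the density-weighted second moment
#' of \eqn{u} are built by grid convolution, and the remaining
#' two-dimensional integral over \eqn{(\beta_0, s)} is evaluated on a
#' fine trapezoidal grid.  No Monte Carlo is involved anywhere, so the
#' result is an independent check on the Gibbs sampler.
#'
#' Requires \code{prior_a > 1/2} (otherwise the posterior mean of a
#' variance component does not exist) and a response with both outcome
#' values present (otherwise the flat-prior posterior of \eqn{\beta_0}
#' has an undecaying tail).
#'
#' @param y binary response vector of the single cluster.
#' @param prior_a,prior_b inverse-gamma hyperparameters shared by the
#'   three variance components.
#' @param lim half-range of the residual grids.
#' @param lim_b0 half-range of the intercept grid.
#' @param step grid step.
#' @return List with posterior means \code{beta0}, \code{sigma2_u},
#'   \code{sigma2_v}, \code{sigma2_f} (the last three equal by the
#'   symmetry of the instance) and the underlying moments \code{e_psi},
#'   \code{e_u2}.
#' @export
quad_reference <- function(y, prior_a = 3, prior_b = 2,
                           lim = 10, lim_b0 = 25, step = 0.02) {
  stopifnot(all(y %in% c(0, 1)))
  n <- length(y)
  sy <- sum(y)
  if (sy == 0 || sy == n)
    stop("reference needs both outcome values present", call. = FALSE)
  if (prior_a <= 0.5)
    stop("posterior mean of the variance requires prior_a > 1/2",
         call. = FALSE)

  g <- seq(-lim, lim, by = step)
  pe <- (prior_b + g^2 / 2)^(-(prior_a + 0.5))
  pe <- pe / (sum(pe) * step)

  # grid convolution: density of s = u + v + f, and weighted u^2 moment
  cv <- function(a, b) step * convolve(a, rev(b), type = "open")
  m_s <- cv(cv(pe, pe), pe)                    # on grid [-3 lim, 3 lim]
  h_s <- cv(cv(g^2 * pe, pe), pe)              # int u^2 pe(u)pe(v)pe(s-u-v)
  gs <- seq(-3 * lim, 3 * lim, by = step)
  stopifnot(length(gs) == length(m_s))

  gb <- seq(-lim_b0, lim_b0, by = step)
  # log-likelihood in psi = b0 + s, computed stably
  log_lik <- function(psi) sy * psi - n * ifelse(psi > 30, psi,
                                                 log1p(exp(psi)))
  psi <- outer(gb, gs, "+")
  L <- exp(log_lik(psi))
  WZ <- L * rep(m_s, each = length(gb))
  Z <- sum(WZ)
  e_b0 <- sum(gb * rowSums(WZ)) / Z
  WH <- L * rep(h_s, each = length(gb))
  e_u2 <- sum(WH) / Z
  e_s <- sum(gs * colSums(WZ)) / Z
  e_s2 <- (prior_b + e_u2 / 2) / (prior_a - 0.5)
  list(beta0 = e_b0, sigma2_u = e_s2, sigma2_v = e_s2, sigma2_f = e_s2,
       e_psi = e_b0 + e_s, e_u2 = e_u2)
}
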