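#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-time estimate using Geyer's initial monotone positive
#' sequence: sums sample autocorrelations in adjacent-lag pairs while the
#' pair sums stay positive, enforcing monotone decay, then returns
#' \eqn{n / \tau} with \eqn{\tau = 2\sum_m \Gamma_m - 1}.
#'
#' @param x numeric chain (at least 2 values).
#' @return Effective sample size; \code{NA} for a constant (degenerate)
#'   chain.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 draws", call. = FALSE)
  if (var(x) == 0) return(NA_real_)
  lag_max <- min(n - 1L, max(100L, floor(10 * log10(n) * 10)))
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}, m = 0, 1, ...
  m_max <- floor((length(rho) - 1) / 2)
  gam <- rho[2 * seq_len(m_max + 1) - 1] + rho[2 * seq_len(m_max + 1)]
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1] - 1)]
  if (length(gam) > 1) gam <- cummin(gam)      # enforce monotone decay
  tau <- max(2 * sum(gam) - 1, 1e-8)
  min(n / tau, n * 1.5)                        # cap antithetic chains
}

#' Split-chain convergence statistic
#'
#' Classic potential-scale-reduction factor computed on the two halves of
#' a single chain.  Values near 1 indicate the two halves explore the
#' same distribution.
#'
#' @param x numeric chain (at least 4 values).
#' @return The split-\eqn{\hat R} value; \code{NA} for a constant chain.
#' @export
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  if (var(x) == 0) return(NA_real_)
  half <- floor(n / 2)
  ch <- list(x[seq_len(half)], x[seq.int(n - half + 1, n)])
  m <- length(ch)
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, var, 0)
  W <- mean(vars)
  B <- half * var(means)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' MCMC diagnostics for a fitted model
#'
#' Effective sample size (autocorrelation-time estimate), split-chain
#' convergence statistic, and Monte-Carlo standard error
#' (\eqn{\mathrm{sd}/\sqrt{ESS}}) for each scalar parameter.
#'
#' @param fit a \code{\link{hlogit4}} fit (or a named list of numeric
#'   chains).
#' @return A data frame with one row per parameter and a \code{flag}
#'   column marking degenerate (constant) chains.
#' @export
mcmc_diagnostics <- function(fit) {
  chains <- if (inherits(fit, "hlogit4")) {
    fit$draws[c("beta0", "sigma2_u", "sigma2_v", "sigma2_f")]
  } else {
    stopifnot(is.list(fit), all(vapply(fit, is.numeric, TRUE)))
    fit
  }
  if (any(lengths(chains) < 2L))
    stop("need at least 2 retained draws", call. = FALSE)
  rows <- lapply(names(chains), function(p) {
    ch <- chains[[p]]
    es <- ess(ch)
    data.frame(parameter = p, ess = es,
               mcse = if (is.na(es)) NA_real_ else sd(ch) / sqrt(es),
               rhat = split_rhat(ch),
               flag = if (is.na(es)) "constant" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
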