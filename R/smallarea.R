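# District prevalence from cluster-level predicted probabilities, and
# the distribution summaries behind the box-plot style reporting.

#' District prevalence as the simple average of cluster predictions
#'
#' Each district's prevalence (in percent) is the unweighted mean of its
#' member clusters' predicted probabilities -- clusters count equally
#' regardless of size, so a district's estimate is driven by its
#' cluster-level small-area predictions, not by raw person counts.
#'
#' @param preds cluster predictions: a data frame with columns
#'   \code{cluster}, \code{district}, \code{prob} (and optionally
#'   \code{state}, \code{n_persons}), as returned by
#'   \code{\link{predict.hlogit4}}, possibly after
#'   \code{\link{apply_crosswalk}}.
#' @param wave,sex,outcome optional provenance labels copied onto every
#'   row.
#' @return Data frame with one row per district: \code{district},
#'   \code{prevalence} (percent), \code{n_clusters}, \code{n_persons},
#'   plus any provenance columns.
#' @export
district_prevalence <- function(preds, wave = NULL, sex = NULL,
                                outcome = NULL) {
  stopifnot(is.data.frame(preds),
            all(c("district", "prob") %in% names(preds)))
  if (nrow(preds) == 0L) stop("no cluster predictions", call. = FALSE)
  if (any(!is.finite(preds$prob) | preds$prob <= 0 | preds$prob >= 1))
    stop("cluster probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  agg <- aggregate(prob ~ district, preds, mean)
  ncl <- aggregate(cbind(n_clusters = prob) ~ district, preds, length)
  out <- data.frame(district = agg$district,
                    prevalence = 100 * agg$prob,
                    n_clusters = ncl$n_clusters[match(agg$district,
                                                      ncl$district)],
                    stringsAsFactors = FALSE)
  out$n_persons <- if ("n_persons" %in% names(preds)) {
    np <- aggregate(n_persons ~ district, preds, sum)
    np$n_persons[match(out$district, np$district)]
  } else NA_integer_
  if (!is.null(wave)) out$wave <- wave
  if (!is.null(sex)) out$sex <- sex
  if (!is.null(outcome)) out$outcome <- outcome
  out[order(out$district), , drop = FALSE]
}

#' Summarise a distribution of district prevalences
#'
#' Median, quartiles (linear-interpolation convention, i.e.
#' \code{quantile} type 7 -- stated explicitly because IQR values depend
#' on it), IQR, mean, and box-plot outlier fences at 1.5 x IQR beyond
#' the quartiles.
#'
#' @param x numeric vector of district prevalences (percent), or a
#'   \code{\link{district_prevalence}} data frame.
#' @return List with \code{n}, \code{median}, \code{q25}, \code{q75},
#'   \code{iqr}, \code{mean}, \code{lower_fence}, \code{upper_fence},
#'   \code{n_outliers}.
#' @export
distribution_summary <- function(x) {
  if (is.data.frame(x)) x <- x$prevalence
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) stop("empty or missing input",
                                        call. = FALSE)
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lf <- q[1] - 1.5 * iqr
  uf <- q[3] + 1.5 * iqr
  list(n = length(x), median = q[2], q25 = q[1], q75 = q[3], iqr = iqr,
       mean = mean(x), lower_fence = lf, upper_fence = uf,
       n_outliers = sum(x < lf | x > uf))
}
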