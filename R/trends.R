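# Between-wave comparative analytics: percentage-point change, change
# bands, baseline-by-direction quadrant counts, and cross-outcome
# district correlation.

#' Percentage-point change in district prevalence between waves
#'
#' Districts must already be on a common target frame (see
#' \code{\link{apply_crosswalk}}).  Districts present in only one wave
#' are excluded and recorded in the \code{"dropped"} attribute.
#'
#' @param w1,w2 district estimate data frames with columns
#'   \code{district} and \code{prevalence} (percent).
#' @return Data frame with \code{district}, \code{prev_w1},
#'   \code{prev_w2}, \code{change} (percentage points, wave 2 minus
#'   wave 1) and \code{band} (see \code{\link{band_changes}}).
#' @export
compute_change <- function(w1, w2) {
  stopifnot(all(c("district", "prevalence") %in% names(w1)),
            all(c("district", "prevalence") %in% names(w2)))
  shared <- intersect(w1$district, w2$district)
  if (length(shared) == 0L) stop("no shared districts", call. = FALSE)
  out <- data.frame(district = sort(shared), stringsAsFactors = FALSE)
  out$prev_w1 <- w1$prevalence[match(out$district, w1$district)]
  out$prev_w2 <- w2$prevalence[match(out$district, w2$district)]
  out$change <- out$prev_w2 - out$prev_w1
  out$band <- change_band(out$change)
  dropped <- c(setdiff(w1$district, shared), setdiff(w2$district, shared))
  attr(out, "dropped") <- sort(unique(dropped))
  out
}

#' Band a percentage-point change
#'
#' Stable iff the change lies in [-2.49, 2.49] (inclusive, the printed
#' legend thresholds, deliberately not rounded to 2.5); increase iff
#' above 2.49; decrease iff below -2.49.
#'
#' @param change numeric vector of percentage-point changes.
#' @return Factor with levels \code{decrease}, \code{stable},
#'   \code{increase}.
#' @export
change_band <- function(change) {
  factor(ifelse(change < -2.49, "decrease",
                ifelse(change > 2.49, "increase", "stable")),
         levels = c("decrease", "stable", "increase"))
}

#' Count districts per change band
#'
#' @param changes numeric changes or a \code{\link{compute_change}}
#'   data frame.
#' @return Named integer vector (\code{decrease}, \code{stable},
#'   \code{increase}) summing to the number of districts.
#' @export
band_changes <- function(changes) {
  if (is.data.frame(changes)) changes <- changes$change
  tab <- table(change_band(changes))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Baseline-by-direction quadrant counts
#'
#' Classifies districts by whether their wave-1 prevalence lies above
#' the unweighted mean of wave-1 district prevalences (the
#' district-level average, not the person-weighted prevalence) and
#' whether their prevalence increased or decreased.  Ties are never
#' silently assigned: districts exactly at the baseline mean count as
#' not-above (documented tie rule), and exact-zero changes are tallied
#' separately rather than forced into a direction.
#'
#' @param changes a \code{\link{compute_change}} data frame (columns
#'   \code{prev_w1}, \code{change}).
#' @return List with \code{counts} (2 x 2 integer matrix, rows
#'   above/below baseline, columns increase/decrease),
#'   \code{zero_change} tally, \code{baseline_mean}, and \code{n}.
#' @export
quadrant_analysis <- function(changes) {
  stopifnot(all(c("prev_w1", "change") %in% names(changes)))
  n <- nrow(changes)
  if (n == 0L) stop("no districts", call. = FALSE)
  baseline <- mean(changes$prev_w1)
  above <- changes$prev_w1 > baseline
  inc <- changes$change > 0
  dec <- changes$change < 0
  counts <- matrix(c(sum(above & inc), sum(above & dec),
                     sum(!above & inc), sum(!above & dec)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("above_average", "below_average"),
                                   c("increase", "decrease")))
  list(counts = counts, zero_change = sum(!inc & !dec),
       baseline_mean = baseline, n = n)
}

#' Correlation between two outcomes' district prevalences
#'
#' Pearson (default) or Spearman correlation over the districts shared
#' by the two estimate tables.
#'
#' @param est_a,est_b district estimate data frames (\code{district},
#'   \code{prevalence}).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return List with \code{r}, \code{n}, \code{method}.
#' @export
cross_outcome_correlation <- function(est_a, est_b,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(est_a$district, est_b$district)
  if (length(shared) < 3L)
    stop("need at least 3 shared districts", call. = FALSE)
  a <- est_a$prevalence[match(shared, est_a$district)]
  b <- est_b$prevalence[match(shared, est_b$district)]
  list(r = cor(a, b, method = method), n = length(shared),
       method = method)
}
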