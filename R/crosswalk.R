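# Cluster-to-district crosswalk: reassigning survey clusters to a
# common target district frame so both waves are comparable.  The
# crosswalk is always consumed as a supplied table; it is never derived
# from geography here.

#' Reassign clusters to the target district frame
#'
#' Replaces each cluster's district and state by the target-frame IDs
#' given in the crosswalk.  The cluster count is conserved; a cluster
#' absent from the crosswalk is a hard error naming the offending IDs.
#'
#' @param clusters data frame with a \code{cluster} column (and
#'   optionally \code{district} / \code{state} columns, which are
#'   replaced); typically person records or cluster predictions.
#' @param xwalk crosswalk data frame with columns \code{cluster},
#'   \code{district}, \code{state} and optionally \code{wave}.
#' @param wave if given and the crosswalk has a \code{wave} column,
#'   restrict the lookup to that wave's rows.
#' @return \code{clusters} with target-frame \code{district} and
#'   \code{state}; per-district cluster tallies are attached as
#'   attribute \code{"district_clusters"}.
#' @export
apply_crosswalk <- function(clusters, xwalk, wave = NULL) {
  stopifnot(is.data.frame(clusters), "cluster" %in% names(clusters))
  need <- setdiff(c("cluster", "district", "state"), names(xwalk))
  if (length(need))
    stop("crosswalk lacks columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(wave) && "wave" %in% names(xwalk))
    xwalk <- xwalk[xwalk$wave == wave, , drop = FALSE]
  if (anyDuplicated(xwalk$cluster))
    stop("crosswalk has duplicated cluster keys", call. = FALSE)
  hit <- match(clusters$cluster, xwalk$cluster)
  if (anyNA(hit)) {
    missing_ids <- sort(unique(clusters$cluster[is.na(hit)]))
    stop("clusters absent from crosswalk: ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) " ..." else "", call. = FALSE)
  }
  clusters$district <- xwalk$district[hit]
  clusters$state <- xwalk$state[hit]
  tal <- table(xwalk$district[hit[!duplicated(clusters$cluster)]])
  attr(clusters, "district_clusters") <- tal
  clusters
}

#' Validate a crosswalk table
#'
#' Report-only check: duplicated (wave, cluster) keys, districts mapped
#' to more than one state, and the target-frame district count.
#'
#' @param xwalk crosswalk data frame (columns \code{cluster},
#'   \code{district}, \code{state}, optionally \code{wave}).
#' @return List with \code{n_rows}, \code{district_count},
#'   \code{duplicates} (offending keys), \code{orphan_districts}
#'   (districts with multiple states).
#' @export
validate_crosswalk <- function(xwalk) {
  if (nrow(xwalk) == 0L)
    return(list(n_rows = 0L, district_count = 0L,
                duplicates = character(0), orphan_districts = character(0)))
  key <- if ("wave" %in% names(xwalk))
    paste(xwalk$wave, xwalk$cluster, sep = "/") else xwalk$cluster
  dup <- sort(unique(key[duplicated(key)]))
  ds <- unique(xwalk[c("district", "state")])
  orphan <- sort(unique(ds$district[duplicated(ds$district)]))
  list(n_rows = nrow(xwalk),
       district_count = length(unique(xwalk$district)),
       duplicates = dup, orphan_districts = orphan)
}
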