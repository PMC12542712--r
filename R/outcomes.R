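# Outcome classification from biomarker readings (WHO cutoffs),
# eligibility filtering, and design-based descriptive prevalence.

#' Combine repeated blood-pressure readings
#'
#' Blood pressure is measured three times per participant; the default
#' rule averages the 2nd and 3rd readings (the DHS biomarker convention,
#' which discards the elevated first reading), separately for systolic
#' and diastolic.  Alternatives: mean of all non-missing readings, or
#' the last reading.
#'
#' @param sbp1,sbp2,sbp3,dbp1,dbp2,dbp3 numeric vectors of readings in
#'   mmHg (NA = missing).
#' @param rule \code{"mean23"} (default), \code{"mean_all"}, or
#'   \code{"last"}.
#' @return Data frame with columns \code{sbp}, \code{dbp}; a person
#'   lacking the readings the rule requires gets NA.
#' @export
combine_bp_readings <- function(sbp1, sbp2, sbp3, dbp1, dbp2, dbp3,
                                rule = c("mean23", "mean_all", "last")) {
  rule <- match.arg(rule)
  comb <- function(r1, r2, r3) {
    switch(rule,
           mean23 = (r2 + r3) / 2,               # NA if either missing
           mean_all = {
             m <- rowMeans(cbind(r1, r2, r3), na.rm = TRUE)
             m[is.nan(m)] <- NA_real_
             m
           },
           last = r3)
  }
  data.frame(sbp = comb(sbp1, sbp2, sbp3), dbp = comb(dbp1, dbp2, dbp3))
}

#' Classify hypertension from combined blood pressure
#'
#' WHO definition: systolic >= 140 mmHg and/or diastolic >= 90 mmHg,
#' cutoffs inclusive, identical for all ages and sexes.
#'
#' @param sbp,dbp combined systolic / diastolic values in mmHg.
#' @return Integer 0/1 vector; NA where either input is missing.
#' @export
classify_hypertension <- function(sbp, dbp) {
  out <- as.integer(sbp >= 140 | dbp >= 90)
  out[is.na(sbp) | is.na(dbp)] <- NA_integer_
  out
}

#' Classify diabetes from random blood glucose
#'
#' WHO random-glucose definition: glucose >= 200 mg/dL, cutoff
#' inclusive, identical for all ages and sexes.
#'
#' @param glucose random blood glucose in mg/dL.
#' @return Integer 0/1 vector; NA where the input is missing.
#' @export
classify_diabetes <- function(glucose) {
  as.integer(glucose >= 200)
}

#' Filter persons to the eligible analysis sample
#'
#' Retains persons aged 15-49 (inclusive) whose biomarkers required for
#' the outcome are present: for hypertension, the combined SBP and DBP
#' under the chosen reading rule; for diabetes, the glucose reading.
#' Rows are never altered, only membership.
#'
#' @param persons person-level data frame (see
#'   \code{\link{simulate_individuals}} for the column schema).
#' @param outcome \code{"hypertension"} or \code{"diabetes"}.
#' @param bp_rule reading-combination rule passed to
#'   \code{\link{combine_bp_readings}}.
#' @return List with \code{persons} (retained rows) and
#'   \code{exclusions}, a named integer tally by reason
#'   (\code{age_ineligible}, \code{missing_biomarker}).
#' @export
filter_eligible <- function(persons,
                            outcome = c("hypertension", "diabetes"),
                            bp_rule = "mean23") {
  outcome <- match.arg(outcome)
  n0 <- nrow(persons)
  if (n0 == 0L)
    return(list(persons = persons,
                exclusions = c(age_ineligible = 0L, missing_biomarker = 0L)))
  ok_age <- !is.na(persons$age) & persons$age >= 15 & persons$age <= 49
  kept <- persons[ok_age, , drop = FALSE]
  if (outcome == "hypertension") {
    if ("status" %in% names(kept) && !"sbp1" %in% names(kept)) {
      ok_bio <- !is.na(kept$status)          # pre-classified input
    } else {
      bp <- combine_bp_readings(kept$sbp1, kept$sbp2, kept$sbp3,
                                kept$dbp1, kept$dbp2, kept$dbp3,
                                rule = bp_rule)
      ok_bio <- !is.na(bp$sbp) & !is.na(bp$dbp)
    }
  } else {
    ok_bio <- if ("glucose" %in% names(kept)) !is.na(kept$glucose)
              else !is.na(kept$status)
  }
  list(persons = kept[ok_bio, , drop = FALSE],
       exclusions = c(age_ineligible = sum(!ok_age),
                      missing_biomarker = sum(!ok_bio)))
}

#' Build the person-level outcome table
#'
#' Applies eligibility filtering, reading combination and WHO-cutoff
#' classification in one step, yielding the binary response table the
#' model consumes.  If the input already carries a binary \code{status}
#' column (binary-mode synthetic data), classification is skipped.
#'
#' @inheritParams filter_eligible
#' @return Data frame with IDs, \code{sex}, \code{weight},
#'   \code{outcome} and binary \code{status}; the exclusion tally is
#'   attached as attribute \code{"exclusions"}.
#' @export
build_outcome_table <- function(persons,
                                outcome = c("hypertension", "diabetes"),
                                bp_rule = "mean23") {
  outcome <- match.arg(outcome)
  flt <- filter_eligible(persons, outcome, bp_rule)
  p <- flt$persons
  status <- if (outcome == "hypertension" && "sbp1" %in% names(p)) {
    bp <- combine_bp_readings(p$sbp1, p$sbp2, p$sbp3,
                              p$dbp1, p$dbp2, p$dbp3, rule = bp_rule)
    classify_hypertension(bp$sbp, bp$dbp)
  } else if (outcome == "diabetes" && "glucose" %in% names(p)) {
    classify_diabetes(p$glucose)
  } else if ("status" %in% names(p)) {
    as.integer(p$status)
  } else {
    stop("input carries neither biomarker readings nor a status column",
         call. = FALSE)
  }
  keep <- intersect(c("person_id", "cluster", "district", "state",
                      "sex", "weight", "true_p"), names(p))
  out <- p[keep]
  out$outcome <- outcome
  out$status <- status
  stopifnot(!anyNA(out$status))
  attr(out, "exclusions") <- flt$exclusions
  out
}

#' Design-based weighted prevalence with a cluster-robust interval
#'
#' Point estimate \eqn{100 \sum w_i y_i / \sum w_i} with a 95\%
#' normal-approximation interval whose variance comes from first-stage
#' PSU linearization: the ratio-estimator influence values are summed
#' within clusters and their between-cluster variation estimates the
#' sampling variance.  With fewer than two clusters, persons are treated
#' as PSUs.  Degenerate all-0 or all-1 input returns a zero-width
#' interval at the boundary.
#'
#' @param status binary 0/1 outcomes.
#' @param weight positive sampling weights.
#' @param cluster PSU identifiers.
#' @param conf confidence level (default 0.95).
#' @return Object of class \code{"weighted_prevalence"}: list with
#'   \code{estimate}, \code{ci_low}, \code{ci_high} (percent, clamped to
#'   [0, 100]), \code{se}, \code{n}, \code{n_clusters}.
#' @export
weighted_prevalence <- function(status, weight, cluster, conf = 0.95) {
  n <- length(status)
  if (n == 0L) stop("empty input", call. = FALSE)
  if (length(weight) != n || length(cluster) != n)
    stop("status, weight and cluster must have equal length", call. = FALSE)
  if (anyNA(status) || anyNA(weight) || any(weight <= 0))
    stop("weights must be positive and inputs non-missing", call. = FALSE)
  W <- sum(weight)
  p <- sum(weight * status) / W
  z <- weight * (status - p) / W               # linearized influence
  zc <- tapply(z, cluster, sum)
  m <- length(zc)
  v <- if (m >= 2) m / (m - 1) * sum(zc^2) else {
    if (n >= 2) n / (n - 1) * sum(z^2) else 0
  }
  se <- sqrt(v)
  q <- qnorm(1 - (1 - conf) / 2)
  structure(list(estimate = 100 * p,
                 ci_low = max(0, 100 * (p - q * se)),
                 ci_high = min(100, 100 * (p + q * se)),
                 se = 100 * se, n = n, n_clusters = m, conf = conf),
            class = "weighted_prevalence")
}

#' @export
print.weighted_prevalence <- function(x, digits = 3, ...) {
  cat(sprintf("Weighted prevalence: %s%% (%d%% CI %s to %s), n = %d in %d PSUs\n",
              signif(x$estimate, digits), round(100 * x$conf),
              signif(x$ci_low, digits), signif(x$ci_high, digits),
              x$n, x$n_clusters))
  invisible(x)
}
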