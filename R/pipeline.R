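# End-to-end pipeline: simulate (or read) -> classify -> crosswalk ->
# fit -> estimate -> trends, one independent model fit per
# (outcome x sex x wave) cell, with delimited-table I/O and a manifest.

.required_cols <- c("person_id", "cluster", "district", "state", "age",
                    "sex", "weight")

#' Read / write person-level survey tables
#'
#' Tab-separated tables with one row per person.  Required columns:
#' \code{person_id}, \code{cluster}, \code{district}, \code{state},
#' \code{age}, \code{sex}, \code{weight}, plus either biomarker columns
#' (\code{sbp1..3}, \code{dbp1..3}, \code{glucose}) or a binary
#' \code{status}.  Unknown extra columns are accepted with a warning;
#' missing required columns are an error.  Numeric columns are written
#' with 17 significant digits so a write-read round trip reproduces
#' values exactly.
#'
#' @param path file path.
#' @return \code{read_survey_table}: the person data frame.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.required_cols, names(df))
  if (length(miss))
    stop("survey table lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  known <- c(.required_cols, "sbp1", "sbp2", "sbp3", "dbp1", "dbp2",
             "dbp3", "glucose", "status", "true_p", "wave", "outcome")
  extra <- setdiff(names(df), known)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  df
}

#' @rdname read_survey_table
#' @param table data frame to write.
#' @export
write_survey_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  out[num] <- lapply(out[num], function(x) ifelse(x == "nan", NA, x))
  for (nm in names(out)[num]) out[[nm]][is.na(table[[nm]])] <- NA
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write an estimates table
#'
#' Thin wrapper around \code{write.table} for district estimate /
#' change / count tables (tab-separated, no quoting, full numeric
#' precision via the R default 15 significant digits).
#'
#' @param table data frame.
#' @param path file path.
#' @export
write_estimates <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the generator settings (\code{sim:}), sampler
#' settings (\code{mcmc:}), the \code{outcomes} and \code{sexes} to
#' loop over, the \code{bp_rule}, and the global \code{seed}.
#'
#' @param path YAML file path.
#' @return A pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

# global seed -> per-cell seed, documented derivation: cells are
# enumerated in sorted (sex, outcome) order and spaced by a prime
.cell_seed <- function(seed, cell_index) {
  as.integer((as.numeric(seed) + 7919 * cell_index) %% 2147483647)
}

#' Run the full small-area estimation pipeline on synthetic data
#'
#' For every (outcome x sex) cell: simulate a two-wave survey, classify
#' outcomes per wave, put wave-1 clusters on the target district frame
#' via the generated crosswalk, fit one four-level model per wave,
#' average cluster predictions into district prevalences, and compute
#' the between-wave change, band and quadrant tables.  Each cell uses an
#' independently derived seed, so the run is reproducible cell by cell
#' from the manifest alone.
#'
#' @param config pipeline configuration list (or a YAML path, see
#'   \code{\link{read_pipeline_config}}) with elements \code{sim}
#'   (arguments for \code{\link{sim_config}}), \code{mcmc} (burn_in,
#'   n_iter, thin, prior_a, prior_b), \code{outcomes}, \code{sexes},
#'   \code{bp_rule}, \code{seed}.
#' @param out_dir output directory; created if needed.  All tables are
#'   tab-separated text.
#' @return Invisibly, a list with the per-cell results (district
#'   estimates per wave, change table, band and quadrant counts,
#'   exclusion tallies) and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config))
  outcomes <- config$outcomes %||% "hypertension"
  sexes <- config$sexes %||% "female"
  seed <- config$seed %||% 1L
  bp_rule <- config$bp_rule %||% "mean23"
  mcmc <- modifyList(list(burn_in = 500, n_iter = 5000, thin = 1,
                          prior_a = 0.001, prior_b = 0.001),
                     config$mcmc %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cells <- expand.grid(sex = sort(sexes), outcome = sort(outcomes),
                       stringsAsFactors = FALSE)
  results <- list()
  manifest <- list(package_version = as.character(
                     utils::packageVersion("districtsae")),
                   r_version = as.character(getRversion()),
                   global_seed = seed, bp_rule = bp_rule, mcmc = mcmc,
                   cells = list())

  for (ci in seq_len(nrow(cells))) {
    sx <- cells$sex[ci]; oc <- cells$outcome[ci]
    cell_seed <- .cell_seed(seed, ci)
    sim_args <- modifyList(config$sim %||% list(),
                           list(sex = sx, outcome = oc, seed = cell_seed))
    scfg <- do.call(sim_config, sim_args)
    tw <- simulate_two_waves(scfg)

    cell <- list(sex = sx, outcome = oc, seed = cell_seed)
    est <- list()
    for (wv in 1:2) {
      wave <- if (wv == 1) tw$wave1 else tw$wave2
      tab <- build_outcome_table(wave$persons, outcome = oc,
                                 bp_rule = bp_rule)
      cell[[paste0("exclusions_w", wv)]] <- attr(tab, "exclusions")
      md <- ml_data(tab$status, tab$cluster, tab$district, tab$state,
                    person_id = tab$person_id)
      fit <- hlogit4(md, burn_in = mcmc$burn_in, n_iter = mcmc$n_iter,
                     thin = mcmc$thin, prior_a = mcmc$prior_a,
                     prior_b = mcmc$prior_b, seed = cell_seed + wv,
                     keep_effects = FALSE)
      preds <- predict(fit)
      preds <- apply_crosswalk(preds, tw$crosswalk, wave = wv)
      est[[wv]] <- district_prevalence(preds, wave = wv, sex = sx,
                                       outcome = oc)
      write_estimates(est[[wv]],
                      file.path(out_dir, sprintf("district_%s_%s_w%d.tsv",
                                                 oc, sx, wv)))
    }
    chg <- compute_change(est[[1]], est[[2]])
    write_estimates(chg, file.path(out_dir,
                                   sprintf("change_%s_%s.tsv", oc, sx)))
    qa <- quadrant_analysis(chg)
    bands <- band_changes(chg)
    counts <- data.frame(measure = c(names(bands),
                                     "above_increase", "above_decrease",
                                     "below_increase", "below_decrease",
                                     "zero_change"),
                         count = c(unname(bands), qa$counts[1, 1],
                                   qa$counts[1, 2], qa$counts[2, 1],
                                   qa$counts[2, 2], qa$zero_change))
    write_estimates(counts, file.path(out_dir,
                                      sprintf("counts_%s_%s.tsv", oc, sx)))
    results[[paste(oc, sx, sep = "_")]] <-
      list(estimates = est, change = chg, bands = bands, quadrants = qa,
           exclusions = cell[grep("^exclusions", names(cell))])
    manifest$cells[[paste(oc, sx, sep = "_")]] <- cell
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(results = results, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
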