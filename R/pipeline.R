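# Pipeline orchestration: generate -> measure -> analyze, with a
# reproducible on-disk layout. A thin command-line wrapper around these
# functions ships in inst/cli/octaquant.R.

#' Generate a synthetic cohort on disk
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory for the cohort.
#' @param force overwrite a non-empty directory.
#' @return Invisibly, the [generate_cohort()] result.
#' @export
octa_generate <- function(config = cohort_config(), out_dir, force = FALSE) {
  res <- generate_cohort(config, dir = out_dir, write_images = TRUE,
                         force = force)
  message(sprintf("wrote %d eye bundles to %s", nrow(res$metadata), out_dir))
  invisible(res)
}

#' Measure every eye of a cohort directory
#'
#' Reads `metadata.csv`, runs the per-eye measurement pipeline on every
#' eye bundle, and writes `metrics.csv` (one row per eye). A corrupt or
#' missing eye is recorded as a row-level failure and the run
#' continues.
#'
#' @param cohort_dir directory written by [octa_generate()].
#' @param params a [measure_params()].
#' @param out_csv output CSV path (default `metrics.csv` inside
#'   `cohort_dir`).
#' @return List with `metrics` (data frame) and `failures` (data frame
#'   of eye-level errors, zero rows when clean).
#' @export
octa_measure <- function(cohort_dir, params = measure_params(),
                         out_csv = file.path(cohort_dir, "metrics.csv")) {
  meta_path <- file.path(cohort_dir, "metadata.csv")
  if (!file.exists(meta_path)) abort("no metadata.csv in %s", cohort_dir)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(meta))
  fails <- list()
  for (i in seq_len(nrow(meta))) {
    fs <- strsplit(meta$paths[i], ";", fixed = TRUE)[[1]]
    res <- tryCatch({
      scp <- read_angiogram(file.path(cohort_dir, fs[1]), "SCP")
      dcp <- read_angiogram(file.path(cohort_dir, fs[2]), "DCP")
      cc <- read_angiogram(file.path(cohort_dir, fs[3]), "CC")
      fz_s <- read_faz_annotation(file.path(cohort_dir, fs[4]))
      fz_d <- read_faz_annotation(file.path(cohort_dir, fs[5]))
      bio <- eye_biometry(meta$axial_length_mm[i],
                          camera_factor_p = params$camera_factor_p)
      compute_eye_metrics(scp, dcp, cc, fz_s, fz_d, bio, params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(participant_id = meta$participant_id[i],
                   eye = meta$eye[i], error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- cbind(meta[i, c("participant_id", "eye", "group")], res)
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  failures <- if (length(fails)) do.call(rbind, fails)
  else data.frame(participant_id = character(), eye = character(),
                  error = character(), stringsAsFactors = FALSE)
  if (!is.null(out_csv)) {
    write.csv(metrics, out_csv, row.names = FALSE)
    if (nrow(failures))
      write.csv(failures, sub("\\.csv$", "_failures.csv", out_csv),
                row.names = FALSE)
  }
  if (nrow(failures))
    warning(sprintf("%d eye(s) failed measurement", nrow(failures)))
  list(metrics = metrics, failures = failures)
}

#' Analyze measured metrics against cohort metadata
#'
#' Joins the per-eye metrics with the cohort covariates and builds the
#' five report tables.
#'
#' @param metrics per-eye metrics data frame or CSV path.
#' @param metadata cohort metadata data frame or CSV path.
#' @param out_dir optional directory for CSV/text output.
#' @param outcomes optional subset of outcome columns.
#' @return An `octa_report` (see [build_tables()]).
#' @export
octa_analyze <- function(metrics, metadata, out_dir = NULL,
                         outcomes = NULL) {
  if (is.character(metrics)) metrics <- read.csv(metrics,
                                                 stringsAsFactors = FALSE)
  if (is.character(metadata)) metadata <- read.csv(metadata,
                                                   stringsAsFactors = FALSE)
  need <- c("participant_id", "eye", outcome_names())
  missing <- setdiff(need, names(metrics))
  if (length(missing))
    abort("metrics table is missing columns: %s",
          paste(missing, collapse = ", "))
  metrics <- metrics[, setdiff(names(metrics), "group")]
  tab <- merge(metadata, metrics, by = c("participant_id", "eye"))
  report <- build_tables(tab, outcomes = outcomes)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the full pipeline: generate, measure, analyze
#'
#' @param config a [cohort_config()].
#' @param out_dir working directory (cohort goes to
#'   `<out_dir>/cohort`, report to `<out_dir>/report`).
#' @param params a [measure_params()].
#' @param force overwrite existing output.
#' @return List with `cohort`, `measured`, `report`.
#' @export
octa_run_all <- function(config = cohort_config(), out_dir,
                         params = measure_params(), force = FALSE) {
  cohort <- octa_generate(config, file.path(out_dir, "cohort"),
                          force = force)
  measured <- octa_measure(file.path(out_dir, "cohort"), params)
  report <- octa_analyze(measured$metrics, cohort$metadata,
                         out_dir = file.path(out_dir, "report"))
  list(cohort = cohort, measured = measured, report = report)
}
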