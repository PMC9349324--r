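# Assembly of the five cohort report tables: participant
# characteristics, univariate and covariate-adjusted group comparisons
# of the OCTA outcomes, and univariate associations with disease
# duration and episode count.

outcome_labels <- function() {
  c(rnfl_um = "Peripapillary RNFL thickness (um)",
    pd_scp_pct = "Perfusion density SCP (%)",
    pd_scp_wo_lv_pct = "Perfusion density SCP w/o LV (%)",
    pd_lv_pct = "Perfusion density LV (%)",
    pd_dcp_pct = "Perfusion density DCP (%)",
    faz_area_s_mm2 = "FAZ area, superficial (mm^2)",
    faz_circ_s = "FAZ circularity, superficial",
    faz_area_d_mm2 = "FAZ area, deep (mm^2)",
    faz_circ_d = "FAZ circularity, deep",
    fd_cc_pct = "Flow deficit CC (%)")
}

#' Participant-level characteristics table with group tests
#' @noRd
characteristics_table <- function(table) {
  pl <- table[!duplicated(table$participant_id), ]
  eye_means <- function(col) tapply(table[[col]], table$participant_id, mean)
  pl$iop_mmHg <- as.numeric(eye_means("iop_mmHg")[pl$participant_id])
  pl$axial_length_mm <-
    as.numeric(eye_means("axial_length_mm")[pl$participant_id])
  pl$signal_strength <-
    as.numeric(eye_means("signal_strength")[pl$participant_id])
  has_oct <- "oct_signal_strength" %in% names(table)
  if (has_oct) pl$oct_signal_strength <-
    as.numeric(eye_means("oct_signal_strength")[pl$participant_id])
  vars <- list(
    list("Age (years)", "age", "continuous"),
    list("Gender (male)", "gender", "categorical"),
    list("Axial length (mm)", "axial_length_mm", "continuous"),
    list("IOP (mmHg)", "iop_mmHg", "continuous"),
    list("Hypertension", "hypertension", "categorical"),
    list("Signal strength of OCTA scans", "signal_strength", "continuous"))
  if (has_oct)
    vars <- c(vars, list(list("Signal strength of OCT scans",
                              "oct_signal_strength", "continuous")))
  grp <- factor(pl$group)
  fmt <- function(v, g, type) {
    v <- v[grp == g]
    if (type == "continuous")
      sprintf("%.1f ± %.1f", mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
    else {
      n1 <- if (is.numeric(v)) sum(v == 1) else sum(v == "male")
      sprintf("%d (%.0f%%)", n1, 100 * n1 / length(v))
    }
  }
  rows <- lapply(vars, function(vr) {
    tst <- univariate_characteristic_test(pl[[vr[[2]]]], grp, vr[[3]])
    data.frame(characteristic = vr[[1]],
               control = fmt(pl[[vr[[2]]]], "control", vr[[3]]),
               MS = fmt(pl[[vr[[2]]]], "MS", vr[[3]]),
               p = tst$p, test = tst$test,
               significant = ifelse(tst$p < 0.10, "*", ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-comparison table (unadjusted or adjusted) over all outcomes
#' @noRd
comparison_table <- function(table, outcomes, adjusted) {
  rows <- lapply(outcomes, function(oc) {
    covs <- if (adjusted) select_covariates(table, oc) else character()
    gm <- gee_group_model(table, oc, covs)
    res <- if (adjusted) gm$adjusted else gm$unadjusted
    ctrl <- res[res$group == "control", ]
    ms <- res[res$group == "MS", ]
    data.frame(outcome = oc,
               label = unname(outcome_labels()[oc]),
               control_mean = ctrl$mean, control_se = ctrl$se,
               ms_mean = ms$mean, ms_se = ms$se,
               p = res$p[1],
               covariates = paste(covs, collapse = "+"),
               significant = ifelse(res$p[1] < 0.05, "*", ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Association table for one predictor over all outcomes
#' @noRd
association_table <- function(table, outcomes, predictor) {
  do.call(rbind, lapply(outcomes, function(oc)
    association_model(table, oc, predictor)))
}

#' Build the full cohort report
#'
#' Produces the five standard tables from a per-eye cohort table:
#' participant characteristics with normality-gated tests, univariate
#' (unadjusted GEE) group comparison of the outcomes, covariate-adjusted
#' GEE comparison, and univariate associations of the outcomes with MS
#' duration and episode count (MS eyes only). Characteristics are
#' flagged at P < 0.10 and outcomes at P < 0.05.
#'
#' @param table cohort data frame: one row per eye with
#'   `participant_id`, `eye`, `group`, covariates and the outcome
#'   columns (optionally `rnfl_um`).
#' @param outcomes outcome columns to analyze (default: RNFL if present
#'   plus the nine imaging outcomes).
#' @return List of class `octa_report` with elements `characteristics`,
#'   `univariate`, `multivariate`, `duration`, `episodes`.
#' @export
build_tables <- function(table, outcomes = NULL) {
  need <- c("participant_id", "group")
  if (!all(need %in% names(table)))
    abort("missing columns: %s", paste(setdiff(need, names(table)),
                                       collapse = ", "))
  if (is.null(outcomes)) {
    outcomes <- c(intersect("rnfl_um", names(table)), outcome_names())
  }
  missing <- setdiff(outcomes, names(table))
  if (length(missing))
    abort("missing outcome columns: %s", paste(missing, collapse = ", "))
  if (nlevels(droplevels(factor(table$group))) != 2L)
    abort("two groups are required")
  has_ms <- any(table$group == "MS" & !is.na(table$duration_years))
  structure(list(
    characteristics = characteristics_table(table),
    univariate = comparison_table(table, outcomes, adjusted = FALSE),
    multivariate = comparison_table(table, outcomes, adjusted = TRUE),
    duration = if (has_ms) association_table(table, outcomes,
                                             "duration_years"),
    episodes = if (has_ms) association_table(table, outcomes, "episodes")
  ), class = "octa_report")
}

#' @export
print.octa_report <- function(x, ...) {
  cat("== Participant characteristics ==\n")
  print(round_df(x$characteristics, 4), row.names = FALSE)
  cat("\n== Univariate group comparison (GEE, mean ± SE) ==\n")
  print(round_df(x$univariate[, c("label", "control_mean", "control_se",
                                  "ms_mean", "ms_se", "p", "significant")],
                 3), row.names = FALSE)
  cat("\n== Adjusted group comparison (GEE, mean ± SE) ==\n")
  print(round_df(x$multivariate[, c("label", "control_mean", "control_se",
                                    "ms_mean", "ms_se", "p", "significant")],
                 3), row.names = FALSE)
  if (!is.null(x$duration)) {
    cat("\n== Association with MS duration (per year) ==\n")
    print(round_df(x$duration, 3), row.names = FALSE)
  }
  if (!is.null(x$episodes)) {
    cat("\n== Association with MS episode count ==\n")
    print(round_df(x$episodes, 3), row.names = FALSE)
  }
  invisible(x)
}

#' Write the report tables to CSV and text
#'
#' @param report an `octa_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (is.null(report[[nm]])) next
    write.csv(report[[nm]], file.path(dir, paste0("table_", nm, ".csv")),
              row.names = FALSE)
  }
  txt <- file.path(dir, "report.txt")
  con <- file(txt, open = "wt", encoding = "UTF-8")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
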