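# Cohort-level statistics: normality-gated univariate tests for
# participant characteristics, GEE group comparisons with adjusted
# means, covariate selection, and univariate associations with disease
# duration / episode count.

#' Normality-gated univariate comparison of one characteristic
#'
#' Continuous variables: Shapiro-Wilk on each group at alpha = 0.05
#' decides between the independent t-test (both groups normal) and the
#' Kruskal-Wallis test. Categorical variables: chi-square test,
#' switching to Fisher's exact test when any expected cell count is
#' below 5. Identical constant samples in both groups are degenerate
#' and return P = 1 with a warning.
#'
#' @param values vector of measurements (or categories).
#' @param group two-level grouping vector.
#' @param var_type `"continuous"` or `"categorical"`.
#' @return List with `p`, `test` (name of the test used) and
#'   `statistic`.
#' @export
univariate_characteristic_test <- function(values, group,
                                           var_type = c("continuous",
                                                        "categorical")) {
  var_type <- match.arg(var_type)
  group <- factor(group)
  if (nlevels(group) != 2L) abort("exactly two groups are required")
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- droplevels(group[keep])
  if (nlevels(group) != 2L) abort("exactly two groups are required")
  if (var_type == "categorical") {
    tab <- table(values, group)
    if (nrow(tab) < 2L) {
      warning("categorical variable is constant; returning P = 1")
      return(list(p = 1, test = "degenerate", statistic = NA_real_))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      return(list(p = ft$p.value, test = "fisher", statistic = NA_real_))
    }
    ct <- chisq.test(tab, correct = FALSE)
    return(list(p = ct$p.value, test = "chi-square",
                statistic = unname(ct$statistic)))
  }
  if (any(table(group) < 3L)) abort("need n >= 3 per group")
  if (var(values) == 0) {
    warning("no variation in either group; returning P = 1")
    return(list(p = 1, test = "degenerate", statistic = NA_real_))
  }
  normal <- vapply(levels(group), function(g) {
    v <- values[group == g]
    if (var(v) == 0) return(FALSE)  # constant: not plausibly normal
    shapiro.test(v)$p.value >= 0.05
  }, logical(1))
  if (all(normal)) {
    tt <- t.test(values ~ group, var.equal = TRUE)
    list(p = tt$p.value, test = "t-test", statistic = unname(tt$statistic))
  } else {
    kw <- kruskal.test(values, group)
    list(p = kw$p.value, test = "kruskal-wallis",
         statistic = unname(kw$statistic))
  }
}

#' Prepare a cohort table for modelling
#' @noRd
prep_cohort <- function(table) {
  table$group <- factor(table$group)
  if (all(c("control", "MS") %in% levels(table$group)))
    table$group <- stats::relevel(table$group, "control")
  if (is.character(table$gender)) table$gender <- factor(table$gender)
  table
}

#' GEE group comparison with adjusted means
#'
#' Fits a linear GEE (exchangeable working correlation, clusters =
#' participants) of one outcome on group plus covariates. The group P
#' value is the robust Wald test of the group coefficient. Adjusted
#' group means are marginal predictions with every covariate held at
#' its grand sample mean (categorical covariates at sample
#' proportions); the unadjusted means come from an intercept-plus-group
#' GEE so their SEs are cluster-robust too.
#'
#' @param table cohort data frame (one row per eye) with
#'   `participant_id`, `group`, the outcome and covariates.
#' @param outcome outcome column name.
#' @param covariates character vector of adjustment covariates (may be
#'   empty).
#' @return List of class `group_comparison`: `outcome`, `covariates`,
#'   `unadjusted` and `adjusted` (data frames with per-group
#'   mean/se and the group P value) and the underlying fits.
#' @export
gee_group_model <- function(table, outcome, covariates = character()) {
  table <- prep_cohort(table)
  if (!outcome %in% names(table)) abort("outcome %s not found", outcome)
  if (nlevels(droplevels(table$group)) != 2L)
    abort("two groups are required")
  rhs <- paste(c("group", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fml0 <- stats::as.formula(paste(outcome, "~ group"))
  fit <- gee_fit(fml, table, id = table$participant_id)
  fit0 <- gee_fit(fml0, table, id = table$participant_id)

  group_means <- function(f) {
    X <- stats::model.matrix(stats::delete.response(f$terms),
                             prep_cohort(table), xlev = f$xlevels)
    a_bar <- colMeans(X[, names(f$coefficients), drop = FALSE])
    gcol <- grep("^group", names(f$coefficients), value = TRUE)
    a0 <- a_bar; a0[gcol] <- 0
    a1 <- a_bar; a1[gcol] <- 1
    m0 <- gee_lincom(f, a0); m1 <- gee_lincom(f, a1)
    pg <- summary(f)[gcol, "p"]
    lv <- levels(droplevels(table$group))
    data.frame(group = lv,
               mean = c(m0[["estimate"]], m1[["estimate"]]),
               se = c(m0[["se"]], m1[["se"]]),
               p = pg, row.names = NULL)
  }
  structure(list(outcome = outcome, covariates = covariates,
                 unadjusted = group_means(fit0),
                 adjusted = group_means(fit),
                 fit = fit, fit_unadjusted = fit0),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (adjusted for: %s)\n", x$outcome,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "nothing"))
  cat(" unadjusted:\n"); print(round_df(x$unadjusted, 4))
  cat(" adjusted:\n"); print(round_df(x$adjusted, 4))
  invisible(x)
}

round_df <- function(d, k) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, k)
  d
}

#' Select adjustment covariates
#'
#' Always includes age, gender, hypertension and OCTA signal strength;
#' any further candidate enters when its univariate GEE (outcome on
#' candidate alone, clustered by participant) has P < 0.10.
#'
#' @param table cohort data frame.
#' @param outcome outcome column name.
#' @param candidates candidate covariate names (default IOP and axial
#'   length).
#' @param forced always-included covariates.
#' @param p_enter entry threshold (default 0.10).
#' @return Character vector of covariate names.
#' @export
select_covariates <- function(table, outcome,
                              candidates = c("iop_mmHg", "axial_length_mm"),
                              forced = c("age", "gender", "hypertension",
                                         "signal_strength"),
                              p_enter = 0.10) {
  table <- prep_cohort(table)
  extra <- character()
  for (cand in candidates) {
    fml <- stats::as.formula(paste(outcome, "~", cand))
    f <- gee_fit(fml, table, id = table$participant_id)
    pv <- summary(f)[setdiff(names(coef(f)), "(Intercept)")[1], "p"]
    if (is.finite(pv) && pv < p_enter) extra <- c(extra, cand)
  }
  c(forced, extra)
}

#' Univariate association of an outcome with disease duration/episodes
#'
#' MS eyes only: linear GEE of the outcome on the predictor, clustered
#' by participant, with robust 95% CI.
#'
#' @param table cohort data frame.
#' @param outcome outcome column name.
#' @param predictor `"duration_years"` or `"episodes"`.
#' @return One-row data frame: `outcome`, `predictor`, `beta`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
association_model <- function(table, outcome,
                              predictor = c("duration_years", "episodes")) {
  predictor <- match.arg(predictor)
  table <- prep_cohort(table)
  ms <- table[table$group == "MS" & !is.na(table[[predictor]]), ]
  if (nrow(ms) < 3L) abort("not enough MS eyes")
  if (var(ms[[predictor]]) == 0) abort("predictor %s has zero variance",
                                       predictor)
  fml <- stats::as.formula(paste(outcome, "~", predictor))
  f <- gee_fit(fml, ms, id = ms$participant_id)
  s <- summary(f)[predictor, ]
  data.frame(outcome = outcome, predictor = predictor,
             beta = s$estimate, ci_low = s$ci_low, ci_high = s$ci_high,
             p = s$p, row.names = NULL)
}
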