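# Whole-cohort synthesis: participants, eyes, covariates, ground-truth
# outcome values with inter-eye correlation, and (optionally) the
# rendered per-eye image bundles on disk.

#' Default per-group outcome configuration
#'
#' One row per outcome with the per-group ground-truth mean and SD used
#' by the cohort sampler. `family` controls the sampling distribution:
#' `normal`, `lognormal` (positive, moment-matched), or `shifted_ln`
#' (1 + lognormal, for circularity ratios bounded below by 1).
#'
#' @return Data frame with columns `outcome`, `control_mean`,
#'   `control_sd`, `ms_mean`, `ms_sd`, `family`.
#' @export
default_outcome_config <- function() {
  data.frame(
    outcome = c("pd_scp_pct", "pd_scp_wo_lv_pct", "pd_lv_pct", "pd_dcp_pct",
                "faz_area_s_mm2", "faz_circ_s", "faz_area_d_mm2",
                "faz_circ_d", "fd_cc_pct", "rnfl_um"),
    control_mean = c(41.9, 28.7, 6.70, 41.5, 0.25, 1.12, 1.06, 1.18, 16.4, 95.4),
    control_sd   = c(3.5, 3.5, 0.8, 3.5, 0.115, 0.115, 0.35, 0.115, 1.2, 11.7),
    ms_mean      = c(43.1, 29.8, 6.55, 39.2, 0.25, 1.16, 1.23, 1.27, 16.6, 86.6),
    ms_sd        = c(3.0, 3.0, 0.8, 6.0, 0.10, 0.20, 0.50, 0.20, 2.0, 16.0),
    family = c("normal", "normal", "normal", "normal", "lognormal",
               "shifted_ln", "lognormal", "shifted_ln", "normal", "normal"),
    stringsAsFactors = FALSE
  )
}

#' Default per-group covariate configuration
#' @noRd
default_covariate_config <- function() {
  list(
    control = list(age_mean = 39, age_sd = 11, male_prop = 28 / 78,
                   iop_mean = 15.4, iop_sd = 2.5,
                   axial_mean = 23.3, axial_sd = 0.9,
                   htn_prev = 0.10, ss_octa_mean = 9.5, ss_octa_sd = 0.9,
                   ss_oct_mean = 8.5, ss_oct_sd = 1.0),
    MS = list(age_mean = 41, age_sd = 11, male_prop = 19 / 58,
              iop_mean = 17.3, iop_sd = 2.8,
              axial_mean = 23.2, axial_sd = 0.9,
              htn_prev = 0.15, ss_octa_mean = 9.5, ss_octa_sd = 0.9,
              ss_oct_mean = 8.8, ss_oct_sd = 0.9,
              duration_shape = 2, duration_mean = 8, episodes_rate = 2)
  )
}

#' Cohort generator configuration
#'
#' Defaults reproduce the reference study design: 58 MS participants
#' contributing 100 eyes and 78 controls contributing 136 eyes, with
#' covariate distributions matching the printed cohort characteristics
#' and ground-truth outcome means set to the printed adjusted group
#' means.
#'
#' @param n_ms_participants,n_ms_eyes,n_control_participants,n_control_eyes
#'   cohort sizes; eyes per group cannot exceed twice the participants.
#' @param outcomes outcome configuration as in
#'   [default_outcome_config()].
#' @param covariates per-group covariate distribution list.
#' @param rho inter-eye (within-participant) correlation of outcome
#'   ground truths, in `[0, 1)`.
#' @param master_seed integer master seed; per-eye seeds are spawned by
#'   a documented counter scheme.
#' @param exact_group_means recentre each group's drawn values so the
#'   realized group mean equals the configured mean exactly.
#' @param n_px image side length.
#' @param capillary_scale,noise_sd,n_large_vessels,lv_width_px,granule_scale
#'   image-texture parameters passed to the per-eye generators.
#' @param camera_factor_p Bennett camera factor used for the per-eye
#'   pixel scale.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_ms_participants = 58L, n_ms_eyes = 100L,
                          n_control_participants = 78L,
                          n_control_eyes = 136L,
                          outcomes = default_outcome_config(),
                          covariates = default_covariate_config(),
                          rho = 0.7, master_seed = 20220803L,
                          exact_group_means = TRUE, n_px = 245L,
                          capillary_scale = 5, noise_sd = 10,
                          n_large_vessels = 3L, lv_width_px = 5L,
                          granule_scale = 6, camera_factor_p = 3.382) {
  if (n_ms_eyes > 2L * n_ms_participants ||
      n_control_eyes > 2L * n_control_participants)
    abort("eyes cannot exceed 2 x participants in a group")
  if (n_ms_eyes < n_ms_participants || n_control_eyes < n_control_participants)
    abort("each participant contributes at least one eye")
  assert_number(rho, "rho", 0, 1 - 1e-9)
  need <- c("outcome", "control_mean", "control_sd", "ms_mean", "ms_sd",
            "family")
  if (!all(need %in% names(outcomes))) abort("malformed outcome config")
  structure(list(n_ms_participants = as.integer(n_ms_participants),
                 n_ms_eyes = as.integer(n_ms_eyes),
                 n_control_participants = as.integer(n_control_participants),
                 n_control_eyes = as.integer(n_control_eyes),
                 outcomes = outcomes, covariates = covariates, rho = rho,
                 master_seed = as.integer(master_seed),
                 exact_group_means = exact_group_means,
                 n_px = as.integer(n_px), capillary_scale = capillary_scale,
                 noise_sd = noise_sd,
                 n_large_vessels = as.integer(n_large_vessels),
                 lv_width_px = as.integer(lv_width_px),
                 granule_scale = granule_scale,
                 camera_factor_p = camera_factor_p),
            class = "cohort_config")
}

#' Clustered draws with a participant-level random effect
#'
#' `value = mu + u[participant] + e[eye]` with
#' `var(u) = rho * sd^2`, `var(e) = (1 - rho) * sd^2`.
#' @noRd
draw_clustered <- function(pid_idx, n_participants, mu, sigma, rho) {
  u <- rnorm(n_participants, 0, sqrt(rho) * sigma)
  e <- rnorm(length(pid_idx), 0, sqrt(1 - rho) * sigma)
  mu + u[pid_idx] + e
}

#' Lognormal parameters matching a target mean and SD
#' @noRd
lnorm_match <- function(m, s) {
  sl2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sl2 / 2, sdlog = sqrt(sl2))
}

#' One outcome column for one group
#' @noRd
draw_outcome <- function(pid_idx, n_participants, m, s, rho, family,
                         recentre = TRUE) {
  v <- switch(family,
    normal = draw_clustered(pid_idx, n_participants, m, s, rho),
    lognormal = {
      p <- lnorm_match(m, s)
      exp(draw_clustered(pid_idx, n_participants, p$meanlog, p$sdlog, rho))
    },
    shifted_ln = {
      p <- lnorm_match(m - 1, s)
      1 + exp(draw_clustered(pid_idx, n_participants, p$meanlog, p$sdlog, rho))
    },
    abort("unknown family %s", family))
  if (recentre) {
    if (family == "normal") v <- v - mean(v) + m
    else if (family == "lognormal") v <- v * m / mean(v)
    else v <- 1 + (v - 1) * (m - 1) / mean(v - 1)
  }
  v
}

#' Draw the ground-truth cohort table (no images)
#'
#' Samples participants, eye allocation, covariates and ground-truth
#' outcome values for a whole cohort. This is the statistical skeleton
#' of [generate_cohort()]; it is also used on its own for simulation
#' studies of the cohort statistics.
#'
#' @param config a [cohort_config()].
#' @return Data frame, one row per eye: `participant_id`, `eye`,
#'   `group`, covariates, and the ground-truth outcome columns.
#' @export
draw_cohort_truth <- function(config) {
  withr::with_seed(config$master_seed, {
    per_group <- function(group, n_p, n_eyes, prefix) {
      cov <- config$covariates[[group]]
      # two eyes each, then demote random participants to one eye
      n_single <- 2L * n_p - n_eyes
      single <- sample.int(n_p, n_single)
      n_eyes_p <- rep(2L, n_p); n_eyes_p[single] <- 1L
      pid_idx <- rep(seq_len(n_p), n_eyes_p)
      eye <- unlist(lapply(n_eyes_p, function(k)
        if (k == 2L) c("OD", "OS") else sample(c("OD", "OS"), 1L)),
        use.names = FALSE)
      age <- round(clamp(rnorm(n_p, cov$age_mean, cov$age_sd), 18, 80))
      male <- rbinom(n_p, 1, cov$male_prop)
      htn <- rbinom(n_p, 1, cov$htn_prev)
      axial_p <- clamp(rnorm(n_p, cov$axial_mean, cov$axial_sd), 21.5, 26.5)
      iop_p <- rnorm(n_p, cov$iop_mean, sqrt(0.8) * cov$iop_sd)
      dur <- if (group == "MS")
        round(rgamma(n_p, shape = cov$duration_shape,
                     scale = cov$duration_mean / cov$duration_shape), 1)
      else rep(NA_real_, n_p)
      epi <- if (group == "MS") 1L + rpois(n_p, cov$episodes_rate)
      else rep(NA_integer_, n_p)
      n_rows <- length(pid_idx)
      df <- data.frame(
        participant_id = sprintf("%s%03d", prefix, pid_idx),
        eye = eye,
        group = group,
        age = age[pid_idx],
        gender = ifelse(male[pid_idx] == 1, "male", "female"),
        iop_mmHg = round(clamp(iop_p[pid_idx] +
                                 rnorm(n_rows, 0, sqrt(0.2) * cov$iop_sd),
                               8, 30), 1),
        axial_length_mm = round(clamp(axial_p[pid_idx] +
                                        rnorm(n_rows, 0, 0.15), 21.5, 26.5), 2),
        hypertension = htn[pid_idx],
        signal_strength = as.integer(round(clamp(
          rnorm(n_rows, cov$ss_octa_mean, cov$ss_octa_sd), 6, 10))),
        oct_signal_strength = as.integer(round(clamp(
          rnorm(n_rows, cov$ss_oct_mean, cov$ss_oct_sd), 6, 10))),
        duration_years = dur[pid_idx],
        episodes = epi[pid_idx],
        stringsAsFactors = FALSE
      )
      oc <- config$outcomes
      mcol <- if (group == "MS") "ms_mean" else "control_mean"
      scol <- if (group == "MS") "ms_sd" else "control_sd"
      # plausibility clamps applied BEFORE recentring, so the recentred
      # group mean is exact; the post-recentring safety bounds are wide
      # enough that they essentially never bind
      clamps <- list(fd_cc_pct = c(2, 27), faz_area_s_mm2 = c(0.05, 0.8),
                     faz_area_d_mm2 = c(0.1, 1.7),
                     faz_circ_s = c(1.0005, 1.55),
                     faz_circ_d = c(1.0005, 1.55))
      safety <- list(fd_cc_pct = c(1, 28), faz_area_s_mm2 = c(0.03, 0.9),
                     faz_area_d_mm2 = c(0.05, 1.8),
                     faz_circ_s = c(1.0005, 1.7),
                     faz_circ_d = c(1.0005, 1.7))
      recentre <- function(v, m, fam, bounds = NULL) {
        if (!config$exact_group_means) return(v)
        # alternate recentring and safety clamping to a fixed point so
        # the group mean is exact even when a bound binds
        for (k in 1:25) {
          v <- if (fam == "normal") v - mean(v) + m
          else if (fam == "lognormal") v * m / mean(v)
          else 1 + (v - 1) * (m - 1) / mean(v - 1)
          if (is.null(bounds)) break
          v <- clamp(v, bounds[1], bounds[2])
          if (abs(mean(v) - m) < 1e-9) break
        }
        v
      }
      vals <- list()
      for (i in seq_len(nrow(oc))) {
        nm <- oc$outcome[i]
        if (nm == "pd_scp_pct") next  # derived below
        v <- draw_outcome(pid_idx, n_p, oc[[mcol]][i], oc[[scol]][i],
                          config$rho, oc$family[i], recentre = FALSE)
        if (!is.null(clamps[[nm]])) v <- clamp(v, clamps[[nm]][1],
                                               clamps[[nm]][2])
        vals[[nm]] <- recentre(v, oc[[mcol]][i], oc$family[i],
                               bounds = safety[[nm]])
      }
      # total superficial PD = PD without LV + a perivascular gap term,
      # so both printed rows are realized simultaneously
      i_tot <- match("pd_scp_pct", oc$outcome)
      i_wo <- match("pd_scp_wo_lv_pct", oc$outcome)
      gap_mean <- oc[[mcol]][i_tot] - oc[[mcol]][i_wo]
      gap <- draw_outcome(pid_idx, n_p, gap_mean, 1.0, config$rho, "normal",
                          recentre = FALSE)
      gap <- recentre(clamp(gap, 1, gap_mean + 6), gap_mean, "normal")
      vals$pd_scp_pct <- vals$pd_scp_wo_lv_pct + gap
      cbind(df, as.data.frame(vals)[c(oc$outcome)])
    }
    rbind(per_group("control", config$n_control_participants,
                    config$n_control_eyes, "C"),
          per_group("MS", config$n_ms_participants, config$n_ms_eyes, "P"))
  })
}

#' Generate a full synthetic cohort
#'
#' Draws the ground-truth cohort table and, unless `write_images =
#' FALSE`, renders every eye's image bundle (three slab PNGs, two FAZ
#' annotation JSONs) into `dir`, together with `metadata.csv` (one row
#' per eye with covariates and file paths), `cohort_truth.csv` (the
#' realized ground-truth outcomes) and `manifest.json` (configuration,
#' seed, content hash).
#'
#' @param config a [cohort_config()].
#' @param dir output directory (required when writing images).
#' @param write_images render and write image bundles (default `TRUE`).
#' @param force overwrite an existing non-empty directory.
#' @return List with `metadata`, `truth` (data frames) and `dir`.
#' @export
generate_cohort <- function(config, dir = NULL, write_images = TRUE,
                            force = FALSE) {
  truth <- draw_cohort_truth(config)
  if (!write_images) {
    return(list(metadata = truth[, !(names(truth) %in% outcome_names())],
                truth = truth, dir = NULL))
  }
  if (is.null(dir)) abort("`dir` is required when writing images")
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    abort("output directory %s is not empty (use force = TRUE)", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  n_eyes <- nrow(truth)
  paths <- character(n_eyes)
  realized <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    row <- truth[i, ]
    base_seed <- spawn_seed(config$master_seed, i * 10L)
    bundle <- generate_eye(
      vf_scp = vessel_field_params(
        target_density = row$pd_scp_pct / 100,
        capillary_scale = config$capillary_scale,
        n_large_vessels = config$n_large_vessels,
        lv_width_px = config$lv_width_px, noise_sd = config$noise_sd,
        seed = base_seed + 1L,
        target_density_wo_lv = row$pd_scp_wo_lv_pct / 100),
      vf_dcp = vessel_field_params(
        target_density = row$pd_dcp_pct / 100,
        capillary_scale = config$capillary_scale,
        noise_sd = config$noise_sd, seed = base_seed + 2L),
      faz_s = faz_params(row$faz_area_s_mm2, seed = base_seed + 3L,
                         target_circularity = row$faz_circ_s),
      faz_d = faz_params(row$faz_area_d_mm2, seed = base_seed + 4L,
                         target_circularity = row$faz_circ_d),
      cc = cc_params(deficit_fraction = row$fd_cc_pct / 100,
                     granule_scale = config$granule_scale,
                     seed = base_seed + 5L),
      biometry = eye_biometry(row$axial_length_mm,
                              camera_factor_p = config$camera_factor_p),
      n_px = config$n_px
    )
    stem <- sprintf("%s_%s", row$participant_id, row$eye)
    fs <- c(SCP = sprintf("%s_SCP.png", stem),
            DCP = sprintf("%s_DCP.png", stem),
            CC = sprintf("%s_CC.png", stem),
            FAZ_SCP = sprintf("%s_FAZ_SCP.json", stem),
            FAZ_DCP = sprintf("%s_FAZ_DCP.json", stem))
    write_angiogram(bundle$scp, file.path(dir, fs[["SCP"]]))
    write_angiogram(bundle$dcp, file.path(dir, fs[["DCP"]]))
    write_angiogram(bundle$cc, file.path(dir, fs[["CC"]]))
    write_faz_annotation(bundle$faz_scp, file.path(dir, fs[["FAZ_SCP"]]))
    write_faz_annotation(bundle$faz_dcp, file.path(dir, fs[["FAZ_DCP"]]))
    paths[i] <- paste(fs, collapse = ";")
    realized[[i]] <- bundle$truth
  }
  realized <- do.call(rbind, realized)
  truth[names(realized)] <- realized  # images realize the drawn targets
  meta <- truth[, !(names(truth) %in% outcome_names())]
  meta$paths <- paths
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  write.csv(truth, file.path(dir, "cohort_truth.csv"), row.names = FALSE)
  cfg_json <- jsonlite::serializeJSON(config)
  jsonlite::write_json(
    list(package = "octaquant", master_seed = config$master_seed,
         n_eyes = n_eyes,
         config_hash = unname(tools::md5sum(
           {tf <- tempfile(); writeLines(as.character(cfg_json), tf); tf}))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  list(metadata = meta, truth = truth, dir = dir)
}
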