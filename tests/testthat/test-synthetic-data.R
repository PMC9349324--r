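test_that("capillary bed density is exactly controllable", {
  p0 <- vessel_field_params(0, seed = 1)
  cb0 <- generate_capillary_bed(p0, 128L)
  expect_false(any(cb0$mask))
  p1 <- vessel_field_params(1, seed = 1)
  expect_true(all(generate_capillary_bed(p1, 64L)$mask))
  cb <- generate_capillary_bed(vessel_field_params(0.42, seed = 7), 245L)
  expect_gte(mean(cb$mask), 0.41)
  expect_lte(mean(cb$mask), 0.43)
  expect_gt(mean(cb$image[cb$mask]), mean(cb$image[!cb$mask]))
})

test_that("capillary bed generation is deterministic and validates parameters", {
  p <- vessel_field_params(0.3, seed = 42)
  expect_identical(generate_capillary_bed(p, 96L),
                   generate_capillary_bed(p, 96L))
  expect_error(vessel_field_params(1.2), "target_density")
  expect_error(generate_capillary_bed(vessel_field_params(0.3,
                                                          capillary_scale = 50),
                                      96L), "controllable")
})

test_that("density control holds in a designated region", {
  reg <- matrix(FALSE, 128, 128); reg[30:90, 30:90] <- TRUE
  cb <- generate_capillary_bed(vessel_field_params(0.35, seed = 5), 128L,
                               region = reg)
  expect_equal(sum(cb$mask & reg) / sum(reg), 0.35, tolerance = 1e-3)
})

test_that("generated FAZ matches analytic circle geometry at zero irregularity", {
  sc <- 3.0 / 245
  f <- generate_faz(faz_params(1.0, irregularity = 0), sc)
  expect_equal(faz_area(f, sc), 1.0, tolerance = 1e-3)
  expect_lte(faz_circularity(f), 1.001)
  # analytic radius sqrt(1/pi) = 0.564 mm
  ctr <- colMeans(f$polygon_px)
  radii <- sqrt(rowSums(sweep(f$polygon_px, 2, ctr)^2)) * sc
  expect_equal(mean(radii), sqrt(1 / pi), tolerance = 2e-3)
})

test_that("irregularity raises circularity and target circularity is solved exactly", {
  sc <- 3.0 / 245
  f <- generate_faz(faz_params(1.0, irregularity = 0.3, seed = 3), sc)
  expect_gt(faz_circularity(f), 1.02)
  for (tc in c(1.05, 1.16, 1.27, 1.45)) {
    ft <- generate_faz(faz_params(0.9, seed = 14, target_circularity = tc), sc)
    expect_equal(faz_circularity(ft), tc, tolerance = 1e-3)
  }
  expect_error(generate_faz(faz_params(40), sc), "fit")
})

test_that("synthetic eyes are deterministic with self-consistent ground truth", {
  e1 <- make_test_eye(77L)
  e2 <- make_test_eye(77L)
  expect_identical(e1$scp$pixels, e2$scp$pixels)
  expect_identical(e1$truth, e2$truth)
  # recompute all truths by brute-force counting on emitted masks
  ann <- e1$annulus$mask
  n_ann <- sum(ann)
  halo <- octaquant:::dilate_mask(e1$lv_truth$mask, 8L)
  expect_identical(e1$truth$pd_scp_pct,
                   100 * sum(e1$vessel_scp_truth$mask & ann) / n_ann)
  expect_identical(e1$truth$pd_scp_wo_lv_pct,
                   100 * sum(e1$vessel_scp_truth$mask & !halo & ann) / n_ann)
  expect_identical(e1$truth$pd_lv_pct,
                   100 * sum(e1$lv_truth$mask & ann) / n_ann)
  expect_identical(e1$truth$pd_dcp_pct,
                   100 * sum(e1$vessel_dcp_truth$mask & ann) / n_ann)
  expect_identical(e1$truth$fd_cc_pct,
                   100 * sum(e1$void_truth$mask & ann) / n_ann)
})

test_that("eye-level targets are realized: flow deficit, vessel-free FAZ, LV-free options", {
  eye <- make_test_eye(91L, deficit = 0.16)
  expect_equal(eye$truth$fd_cc_pct, 16, tolerance = 1 / 16)
  fz <- rasterize_faz(eye$faz_scp, 245L)$mask
  expect_false(any(eye$vessel_scp_truth$mask & fz))
  fzd <- rasterize_faz(eye$faz_dcp, 245L)$mask
  expect_false(any(eye$vessel_dcp_truth$mask & fzd))
  eye0 <- make_test_eye(92L, n_large_vessels = 0L)
  expect_false(any(eye0$lv_truth$mask))
  expect_equal(eye0$truth$pd_lv_pct, 0)
})

test_that("cohort truth tables reproduce the configured design", {
  cfg <- cohort_config(master_seed = 123L)
  tr <- draw_cohort_truth(cfg)
  expect_equal(nrow(tr), 236L)
  expect_equal(sum(tr$group == "control"), 136L)
  expect_equal(sum(tr$group == "MS"), 100L)
  expect_equal(length(unique(tr$participant_id[tr$group == "MS"])), 58L)
  expect_equal(length(unique(tr$participant_id[tr$group == "control"])), 78L)
  expect_true(all(table(tr$participant_id) <= 2))
  # determinism
  expect_identical(tr, draw_cohort_truth(cfg))
  # exact group means for the configured outcomes
  oc <- cfg$outcomes
  for (i in seq_len(nrow(oc))) {
    nm <- oc$outcome[i]
    if (nm %in% c("pd_scp_pct", "pd_lv_pct")) next  # composed/realized
    expect_equal(mean(tr[[nm]][tr$group == "MS"]), oc$ms_mean[i],
                 tolerance = 1e-6)
    expect_equal(mean(tr[[nm]][tr$group == "control"]), oc$control_mean[i],
                 tolerance = 1e-6)
  }
  # total superficial PD composes exactly from the without-LV draw + gap
  expect_equal(mean(tr$pd_scp_pct[tr$group == "MS"]),
               oc$ms_mean[oc$outcome == "pd_scp_pct"], tolerance = 1e-6)
})

test_that("forcing two eyes per participant fills every participant", {
  cfg <- cohort_config(n_ms_participants = 10L, n_ms_eyes = 20L,
                       n_control_participants = 8L, n_control_eyes = 16L,
                       master_seed = 5L)
  tr <- draw_cohort_truth(cfg)
  expect_true(all(table(tr$participant_id) == 2))
  expect_error(cohort_config(n_ms_participants = 5L, n_ms_eyes = 11L),
               "2 x participants")
})

test_that("inter-eye correlation of ground truths tracks the configured rho", {
  cfg <- cohort_config(n_ms_participants = 100L, n_ms_eyes = 200L,
                       n_control_participants = 100L,
                       n_control_eyes = 200L, rho = 0.99,
                       master_seed = 31L, exact_group_means = FALSE)
  tr <- draw_cohort_truth(cfg)
  two <- names(which(table(tr$participant_id) == 2))
  pairs <- t(vapply(two, function(p) tr$pd_dcp_pct[tr$participant_id == p],
                    numeric(2)))
  expect_gt(cor(pairs[, 1], pairs[, 2]), 0.9)
  # moderate rho lands within +-0.1
  cfg2 <- cohort_config(n_ms_participants = 100L, n_ms_eyes = 200L,
                        n_control_participants = 100L,
                        n_control_eyes = 200L, rho = 0.5,
                        master_seed = 32L, exact_group_means = FALSE)
  tr2 <- draw_cohort_truth(cfg2)
  pairs2 <- t(vapply(two, function(p)
    tr2$pd_scp_wo_lv_pct[tr2$participant_id == p], numeric(2)))
  expect_lt(abs(cor(pairs2[, 1], pairs2[, 2]) - 0.5), 0.1)
})
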