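ann_nominal <- annulus_mask(245L, annulus_spec(), 3.0 / 245)

test_that("perfusion density covers the saturation cases and symmetry", {
  full <- binary_map(matrix(TRUE, 245, 245), "vessel")
  none <- binary_map(matrix(FALSE, 245, 245), "vessel")
  expect_equal(perfusion_density(full, ann_nominal), 100)
  expect_equal(perfusion_density(none, ann_nominal), 0)
  g <- matrix(rep(0:244, each = 245), 245)  # x coordinate
  half <- binary_map(g < 122, "vessel")     # left half-plane
  expect_equal(perfusion_density(half, ann_nominal), 50, tolerance = 0.5 / 50)
  expect_error(perfusion_density(full, binary_map(matrix(FALSE, 245, 245),
                                                  "annulus")), "empty")
})

test_that("LV removal behaves as identity/zero in the limiting cases", {
  vess <- binary_map(matrix(rep_len(c(TRUE, FALSE), 245^2), 245, 245),
                     "vessel")
  no_lv <- binary_map(matrix(FALSE, 245, 245), "large_vessel")
  all_lv <- binary_map(matrix(TRUE, 245, 245), "large_vessel")
  expect_equal(pd_without_lv(vess, no_lv, ann_nominal),
               perfusion_density(vess, ann_nominal))
  expect_equal(pd_without_lv(vess, all_lv, ann_nominal), 0)
  expect_equal(lv_density(no_lv, ann_nominal), 0)
  expect_equal(lv_density(all_lv, ann_nominal), 100)
})

test_that("densities on toy masks equal brute-force nested-loop counts exactly", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      num <- matrix(runif(256) < 0.4, 16, 16)
      reg <- matrix(runif(256) < 0.7, 16, 16)
      if (!any(reg)) next
      expect_identical(
        perfusion_density(binary_map(num, "vessel"),
                          binary_map(reg, "annulus")),
        brute_density(num, reg))
    }
  })
})

test_that("density monotonicity: more vessel pixels never decrease PD, larger LV never increases PD w/o LV", {
  withr::with_seed(9, {
    v1 <- matrix(runif(245^2) < 0.3, 245, 245)
    v2 <- v1 | (matrix(runif(245^2) < 0.1, 245, 245))
    expect_gte(perfusion_density(binary_map(v2, "vessel"), ann_nominal),
               perfusion_density(binary_map(v1, "vessel"), ann_nominal))
    lv1 <- matrix(runif(245^2) < 0.02, 245, 245)
    lv2 <- lv1 | (matrix(runif(245^2) < 0.02, 245, 245))
    expect_lte(pd_without_lv(binary_map(v2, "vessel"),
                             binary_map(lv2, "large_vessel"), ann_nominal),
               pd_without_lv(binary_map(v2, "vessel"),
                             binary_map(lv1, "large_vessel"), ann_nominal))
  })
})

test_that("FAZ area matches analytic values and scales quadratically", {
  sc <- 3.0 / 245
  r_px <- sqrt(1 / pi) / sc  # 1 mm^2 disc
  circ <- faz_annotation(circle_polygon(c(122, 122), r_px, 360), "SCP")
  expect_equal(faz_area(circ, sc), 1.0, tolerance = 1e-3)
  sq <- faz_annotation(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
                       "SCP")
  expect_equal(faz_area(sq, 0.01), 1.0, tolerance = 1e-12)
  sq2 <- faz_annotation(sq$polygon_px * 2, "SCP")
  expect_equal(faz_area(sq2, 0.01), 4 * faz_area(sq, 0.01))
})

test_that("FAZ circularity matches closed forms and a high-resolution perimeter oracle", {
  circ <- faz_annotation(circle_polygon(c(0, 0), 40, 360), "SCP")
  expect_equal(faz_circularity(circ), 1.0, tolerance = 1e-3)
  sq <- faz_annotation(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), "SCP")
  expect_equal(faz_circularity(sq), 2 / sqrt(pi), tolerance = 1e-12)  # 1.128
  # 2:1 ellipse: oracle = Ramanujan perimeter / (2 sqrt(pi a b))
  th <- seq(0, 2 * pi, length.out = 2049)[-2049]
  a <- 2; b <- 1
  ell <- faz_annotation(cbind(a * cos(th), b * sin(th)), "DCP")
  h <- ((a - b) / (a + b))^2
  p_ramanujan <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  oracle <- p_ramanujan / (2 * sqrt(pi * pi * a * b))
  expect_equal(faz_circularity(ell), oracle, tolerance = 1e-3)
  expect_equal(round(oracle, 2), 1.09)
})

test_that("circularity is invariant under rigid motion and uniform scaling", {
  withr::with_seed(21, {
    base <- generate_faz(faz_params(1.0, irregularity = 0.4, seed = 8),
                         3 / 245)$polygon_px
    c0 <- faz_circularity(faz_annotation(base, "SCP"))
    th <- 0.7
    rot <- base %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    moved <- sweep(rot * 3.7, 2, c(11, -5), "+")
    expect_equal(faz_circularity(faz_annotation(moved, "SCP")), c0,
                 tolerance = 1e-12)
  })
})

test_that("circularity respects the isoperimetric bound on random simple polygons", {
  withr::with_seed(33, {
    for (k in 1:8) {
      f <- generate_faz(faz_params(0.8, irregularity = runif(1, 0, 1),
                                   seed = k), 3 / 245)
      expect_gte(faz_circularity(f), 1 - 0.01)
    }
  })
})

test_that("per-eye metrics recover generator ground truth within stated tolerances", {
  eye <- make_test_eye(11L)
  m <- compute_eye_metrics(eye$scp, eye$dcp, eye$cc, eye$faz_scp,
                           eye$faz_dcp, eye$biometry)
  tr <- eye$truth
  expect_lt(abs(m$pd_scp_pct - tr$pd_scp_pct), 1.5)
  expect_lt(abs(m$pd_scp_wo_lv_pct - tr$pd_scp_wo_lv_pct), 1.5)
  expect_lt(abs(m$pd_dcp_pct - tr$pd_dcp_pct), 1.5)
  expect_lt(abs(m$fd_cc_pct - tr$fd_cc_pct), 1.0)
  expect_lt(abs(m$faz_area_s_mm2 - tr$faz_area_s_mm2) / tr$faz_area_s_mm2,
            0.02)
  expect_lt(abs(m$faz_area_d_mm2 - tr$faz_area_d_mm2) / tr$faz_area_d_mm2,
            0.02)
  expect_lt(abs(m$faz_circ_s - tr$faz_circ_s), 0.02)
  expect_lt(abs(m$faz_circ_d - tr$faz_circ_d), 0.02)
  # determinism
  m2 <- compute_eye_metrics(eye$scp, eye$dcp, eye$cc, eye$faz_scp,
                            eye$faz_dcp, eye$biometry)
  expect_identical(m, m2)
})

test_that("a FAZ reaching into the annulus lowers perfusion density", {
  eye <- make_test_eye(31L)
  m_with <- compute_eye_metrics(eye$scp, eye$dcp, eye$cc, eye$faz_scp,
                                eye$faz_dcp, eye$biometry)
  # replace the deep FAZ by a tiny one: less of the annulus is masked
  tiny <- faz_annotation(circle_polygon(c(122, 122), 8, 90), "DCP")
  dcp_img <- eye$dcp
  m_tiny_faz <- binarize_plexus(dcp_img, rasterize_faz(tiny, 245L))
  pd_tiny <- perfusion_density(m_tiny_faz, eye$annulus)
  expect_gte(pd_tiny, m_with$pd_dcp_pct)
})
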