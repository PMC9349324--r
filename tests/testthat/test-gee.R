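test_that("GEE with singleton clusters reproduces OLS to 1e-8", {
  withr::with_seed(101, {
    n <- 80
    d <- data.frame(y = rnorm(n), x = rnorm(n), id = seq_len(n))
    f <- gee_fit(y ~ x, d, id)
    ols <- lm(y ~ x, d)
    expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 1e-8)
    expect_equal(f$alpha, 0)
  })
})

test_that("GEE matches the statsmodels reference implementation on clustered data", {
  withr::with_seed(42, {
    K <- 60
    id <- rep(seq_len(K), each = 2)
    u <- rnorm(K)[id]
    x1 <- rnorm(2 * K); x2 <- rbinom(2 * K, 1, 0.4)
    y <- 1 + 0.5 * x1 - 0.8 * x2 + u + rnorm(2 * K)
    d <- data.frame(y, x1, x2, id)
  })
  f <- gee_fit(y ~ x1 + x2, d, id)
  csv <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".txt")
  write.csv(d, csv, row.names = FALSE)
  script <- sprintf(
    "import pandas as pd, statsmodels.api as sm\nd = pd.read_csv('%s')\nm = sm.GEE.from_formula('y ~ x1 + x2', groups='id', data=d, cov_struct=sm.cov_struct.Exchangeable())\nr = m.fit()\nopen('%s','w').write(' '.join('%%.10f' %% v for v in list(r.params) + list(r.bse)))\n",
    csv, out)
  status <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  ref <- scan(out, quiet = TRUE)
  expect_equal(unname(coef(f)), ref[1:3], tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov_robust))), ref[4:6], tolerance = 1e-6)
})

test_that("robust SEs exceed naive SEs on positively correlated clusters, on average", {
  withr::with_seed(7, {
    ratio <- replicate(30, {
      K <- 40
      id <- rep(seq_len(K), each = 2)
      grp <- rep(rbinom(K, 1, 0.5), each = 2)
      y <- 5 + 0.5 * grp + rnorm(K, 0, sqrt(0.6))[id] +
        rnorm(2 * K, 0, sqrt(0.4))
      # fit with working independence so the naive SE ignores clustering
      f <- gee_fit(y ~ grp, data.frame(y, grp, id), id,
                   corstr = "independence")
      sqrt(f$vcov_robust[2, 2] / f$vcov_naive[2, 2])
    })
    expect_gt(mean(ratio), 1)
  })
})

test_that("a deterministic linear relation is fitted exactly with vanishing CI", {
  d <- data.frame(x = rep(1:10, each = 2), id = rep(1:10, each = 2))
  d$y <- 2 * d$x
  f <- gee_fit(y ~ x, d, id)
  expect_equal(unname(coef(f)["x"]), 2, tolerance = 1e-10)
  expect_lt(sqrt(f$vcov_robust["x", "x"]), 1e-6)
})

test_that("collinear covariates are rejected with the offending names", {
  d <- data.frame(y = rnorm(20), a = 1:20, id = 1:20)
  d$b <- 2 * d$a
  expect_error(gee_fit(y ~ a + b, d, id), "collinear.*b")
})

test_that("adjusted means equal raw group means without covariates and clustering", {
  withr::with_seed(55, {
    d <- data.frame(participant_id = sprintf("s%02d", 1:40),
                    group = rep(c("control", "MS"), each = 20),
                    y = rnorm(40, 10, 2))
    gm <- gee_group_model(d, "y")
    expect_equal(gm$adjusted$mean[gm$adjusted$group == "control"],
                 mean(d$y[d$group == "control"]), tolerance = 1e-8)
    expect_equal(gm$adjusted$mean[gm$adjusted$group == "MS"],
                 mean(d$y[d$group == "MS"]), tolerance = 1e-8)
    expect_equal(gm$adjusted$mean, gm$unadjusted$mean, tolerance = 1e-8)
  })
})

test_that("group label swap mirrors the comparison without changing P", {
  withr::with_seed(56, {
    d <- data.frame(participant_id = rep(sprintf("s%02d", 1:30), each = 2),
                    group = rep(c("alpha", "beta"), each = 30),
                    y = rnorm(60, 10, 2))
    g1 <- gee_group_model(d, "y")
    d2 <- d; d2$group <- ifelse(d$group == "alpha", "beta", "alpha")
    g2 <- gee_group_model(d2, "y")
    expect_equal(sort(g1$adjusted$mean), sort(g2$adjusted$mean),
                 tolerance = 1e-10)
    expect_equal(g1$adjusted$p[1], g2$adjusted$p[1], tolerance = 1e-10)
  })
})

test_that("parameter recovery: a configured DCP deficit is estimated within 2 SE", {
  cfg <- cohort_config(master_seed = 77L)
  tr <- draw_cohort_truth(cfg)
  tr$group <- factor(tr$group, levels = c("control", "MS"))
  f <- gee_fit(pd_dcp_pct ~ group, tr, participant_id)
  est <- coef(f)[["groupMS"]]
  se <- sqrt(f$vcov_robust["groupMS", "groupMS"])
  expect_lt(abs(est - (39.2 - 41.5)), 2 * se)
})
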