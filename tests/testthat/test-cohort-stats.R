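test_that("normality gate picks the t-test for normal data and Kruskal-Wallis otherwise", {
  withr::with_seed(61, {
    g <- rep(c("a", "b"), each = 60)
    v_norm <- rnorm(120, 10, 2)
    expect_equal(univariate_characteristic_test(v_norm, g)$test, "t-test")
    v_skew <- rexp(120)^2
    expect_equal(univariate_characteristic_test(v_skew, g)$test,
                 "kruskal-wallis")
  })
})

test_that("type-I error of the gated continuous test stays near nominal", {
  withr::with_seed(62, {
    rej <- mean(replicate(500, {
      g <- rep(c("a", "b"), each = 50)
      univariate_characteristic_test(rnorm(100), g)$p < 0.05
    }))
    expect_gte(rej, 0.03); expect_lte(rej, 0.08)
  })
})

test_that("sparse categorical tables switch to Fisher's exact test", {
  vals <- rep(c("x", "y", "x", "y"), c(1, 9, 8, 2))
  g <- rep(c("a", "b"), each = 10)
  res <- univariate_characteristic_test(vals, g, "categorical")
  expect_equal(res$test, "fisher")
  expect_lt(res$p, 0.05)
  # independent oracle: two-sided hypergeometric tail sum
  tab <- table(vals, g)
  probs <- dhyper(0:9, 9, 11, 10)
  p_oracle <- sum(probs[probs <= dhyper(tab["x", "a"], 9, 11, 10) + 1e-12])
  expect_equal(res$p, p_oracle, tolerance = 1e-9)
})

test_that("degenerate constant samples return P = 1 with a warning", {
  g <- rep(c("a", "b"), each = 5)
  expect_warning(res <- univariate_characteristic_test(rep(3, 10), g),
                 "no variation")
  expect_equal(res$p, 1)
  expect_warning(res2 <- univariate_characteristic_test(rep(0, 10), g,
                                                        "categorical"),
                 "constant")
  expect_equal(res2$p, 1)
  expect_error(univariate_characteristic_test(rnorm(5), rep("a", 5)),
               "two groups")
})

test_that("covariate selection keeps the forced set and screens candidates at P < 0.10", {
  withr::with_seed(63, {
    n <- 120
    d <- data.frame(participant_id = rep(sprintf("s%03d", 1:60), each = 2),
                    group = rep(c("control", "MS"), each = 60),
                    age = rnorm(n, 40, 10), gender = sample(c("m", "f"), n, TRUE),
                    hypertension = rbinom(n, 1, 0.2),
                    signal_strength = sample(7:10, n, TRUE))
    d$strong <- rnorm(n)
    d$y <- 5 + 3 * d$strong + rnorm(n)
    sel <- select_covariates(d, "y", candidates = "strong")
    expect_true("strong" %in% sel)
    expect_identical(select_covariates(d, "y", candidates = character()),
                     c("age", "gender", "hypertension", "signal_strength"))
  })
})

test_that("a pure-noise candidate enters at roughly the 10% screening rate", {
  withr::with_seed(64, {
    hits <- mean(replicate(200, {
      n <- 80
      d <- data.frame(participant_id = sprintf("s%03d", 1:n),
                      group = "MS", noise = rnorm(n), y = rnorm(n))
      "noise" %in% select_covariates(d, "y", candidates = "noise",
                                     forced = character())
    }))
    expect_gte(hits, 0.05); expect_lte(hits, 0.15)
  })
})

test_that("association models recover deterministic slopes and reject degenerate predictors", {
  d <- data.frame(participant_id = rep(sprintf("p%02d", 1:20), each = 2),
                  group = "MS", duration_years = rep(seq(1, 20), each = 2))
  d$episodes <- 3L
  d$y <- 2 * d$duration_years
  res <- association_model(d, "y", "duration_years")
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_lt(res$ci_high - res$ci_low, 1e-6)
  expect_error(association_model(d, "y", "episodes"), "zero variance")
})

test_that("association slope sign is recovered under noise at cohort scale", {
  withr::with_seed(65, {
    signs <- replicate(100, {
      K <- 58
      id <- rep(sprintf("p%02d", 1:K), each = 2)
      dur <- rep(rgamma(K, 2, scale = 4), each = 2)
      y <- 40 + 0.5 * dur + rnorm(K, 0, 2)[rep(1:K, each = 2)] +
        rnorm(2 * K, 0, 2)
      d <- data.frame(participant_id = id, group = "MS",
                      duration_years = dur, y = y)
      sign(association_model(d, "y", "duration_years")$beta)
    })
    expect_gte(mean(signs == 1), 0.95)
  })
})

test_that("report tables carry the expected rows and are deterministic", {
  cfg <- cohort_config(n_ms_participants = 12L, n_ms_eyes = 20L,
                       n_control_participants = 12L, n_control_eyes = 20L,
                       master_seed = 99L)
  tr <- draw_cohort_truth(cfg)
  rep1 <- build_tables(tr)
  expect_s3_class(rep1, "octa_report")
  expect_equal(nrow(rep1$univariate), 10L)  # 9 OCTA outcomes + RNFL row
  expect_true("rnfl_um" %in% rep1$univariate$outcome)
  expect_equal(nrow(rep1$duration), 10L)
  rep2 <- build_tables(tr)
  expect_identical(rep1$multivariate, rep2$multivariate)
  expect_error(build_tables(tr[, setdiff(names(tr), "fd_cc_pct")]),
               "missing outcome")
  expect_error(build_tables(tr[tr$group == "MS", ]), "two groups")
})

test_that("swapping group labels swaps columns but not P values", {
  cfg <- cohort_config(n_ms_participants = 12L, n_ms_eyes = 20L,
                       n_control_participants = 12L, n_control_eyes = 20L,
                       master_seed = 98L)
  tr <- draw_cohort_truth(cfg)
  g1 <- gee_group_model(tr, "pd_dcp_pct")
  tr2 <- tr
  tr2$group <- ifelse(tr$group == "MS", "control", "MS")
  g2 <- gee_group_model(tr2, "pd_dcp_pct")
  expect_equal(g1$adjusted$mean[g1$adjusted$group == "MS"],
               g2$adjusted$mean[g2$adjusted$group == "control"],
               tolerance = 1e-10)
  expect_equal(g1$adjusted$p[1], g2$adjusted$p[1], tolerance = 1e-10)
})
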