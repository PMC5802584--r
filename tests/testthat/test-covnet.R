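make_cohort_from_matrix <- function(x) {
  structure(data.frame(
    subject_id = paste0("s", seq_len(2 * nrow(x))),
    group = factor(rep(c("patient", "control"), each = nrow(x)),
                   levels = c("control", "patient")),
    rbind(x, x), check.names = FALSE),
    regions = region_set(colnames(x)), class = c("cohort_table", "data.frame"))
}

test_that("correlation matrices match a brute-force computation", {
  set.seed(31)
  x <- matrix(rnorm(14 * 36, 1.8, 0.2), 14, 36,
              dimnames = list(NULL, default_regions()$names))
  coh <- make_cohort_from_matrix(x)
  m <- corr_matrix(coh, "patient")
  expect_equal(m$r, brute_corr(x), tolerance = 1e-12)
  expect_equal(diag(m$r), rep(1, 36), ignore_attr = TRUE)
  expect_equal(m$n, 14L)
  expect_true(isSymmetric(m$r))
})

test_that("degenerate columns give r = +/-1 or an informative error", {
  set.seed(32)
  x <- cbind(a = rnorm(10, 2, 0.2))
  x <- cbind(x, dup = x[, "a"], anti = 5 - x[, "a"])
  coh <- make_cohort_from_matrix(x)
  m <- corr_matrix(coh, "control")
  expect_equal(m$r["a", "dup"], 1, tolerance = 1e-12)
  expect_equal(m$r["a", "anti"], -1, tolerance = 1e-12)
  x0 <- cbind(x, flat = rep(2, 10))
  expect_error(corr_matrix(make_cohort_from_matrix(x0), "control"),
               "zero-variance.*flat")
  expect_error(corr_matrix(make_cohort_from_matrix(x)[1:3, ], "patient"),
               ">= 4 subjects")
})

test_that("Fisher z is the odd, increasing atanh with boundary clamping", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-15)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-15)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))
  expect_error(fisher_z(1.01), "<= 1")
})

test_that("pair z test matches the independent-correlations formula", {
  zt <- pair_z_test(0.3, 14, 0.9, 14)
  expect_equal(zt$stat, (atanh(0.3) - atanh(0.9)) / sqrt(2 / 11),
               tolerance = 1e-12)
  expect_equal(zt$stat, -2.726773, tolerance = 1e-6)
  # antisymmetry under group swap; null gives stat 0, p 1
  set.seed(33)
  for (i in 1:25) {
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    a <- pair_z_test(r1, n1, r2, n2); b <- pair_z_test(r2, n2, r1, n1)
    expect_equal(a$stat, -b$stat, tolerance = 1e-12)
    # brute-force oracle: direct high-precision evaluation
    se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    z_ref <- (0.5 * log((1 + r1) / (1 - r1)) - 0.5 * log((1 + r2) / (1 - r2))) / se
    expect_equal(a$stat, z_ref, tolerance = 1e-12)
    expect_equal(a$p, 2 * pnorm(-abs(z_ref)), tolerance = 1e-12)
  }
  same <- pair_z_test(0.4, 20, 0.4, 15)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
  expect_error(pair_z_test(0.5, 3, 0.5, 14), "exceed 3")
  # one-tailed orientation: greater = first correlation larger
  expect_lt(pair_z_test(0.9, 14, 0.3, 14, tail = "greater")$p, 0.05)
  expect_gt(pair_z_test(0.9, 14, 0.3, 14, tail = "less")$p, 0.95)
})

test_that("per-pair comparison table has the pair structure and flags", {
  coh <- generate_cohort(make_default_config(), seed = 34, clinical = FALSE)
  m_ctl <- corr_matrix(coh, "control")
  m_pat <- corr_matrix(coh, "patient")
  pc <- compare_all_pairs(m_ctl, m_pat)
  expect_equal(nrow(pc), 630L)
  expect_identical(pc[, c("region_a", "region_b")],
                   unique_pairs(default_regions()),
                   ignore_attr = TRUE)
  expect_true(all(pc$p_one_tailed >= 0 & pc$p_one_tailed <= 1))
  # identical matrices: no flags, stat identically zero
  pc0 <- compare_all_pairs(m_ctl, m_ctl)
  expect_false(any(pc0$flagged))
  expect_true(all(pc0$stat == 0))
  # mismatched region order errors
  m_swap <- m_pat
  m_swap$regions <- rev(m_swap$regions)
  expect_error(compare_all_pairs(m_ctl, m_swap), "region order mismatch")
})

test_that("injected patient couplings dominate the pair ranking across seeds", {
  cfg <- make_default_config()
  cp <- cfg$couplings[cfg$couplings$group == "patient", ]
  injected <- paste(cp$region_a, cp$region_b)
  top_hit <- logical(30)
  for (s in seq_len(30)) {
    coh <- generate_cohort(cfg, seed = 400 + s, clinical = FALSE)
    pc <- compare_all_pairs(corr_matrix(coh, "control"),
                            corr_matrix(coh, "patient"))
    best <- pc[which.min(pc$p_one_tailed), ]
    top_hit[s] <- paste(best$region_a, best$region_b) %in% injected
  }
  expect_gt(mean(top_hit), 0.5)
})

test_that("global comparison is a Welch test over the unique correlations", {
  coh <- generate_cohort(make_default_config(), seed = 35, clinical = FALSE)
  m_ctl <- corr_matrix(coh, "control")
  m_pat <- corr_matrix(coh, "patient")
  g <- global_comparison(m_ctl, m_pat)
  expect_equal(g$n_pairs, 630L)
  expect_lte(g$df, 1258)
  ref <- welch_test(atanh(m_ctl$r[upper.tri(m_ctl$r)]),
                    atanh(m_pat$r[upper.tri(m_pat$r)]))
  expect_equal(g$t, ref$t, tolerance = 1e-12)
  g0 <- global_comparison(m_ctl, m_ctl)
  expect_equal(g0$t, 0)
  # uniformly higher patient correlations -> negative t (controls - patients)
  cfg_lo <- make_default_config(n_patients = 200L, n_controls = 200L,
                                base_corr = 0.4)
  cfg_hi <- make_default_config(n_patients = 200L, n_controls = 200L,
                                base_corr = 0.7)
  cfg_lo$couplings <- cfg_lo$couplings[0, ]
  cfg_hi$couplings <- cfg_hi$couplings[0, ]
  m_lo <- corr_matrix(generate_cohort(cfg_lo, seed = 36, clinical = FALSE),
                      "control")
  m_hi <- corr_matrix(generate_cohort(cfg_hi, seed = 37, clinical = FALSE),
                      "patient")
  expect_lt(global_comparison(m_lo, m_hi)$t, 0)
  expect_lt(global_comparison(m_lo, m_hi, "raw_r")$t, 0)
})

test_that("z-transformed and raw global tests agree in sign on moderate data", {
  for (s in 1:15) {
    cfg_a <- make_default_config(n_patients = 30L, n_controls = 30L,
                                 base_corr = 0.4)
    cfg_b <- make_default_config(n_patients = 30L, n_controls = 30L,
                                 base_corr = 0.55)
    cfg_a$couplings <- cfg_a$couplings[0, ]
    cfg_b$couplings <- cfg_b$couplings[0, ]
    m_ctl <- corr_matrix(generate_cohort(cfg_a, seed = 500 + s,
                                         clinical = FALSE), "control")
    m_pat <- corr_matrix(generate_cohort(cfg_b, seed = 600 + s,
                                         clinical = FALSE), "patient")
    tz <- global_comparison(m_ctl, m_pat, "fisher_z")$t
    tr <- global_comparison(m_ctl, m_pat, "raw_r")$t
    expect_identical(sign(tz), sign(tr))
  }
})

test_that("difference map is the antisymmetric controls-minus-patients map", {
  coh <- generate_cohort(make_default_config(n_patients = 2000L,
                                             n_controls = 2000L),
                         seed = 38, clinical = FALSE)
  m_ctl <- corr_matrix(coh, "control")
  m_pat <- corr_matrix(coh, "patient")
  d <- difference_map(m_ctl, m_pat)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 36), ignore_attr = TRUE)
  expect_equal(d, -difference_map(m_pat, m_ctl), tolerance = 1e-15)
  expect_equal(difference_map(m_ctl, m_ctl),
               matrix(0, 36, 36, dimnames = dimnames(d)), tolerance = 1e-15)
  # injected patient-only coupling shows as strongly negative entries
  expect_lt(d["anterior_cingulate_gyrus", "middle_orbitofrontal_cortex"], -0.5)
  expect_lt(d["anterior_cingulate_gyrus", "straight_gyrus"], -0.5)
})
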