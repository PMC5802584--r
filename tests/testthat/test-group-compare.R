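test_that("Welch test reproduces printed summary-table comparisons", {
  bdi <- welch_test(list(mean = 3.5, sd = 3.2, n = 14),
                    list(mean = 1.1, sd = 1.7, n = 14))
  expect_equal(round(bdi$t, 1), 2.5)
  bai <- welch_test(list(mean = 2.1, sd = 1.9, n = 14),
                    list(mean = 0.9, sd = 1.9, n = 14))
  expect_equal(round(bai$t, 1), 1.7)
  expect_equal(bai$df, 26)  # equal variances, equal n -> n1 + n2 - 2
  amy <- welch_test(list(mean = 1.91, sd = 0.20, n = 14),
                    list(mean = 1.69, sd = 0.14, n = 14))
  expect_equal(amy$t, 3.371813684, tolerance = 1e-8)
})

test_that("Welch test matches stats::t.test on random instances", {
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.2, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1), sd = runif(1, 0.2, 3))
    w <- welch_test(x, y)
    r <- t.test(x, y)
    expect_equal(w$t, unname(r$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(r$parameter), tolerance = 1e-9)
    expect_equal(w$p, r$p.value, tolerance = 1e-9)
  }
})

test_that("Welch test invariants: symmetry, summary equivalence, df bounds", {
  set.seed(102)
  for (i in 1:25) {
    x <- rnorm(sample(4:20, 1)); y <- rnorm(sample(4:20, 1))
    a <- welch_test(x, y); b <- welch_test(y, x)
    expect_equal(a$t, -b$t)
    s <- welch_test(list(mean = mean(x), sd = sd(x), n = length(x)),
                    list(mean = mean(y), sd = sd(y), n = length(y)))
    expect_identical(a$t, s$t)
    expect_identical(a$df, s$df)
    expect_lte(a$df, length(x) + length(y) - 2)
    expect_gte(a$df, min(length(x), length(y)) - 1)
  }
  x <- rnorm(10)
  ident <- welch_test(x, x)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(welch_test(rep(1, 5), rep(2, 5)), "degenerate")
  # one-tailed orientation
  expect_lt(welch_test(list(mean = 2, sd = 1, n = 10),
                       list(mean = 0, sd = 1, n = 10), tail = "greater")$p, 0.05)
})

test_that("one-way region comparison equals the squared pooled t", {
  set.seed(103)
  rs <- region_set(c("a", "b"))
  for (i in 1:20) {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    coh <- structure(data.frame(
      subject_id = paste0("s", seq_len(n1 + n2)),
      group = factor(rep(c("patient", "control"), c(n1, n2)),
                     levels = c("control", "patient")),
      a = rnorm(n1 + n2, 1.8, 0.2), b = rnorm(n1 + n2, 1.8, 0.2)),
      regions = rs, class = c("cohort_table", "data.frame"))
    rc <- ancova_region(coh, "a")
    t2 <- pooled_t(coh$a[coh$group == "patient"],
                   coh$a[coh$group == "control"])^2
    expect_equal(rc$f, t2, tolerance = 1e-10)
    expect_equal(rc$df_den, n1 + n2 - 2)
    # effect size invariant to affine rescaling of the DVR
    coh2 <- coh; coh2$a <- 3.2 * coh2$a - 5
    expect_equal(ancova_region(coh2, "a")$partial_eta_sq, rc$partial_eta_sq,
                 tolerance = 1e-10)
  }
})

test_that("identical group values give F = 0 and zero effect size", {
  rs <- region_set(c("a", "b"))
  v <- c(1.5, 1.8, 2.1, 1.9)
  coh <- structure(data.frame(
    subject_id = paste0("s", 1:8),
    group = factor(rep(c("patient", "control"), each = 4),
                   levels = c("control", "patient")),
    a = c(v, v), b = rnorm(8, 1.8, 0.1)),
    regions = rs, class = c("cohort_table", "data.frame"))
  rc <- ancova_region(coh, "a")
  expect_equal(rc$f, 0)
  expect_equal(rc$partial_eta_sq, 0)
})

test_that("covariate-adjusted model detects collinearity and adjusts the F", {
  coh <- generate_cohort(make_default_config(), seed = 21)
  adj <- ancova_region(coh, "amygdala", covariates = c("BDI", "BAI"))
  una <- ancova_region(coh, "amygdala")
  expect_true(adj$adjusted && !una$adjusted)
  expect_equal(adj$df_den, 24L)
  expect_equal(una$df_den, 26L)
  coh$BDI_copy <- coh$BDI
  expect_error(ancova_region(coh, "amygdala", c("BDI", "BDI_copy")),
               "rank-deficient")
})

test_that("amygdala group effect is significant, patients above controls", {
  coh <- generate_cohort(make_default_config(n_patients = 500L,
                                             n_controls = 500L), seed = 22)
  rc <- ancova_region(coh, "amygdala")
  expect_lt(rc$p, 0.005)
  expect_gt(rc$patient$mean, rc$control$mean)
})

test_that("whole-table comparison covers every region in order", {
  coh <- generate_cohort(make_default_config(n_patients = 10000L,
                                             n_controls = 10000L),
                         seed = 23, clinical = FALSE)
  tbl <- compare_all_regions(coh)
  expect_identical(tbl$region, default_regions()$names)
  temporal <- c("hippocampus", "amygdala", "anterior_temporal_lobe_medial",
                "anterior_temporal_lobe_lateral", "parahippocampal_ambient_gyri",
                "superior_temporal_gyrus_posterior",
                "middle_inferior_temporal_gyrus", "fusiform_gyrus",
                "posterior_temporal_lobe", "superior_temporal_gyrus_anterior")
  sub <- tbl[tbl$region %in% temporal, ]
  expect_true(all(sub$mean_pat > sub$mean_ctl))
  # single-region cohort -> single row
  rs1 <- region_set("amygdala")
  both <- c(which(coh$group == "patient")[1:20],
            which(coh$group == "control")[1:20])
  coh1 <- structure(coh[both, c("subject_id", "group", "amygdala")],
                    regions = rs1, class = c("cohort_table", "data.frame"))
  expect_equal(nrow(compare_all_regions(coh1)), 1L)
})

test_that("permuted labels give a nominal 5% false-positive rate", {
  coh <- generate_cohort(make_default_config(), seed = 24, clinical = FALSE)
  set.seed(24)
  frac <- replicate(100, {
    perm <- coh
    perm$group <- sample(perm$group)
    mean(compare_all_regions(perm)$p_unadj < 0.05)
  })
  expect_gt(mean(frac), 0.015)
  expect_lt(mean(frac), 0.095)
})

test_that("multivariate front-end collapses, errors and behaves under the null", {
  # singular at 36 DVs with 28 subjects
  coh <- generate_cohort(make_default_config(), seed = 25, clinical = FALSE)
  expect_error(mancova(coh), "singular multivariate design")
  # 1 region: multivariate statistics collapse to the univariate F
  rs1 <- region_set("amygdala")
  coh1 <- structure(coh[, c("subject_id", "group", "amygdala")],
                    regions = rs1, class = c("cohort_table", "data.frame"))
  mv <- mancova(coh1)
  expect_equal(mv$wilks$f, ancova_region(coh1, "amygdala")$f, tolerance = 1e-10)
  # null 3-region design at n = 200: Pillai p roughly uniform over repetitions
  cfg <- make_default_config(n_patients = 100L, n_controls = 100L,
                             regions = region_set(c("a1", "a2", "a3")))
  cfg$region_params$mean_patient <- cfg$region_params$mean_control
  cfg$region_params$sd_patient <- cfg$region_params$sd_control
  set.seed(26)
  ps <- replicate(60, mancova(generate_cohort(cfg, seed = NULL,
                                              clinical = FALSE))$pillai$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("normality screen flags skew and marks degenerate cells", {
  rs <- region_set(c("skewed", "normal"))
  set.seed(27)
  n <- 14
  coh <- structure(data.frame(
    subject_id = paste0("s", 1:(2 * n)),
    group = factor(rep(c("patient", "control"), each = n),
                   levels = c("control", "patient")),
    skewed = exp(rnorm(2 * n, 0, 1.5)), normal = rnorm(2 * n, 1.8, 0.15)),
    regions = rs, class = c("cohort_table", "data.frame"))
  scr <- normality_screen(coh)
  expect_true(all(scr$flagged[scr$region == "skewed"]))
  coh$normal <- 1.8
  scr2 <- normality_screen(coh)
  expect_true(all(scr2$indeterminate[scr2$region == "normal"]))
  expect_false(any(scr2$flagged[scr2$region == "normal"]))
  # under normal generation, about 5% of cells flag
  set.seed(28)
  rates <- replicate(20, {
    coh <- generate_cohort(make_default_config(), seed = NULL, clinical = FALSE)
    mean(normality_screen(coh)$flagged)
  })
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.12)
})
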