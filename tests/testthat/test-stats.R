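test_that("normality gate routes clean and skewed samples correctly", {
  set.seed(61)
  g <- rep(c("a", "b"), each = 200)
  x_norm <- c(rnorm(200), rnorm(200, 1))
  expect_equal(normality_gate(x_norm, g), "normal")
  x_skew <- c(rexp(200), rnorm(200))
  expect_equal(normality_gate(x_skew, g), "non_normal")
  # degenerate constant sample is classified non-normal, not an error
  x_const <- c(rep(1, 200), rnorm(200))
  expect_equal(normality_gate(x_const, g), "non_normal")
  expect_error(normality_gate(c(1, 2, 3, 4), rep(c("a", "b"), 2)), ">= 3")
})

test_that("group comparison: identical samples, known difference, gate respect", {
  x <- c(1.1, 2.3, 3.1, 4.9, 5.2)
  vals <- c(x, x)
  g <- rep(c("a", "b"), each = 5)
  r <- compare_groups(vals, g, gate = "normal")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)
  expect_equal(r$test_used, "t")
  r2 <- compare_groups(vals, g, gate = "non_normal")
  expect_equal(r2$test_used, "mann_whitney")
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  # statistic orientation: reference (control) minus other
  set.seed(62)
  v <- c(rnorm(20, 1), rnorm(25, 0))
  gg <- rep(c("control", "patient"), c(20, 25))
  rt <- compare_groups(v, gg, gate = "normal")
  expect_gt(rt$statistic, 0)
  expect_equal(rt$group_1, "control")
  # pooled-variance Student t matches stats::t.test
  tt <- t.test(v[gg == "control"], v[gg == "patient"], var.equal = TRUE)
  expect_equal(rt$statistic, unname(tt$statistic))
  expect_equal(rt$p_raw, tt$p.value)
})

test_that("Mann-Whitney z matches wilcox.test normal approximation", {
  set.seed(63)
  for (rep in 1:10) {
    x <- round(rnorm(15), 1)  # rounding induces ties
    y <- round(rnorm(12, 0.5), 1)
    mw <- scnet:::mann_whitney_z(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  }
})

test_that("type-I error of the gated comparison is nominal", {
  set.seed(64)
  reps <- 500
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    v <- rnorm(45)
    g <- rep(c("control", "patient"), c(20, 25))
    p[r] <- compare_groups(v, g)$p_raw
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("power against a unit shift at the study's group sizes", {
  set.seed(65)
  rej <- vapply(1:200, function(r) {
    v <- c(rnorm(20, 1), rnorm(25, 0))
    g <- rep(c("control", "patient"), c(20, 25))
    compare_groups(v, g)$p_raw < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.8)
})

test_that("2x2 chi-square: closed forms and transposition invariance", {
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2, 2))$p, 1)
  expect_equal(chi_square_2x2(matrix(c(20, 0, 0, 20), 2, 2))$statistic, 40)
  tab <- matrix(c(7, 14, 13, 11), 2, 2)
  expect_equal(chi_square_2x2(tab)$statistic, chi_square_2x2(t(tab))$statistic)
  # closed-form Pearson formula n(ad-bc)^2 / (r1 r2 c1 c2)
  a <- 7; b <- 13; c <- 14; d <- 11
  expect_equal(chi_square_2x2(matrix(c(a, c, b, d), 2, 2))$statistic,
               45 * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)))
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(66)
  for (r in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdr_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("clinical correlations recover exact and null relationships", {
  x <- seq(1, 10)
  r <- correlate_clinical(matrix(x, dimnames = list(NULL, "m")),
                          data.frame(clin = 2 * x + 1))
  expect_equal(r$pearson_r, 1)
  r2 <- correlate_clinical(matrix(x, dimnames = list(NULL, "m")),
                           data.frame(clin = -x))
  expect_equal(r2$pearson_r, -1)
  set.seed(67)
  r3 <- correlate_clinical(matrix(rnorm(500), dimnames = list(NULL, "m")),
                           data.frame(clin = rnorm(500)))
  expect_lt(abs(r3$pearson_r), 0.1)
  expect_error(correlate_clinical(matrix(rep(1, 10), dimnames = list(NULL, "m")),
                                  data.frame(clin = rnorm(10))), "variance")
})

test_that("family-wise comparison table carries consistent FDR values", {
  set.seed(68)
  mat <- cbind(a = rnorm(45), b = c(rnorm(20, 2), rnorm(25)), c = rnorm(45))
  g <- rep(c("control", "patient"), c(20, 25))
  fam <- compare_groups_family(mat, g)
  expect_equal(fam$p_fdr, fdr_adjust(fam$p_raw))
  expect_true(all(fam$p_fdr >= fam$p_raw))
  expect_lt(fam$p_fdr[fam$variable == "b"], 0.05)
})
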