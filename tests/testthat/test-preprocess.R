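make_features <- function(vals, groups) {
  # minimal bilateral table over the full roster, overriding a few columns
  roster <- node_roster()
  n <- nrow(vals)
  base <- matrix(rep(seq(2, 5, length.out = 74), each = n), n, 74)
  base[, seq_len(ncol(vals))] <- vals
  morph_table(base,
              data.frame(region = roster$region,
                         feature_class = roster$feature_class,
                         hemisphere = "bilateral", stringsAsFactors = FALSE),
              data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                         group = groups, stringsAsFactors = FALSE))
}

make_covariates <- function(n, groups, age = NULL, sex = NULL, icv = NULL) {
  data.frame(subject_id = sprintf("S%02d", seq_len(n)),
             age = if (is.null(age)) 55 + (seq_len(n) * 7) %% 20 else age,
             sex = if (is.null(sex)) rep_len(c("male", "female"), n) else sex,
             icv = if (is.null(icv)) 1300 + (seq_len(n) * 13) %% 250 else icv,
             group = groups, mmse = NA_real_, fab = NA_real_,
             duration = NA_real_, stringsAsFactors = FALSE)
}

test_that("residuals remove a planted linear age effect", {
  set.seed(11)
  n <- 200
  groups <- rep("control", n)
  age <- runif(n, 50, 80)
  vals <- matrix(rep(seq(2, 5, length.out = 74), each = n), n, 74)
  vals[, 1] <- 2.5 + 0.01 * age + rnorm(n, 0, 0.02)
  ft <- make_features(vals, groups)
  cv <- make_covariates(n, groups, age = age,
                        sex = sample(c("male", "female"), n, TRUE),
                        icv = rnorm(n, 1400, 150))
  res <- residualize(ft, cv)
  expect_lt(abs(cor(res[, 1], age)), 0.05)
  # reference regression agrees
  ref <- residuals(lm(vals[, 1] ~ age + I(cv$sex == "male") + cv$icv))
  expect_equal(unname(res[, 1]), unname(ref), tolerance = 1e-8)
})

test_that("patient residuals use control-fit coefficients", {
  n <- 12
  groups <- rep(c("control", "patient"), c(8, 4))
  set.seed(2)
  vals <- matrix(runif(n * 74, 2, 5), n, 74)
  ft <- make_features(vals, groups)
  cv <- make_covariates(n, groups)
  res <- residualize(ft, cv, fit_on = "controls")
  beta <- attr(res, "coefficients")
  X <- cbind(1, cv$age, as.numeric(cv$sex == "male"), cv$icv)
  expect_equal(unname(res[10, 3]),
               unname(ft$values[10, 3] - X[10, ] %*% beta[, 3])[1])
  # OLS with intercept: residuals average to zero over the fitting set
  fit <- which(groups == "control")
  expect_equal(unname(colMeans(res[fit, ])), rep(0, 74), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the covariate", {
  n <- 10
  groups <- rep("control", n)
  ft <- make_features(matrix(runif(n * 74, 2, 5), n, 74), groups)
  cv <- make_covariates(n, groups, sex = rep("female", n))
  expect_error(residualize(ft, cv), "sex")
  few <- rep(c("control", "patient"), c(4, 6))
  ft2 <- make_features(matrix(runif(n * 74, 2, 5), n, 74), few)
  expect_error(residualize(ft2, make_covariates(n, few)), "5 subjects")
})

test_that("control z-scores have mean 0 and SD 1 by construction", {
  co <- tiny_cohort(seed = 21)
  z <- preprocess_morphometry(bilateral_average(co$features), co$covariates)
  ctrl <- co$covariates$subject_id[co$covariates$group == "control"]
  zc <- z[ctrl, ]
  expect_lt(max(abs(colMeans(zc))), 1e-10)
  expect_lt(max(abs(apply(zc, 2, sd) - 1)), 1e-10)
  expect_true(all(is.finite(z)))
})

test_that("z-scoring matches its definition on a hand case", {
  res <- matrix(c(-1, 0, 1, 0.5), 4, 1,
                dimnames = list(c("a", "b", "c", "p"), "node1"))
  z <- zscore_by_controls(res, c("a", "b", "c"))
  expect_equal(unname(z[1:3, 1]), c(-1, 0, 1))
  expect_equal(unname(z["p", 1]), 0.5)       # controls have mean 0, sd 1
  res2 <- res; res2["p", 1] <- 2              # mean + 2*SD -> z = 2
  expect_equal(unname(zscore_by_controls(res2, c("a", "b", "c"))["p", 1]), 2)
  resc <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "flat"))
  expect_error(zscore_by_controls(resc, c("a", "b", "c")), "flat")
})

test_that("z-scores are invariant to feature unit rescaling and sex coding", {
  co <- tiny_cohort(seed = 22)
  ft <- bilateral_average(co$features)
  z1 <- preprocess_morphometry(ft, co$covariates)
  ft2 <- ft
  ft2$values[, 5] <- ft$values[, 5] * 1000  # e.g. mm -> um
  ft2 <- morph_table(ft2$values, ft2$features, ft2$subjects)
  z2 <- preprocess_morphometry(ft2, co$covariates)
  expect_equal(z1, z2, tolerance = 1e-9, ignore_attr = TRUE)
  # flipped binary sex coding gives identical residuals
  cv2 <- co$covariates
  cv2$sex <- ifelse(cv2$sex == "male", "female", "male")
  z3 <- preprocess_morphometry(ft, cv2)
  expect_equal(z1, z3, tolerance = 1e-9, ignore_attr = TRUE)
})
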