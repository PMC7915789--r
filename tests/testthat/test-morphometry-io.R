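test_that("node roster has the documented composition and order", {
  r <- node_roster()
  expect_equal(nrow(r), 74)
  expect_equal(unname(table(r$feature_class)[c("thickness", "area", "volume")]),
               c(34L, 34L, 6L), ignore_attr = TRUE)
  expect_equal(length(dk_cortical_regions()), 34)
  expect_equal(length(subcortical_regions()), 6)
  # fixed order: thickness block first, then area, then volume
  expect_equal(r$feature_class, rep(c("thickness", "area", "volume"),
                                    c(34, 34, 6)))
  expect_equal(r$node, 1:74)
  # packaged fixture matches the in-code roster
  fix <- read.table(system.file("extdata", "node_roster.tsv", package = "scnet"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(fix$label, r$label)
})

test_that("wide tables round-trip through write/read at full precision", {
  co <- tiny_cohort(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(co$features, path)
  back <- read_feature_table(path, layout = "wide")
  expect_equal(back$values[, colnames(co$features$values)],
               co$features$values, tolerance = 0)
  expect_equal(back$subjects$group, co$features$subjects$group)
})

test_that("bilateral averaging is the arithmetic mean and is idempotent", {
  co <- tiny_cohort(seed = 4)
  bi <- bilateral_average(co$features)
  expect_equal(ncol(bi$values), 74)
  # mean of hemispheres, checked manually on one feature
  lab <- "precuneus_thickness"
  expect_equal(bi$values[, lab],
               (co$features$values[, paste0(lab, "_lh")] +
                co$features$values[, paste0(lab, "_rh")]) / 2)
  # left == right implies output equals either hemisphere
  sym <- co$features
  sym$values[, 75:148] <- sym$values[, 1:74]
  colnames(sym$values) <- colnames(co$features$values)
  bis <- bilateral_average(morph_table(sym$values, sym$features, sym$subjects))
  expect_equal(unname(bis$values), unname(sym$values[, 1:74]))
  # idempotent on already-bilateral tables
  expect_equal(bilateral_average(bi)$values, bi$values)
})

test_that("long layout parses and averages to the same bilateral table", {
  co <- tiny_cohort(seed = 5)
  ft <- co$features
  idx <- expand.grid(s = seq_len(nrow(ft$values)), f = seq_len(ncol(ft$values)))
  long <- data.frame(subject_id = ft$subjects$subject_id[idx$s],
                     group = ft$subjects$group[idx$s],
                     region = ft$features$region[idx$f],
                     hemisphere = ft$features$hemisphere[idx$f],
                     feature_class = ft$features$feature_class[idx$f],
                     value = sprintf("%.17g", ft$values[cbind(idx$s, idx$f)]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_feature_table(path, layout = "long")
  expect_equal(bilateral_average(parsed)$values[rownames(ft$values), ],
               bilateral_average(ft)$values)
})

test_that("feature-table validation names the offending region/cell", {
  co <- tiny_cohort(seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(co$features, path)
  df <- read.csv(path, check.names = FALSE)

  # dropped region pair -> error listing it
  broken <- df[, !grepl("^precuneus_thickness", names(df))]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(p2, "wide"), "precuneus")

  # one hemisphere missing -> error
  broken <- df[, names(df) != "cuneus_area_rh"]
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, p3, row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(p3, "wide"), "cuneus")

  # non-numeric cell -> error naming the column
  broken <- df
  broken[["insula_thickness_lh"]][2] <- "oops"
  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, p4, row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(p4, "wide"), "insula_thickness_lh")

  # duplicate subject -> error
  broken <- rbind(df, df[1, ])
  p5 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, p5, row.names = FALSE, quote = FALSE)
  expect_error(read_feature_table(p5, "wide"), "duplicate")
})

test_that("FreeSurfer-style hemisphere prefixes and aliases are understood", {
  sp <- scnet:::split_hemisphere_prefix
  got <- sp(c("ctx-lh-precuneus", "Right-Thalamus-Proper", "lh_bankssts",
              "cuneus"))
  expect_equal(got$region, c("precuneus", "thalamus", "bankssts", "cuneus"))
  expect_equal(got$hemisphere, c("left", "right", "left", NA))
})

test_that("covariates are validated: codes, duplicates, coverage", {
  co <- tiny_cohort(seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_covariates(co$covariates, path)
  cv <- read_covariates(path)
  expect_s3_class(cv, "covariate_table")
  expect_true(all(cv$sex %in% c("male", "female")))
  expect_equal(cv$age, co$covariates$age)

  df <- read.csv(path)
  df$sex[3] <- "X"
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE, quote = FALSE)
  expect_error(read_covariates(p2), "sex")

  df <- read.csv(path)
  df$icv[1] <- -5
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p3, row.names = FALSE, quote = FALSE)
  expect_error(read_covariates(p3), "icv")

  df <- read.csv(path)
  df <- rbind(df, df[1, ])
  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p4, row.names = FALSE, quote = FALSE)
  expect_error(read_covariates(p4), "duplicate")

  # subject present in features but missing from covariates
  cut <- co$covariates[-1, ]
  expect_error(scnet:::check_subjects_covered(co$features, cut), "S001")
})
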