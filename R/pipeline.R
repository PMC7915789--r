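#' Pipeline run configuration
#'
#' Collects the tunable parameters of the end-to-end analysis. Defaults
#' reproduce the reference analysis conditions: densities 0.10-0.40 in
#' steps of 0.01, 1000 nulls per (subject, density) for small-world
#' normalization, controls-only covariate fitting, Onnela weighted
#' clustering, FDR level 0.05. `n_nulls = 100` is the documented fast
#' mode for tests and smoke runs; `small_world = FALSE` skips null
#' generation entirely (gamma/lambda/sigma are then not reported).
#'
#' @param density_lo,density_hi,density_step density sweep bounds and
#'   increment.
#' @param n_nulls null networks per (subject, density).
#' @param rewires_per_edge attempted Maslov-Sneppen swaps per edge.
#' @param seed global seed; per-subject, per-density substreams are
#'   derived from it by a counter-based scheme keyed on a hash of the
#'   subject id, so results do not depend on subject order.
#' @param fit_on covariate fitting set, `"controls"` or `"all"`.
#' @param clustering `"onnela"` or `"barrat"`.
#' @param alpha FDR significance level.
#' @param small_world compute null-normalized small-world metrics.
#' @param nodal compute nodal metrics.
#' @param outdir optional output directory for artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(density_lo = 0.10, density_hi = 0.40,
                       density_step = 0.01, n_nulls = 1000,
                       rewires_per_edge = 100, seed = 1,
                       fit_on = c("controls", "all"),
                       clustering = c("onnela", "barrat"), alpha = 0.05,
                       small_world = TRUE, nodal = TRUE, outdir = NULL) {
  fit_on <- match.arg(fit_on)
  clustering <- match.arg(clustering)
  densities <- density_grid(density_lo, density_hi, density_step)
  structure(list(densities = densities, n_nulls = n_nulls,
                 rewires_per_edge = rewires_per_edge, seed = seed,
                 fit_on = fit_on, clustering = clustering, alpha = alpha,
                 small_world = small_world, nodal = nodal, outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from a key = value text file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Keys mirror the [run_config()] arguments.
#'
#' @param path config file path.
#' @param ... overrides applied after the file is read.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", lines))
  args <- list()
  for (m in kv) {
    if (length(m) != 3) next
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full covariance-network analysis
#'
#' Stages: validate and bilaterally average the morphometry; residualize
#' against age, sex, and ICV and z-score against controls; build each
#' subject's 74-node network; sweep densities and compute graph metrics
#' (with degree-preserving null normalization when
#' `config$small_world`); reduce to AUCs; compare groups (global-metric
#' family and one FDR family per nodal metric across the 74 nodes); and
#' correlate patients' nodal AUC metrics with available clinical scores
#' (MMSE, FAB, disease duration). With `config$outdir` set, TSV reports
#' and a JSON manifest (config, seed, package version, file checksums)
#' are written; identical seed and inputs give identical artifacts.
#'
#' @param features a [morph_table] (hemisphere-resolved or bilateral) or
#'   a path to a wide-format feature table.
#' @param covariates a covariate table or a path (see
#'   [read_covariates()]).
#' @param config a [run_config()].
#' @return list of class `scnet_result`: `zscores`, `networks`,
#'   `global_curves` (per-subject, per-density global metrics),
#'   `global_auc` (data.frame), `nodal_auc` (long data.frame),
#'   `global_comparisons`, `nodal_comparisons`, `correlations`,
#'   `config`, `manifest`.
#' @export
run_pipeline <- function(features, covariates, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  covariates <- stage("read_covariates", {
    if (is.character(covariates)) read_covariates(covariates) else covariates
  })
  features <- stage("read_features", {
    if (is.character(features)) read_feature_table(features, "wide") else features
  })
  features <- stage("bilateral_average", bilateral_average(features))
  # groups come from the covariates (the morphometric table may carry
  # placeholder labels when read from a long layout without group)
  stage("covariate_check", check_subjects_covered(features, covariates))
  cov <- covariates[match(features$subjects$subject_id, covariates$subject_id), ]
  features$subjects$group <- cov$group

  z <- stage("preprocess", preprocess_morphometry(features, covariates,
                                                  config$fit_on))
  subjects <- features$subjects
  networks <- stage("build_networks",
                    lapply(seq_len(nrow(z)),
                           function(i) build_covariance_network(z[i, ])))
  names(networks) <- subjects$subject_id

  per_subj <- stage("metrics", lapply(seq_len(nrow(z)), function(i) {
    tryCatch(
      sweep_metrics(networks[[i]], densities = config$densities,
                    n_nulls = config$n_nulls,
                    rewires_per_edge = config$rewires_per_edge,
                    seed = derive_seed(config$seed,
                                       hash_id(subjects$subject_id[i]), 0),
                    small_world = config$small_world, nodal = config$nodal,
                    variant = config$clustering),
      error = function(e) stop(sprintf("subject %s: %s",
                                       subjects$subject_id[i],
                                       conditionMessage(e)), call. = FALSE))
  }))

  global_curves <- do.call(rbind, lapply(seq_along(per_subj), function(i)
    cbind(subject_id = subjects$subject_id[i], group = subjects$group[i],
          per_subj[[i]]$global, stringsAsFactors = FALSE)))
  global_auc <- data.frame(subject_id = subjects$subject_id,
                           group = subjects$group,
                           do.call(rbind, lapply(per_subj, function(s)
                             as.data.frame(as.list(s$global_auc)))),
                           stringsAsFactors = FALSE)
  roster <- node_roster()
  nodal_auc <- NULL
  if (config$nodal) {
    nodal_auc <- do.call(rbind, lapply(seq_along(per_subj), function(i) {
      m <- per_subj[[i]]$nodal_auc
      data.frame(subject_id = subjects$subject_id[i],
                 group = subjects$group[i],
                 node = rep(roster$label, ncol(m)),
                 feature_class = rep(roster$feature_class, ncol(m)),
                 metric = rep(colnames(m), each = nrow(m)),
                 auc_value = as.vector(m), stringsAsFactors = FALSE)
    }))
  }

  gmat <- as.matrix(global_auc[, setdiff(names(global_auc),
                                         c("subject_id", "group"))])
  global_comparisons <- stage("stats_global",
                              compare_groups_family(gmat, global_auc$group))
  nodal_comparisons <- NULL
  if (config$nodal) {
    nodal_comparisons <- stage("stats_nodal", {
      do.call(rbind, lapply(unique(nodal_auc$metric), function(m) {
        sub <- nodal_auc[nodal_auc$metric == m, ]
        # rows of sub are grouped by subject (node fastest): reshape
        mat <- do.call(rbind, lapply(split(sub$auc_value, sub$subject_id)[
          subjects$subject_id], function(v) v))
        colnames(mat) <- roster$label
        cbind(metric = m, compare_groups_family(mat, subjects$group),
              stringsAsFactors = FALSE)
      }))
    })
  }

  correlations <- NULL
  if (config$nodal) {
    correlations <- stage("correlations", {
      pat <- subjects$group == "patient"
      clin <- cov[pat, intersect(c("mmse", "fab", "duration"), names(cov)),
                  drop = FALSE]
      clin <- clin[, vapply(clin, function(x) sum(is.finite(x)) >= 3,
                            TRUE), drop = FALSE]
      if (sum(pat) >= 3 && ncol(clin) > 0) {
        do.call(rbind, lapply(c("local_efficiency", "strength"), function(m) {
          sub <- nodal_auc[nodal_auc$metric == m &
                             nodal_auc$group == "patient", ]
          mat <- do.call(rbind, lapply(split(sub$auc_value, sub$subject_id)[
            subjects$subject_id[pat]], function(v) v))
          colnames(mat) <- roster$label
          keep <- apply(mat, 2, sd) > 0
          cbind(metric = m,
                correlate_clinical(mat[, keep, drop = FALSE], clin),
                stringsAsFactors = FALSE)
        }))
      } else NULL
    })
  }

  result <- structure(list(zscores = z, networks = networks,
                           global_curves = global_curves,
                           global_auc = global_auc, nodal_auc = nodal_auc,
                           global_comparisons = global_comparisons,
                           nodal_comparisons = nodal_comparisons,
                           correlations = correlations, config = config),
                      class = "scnet_result")
  if (!is.null(config$outdir))
    result$manifest <- stage("write_artifacts",
                             write_run_artifacts(result, config$outdir))
  result
}

#' @export
print.scnet_result <- function(x, ...) {
  cat(sprintf("scnet_result: %d subjects (%d controls / %d patients), %d densities\n",
              nrow(x$zscores), sum(x$global_auc$group == "control"),
              sum(x$global_auc$group == "patient"),
              length(x$config$densities)))
  cat("global AUC comparisons:\n")
  print(x$global_comparisons[, c("variable", "test_used", "statistic",
                                 "p_raw", "p_fdr")], row.names = FALSE)
  invisible(x)
}

#' @keywords internal
write_run_artifacts <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    zscores = {
      p <- file.path(outdir, "zscores.tsv"); write_zscore_table(result$zscores, p); p
    },
    global_auc = wt(result$global_auc, "global_auc.tsv"),
    global_comparisons = wt(result$global_comparisons, "global_comparisons.tsv"))
  if (!is.null(result$nodal_auc))
    paths["nodal_auc"] <- wt(result$nodal_auc, "nodal_auc.tsv")
  if (!is.null(result$nodal_comparisons))
    paths["nodal_comparisons"] <- wt(result$nodal_comparisons,
                                     "nodal_comparisons.tsv")
  if (!is.null(result$correlations))
    paths["correlations"] <- wt(result$correlations, "correlations.tsv")
  manifest <- list(package = "scnet",
                   version = as.character(packageVersion("scnet")),
                   config = unclass(result$config),
                   files = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
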