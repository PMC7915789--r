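#' Specification for a synthetic two-group morphometric cohort
#'
#' Defines the study conditions the generator emulates: a control group
#' and a patient group with frontotemporal-dementia-like demographics
#' (defaults follow the reference cohort: 20 controls of age
#' 63.6 +/- 5.9 y, 13/20 female; 25 patients of age 66.9 +/- 7.7 y,
#' 11/25 female; ICV 1406 +/- 156 vs 1432 +/- 164 ml), linear covariate
#' loadings of every feature on age and ICV, and planted atrophy in a
#' frontotemporal target set of cortical-thickness nodes.
#'
#' Atrophy has two components per target node, both in units of the
#' feature-class noise SD: a mean shift `delta` (default -1.5) and a
#' per-subject, per-region heterogeneity jitter with SD `tau`
#' (default 0.8). The heterogeneity is the effect carrier for the
#' covariance networks: a uniform shift alone leaves within-subject
#' z-score differences (hence the edge weights) nearly unchanged, while
#' region-to-region jitter decorrelates target nodes from the rest.
#'
#' MMSE is coupled to the atrophy burden (mean planted deficit in SD
#' units) as `mmse = 28 - 4 * burden + N(0, 2)`, clipped to `[0, 30]`,
#' giving patients roughly 21 +/- 5; FAB and disease duration follow the
#' same cohort scales.
#'
#' @param n_controls,n_patients group sizes.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param age_mean,age_sd,icv_mean,icv_sd named numeric vectors
#'   (`control`, `patient`), years and ml.
#' @param p_female named numeric vector of female probabilities.
#' @param delta planted mean shift at target nodes (control-SD units,
#'   patients only).
#' @param tau planted heterogeneity SD at target nodes (control-SD
#'   units, patients only).
#' @param atrophy_targets character vector of target regions (thickness
#'   nodes).
#' @param mmse_slope,mmse_noise_sd MMSE coupling (score units per SD of
#'   burden) and noise SD.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 20, n_patients = 25, seed = 1,
                        age_mean = c(control = 63.6, patient = 66.9),
                        age_sd = c(control = 5.9, patient = 7.7),
                        p_female = c(control = 13 / 20, patient = 11 / 25),
                        icv_mean = c(control = 1406.2, patient = 1431.8),
                        icv_sd = c(control = 155.7, patient = 163.7),
                        delta = -1.5, tau = 0.8,
                        atrophy_targets = c("rostralmiddlefrontal",
                                            "caudalmiddlefrontal",
                                            "parsopercularis",
                                            "rostralanteriorcingulate",
                                            "caudalanteriorcingulate",
                                            "inferiortemporal",
                                            "transversetemporal",
                                            "precuneus", "cuneus"),
                        mmse_slope = 4, mmse_noise_sd = 2) {
  stopifnot(n_controls >= 2, n_patients >= 2,
            all(age_sd > 0), all(icv_sd > 0), tau >= 0)
  if (!all(atrophy_targets %in% dk_cortical_regions()))
    stop("unknown atrophy target region(s): ",
         paste(setdiff(atrophy_targets, dk_cortical_regions()), collapse = ", "))
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 seed = seed, age_mean = age_mean, age_sd = age_sd,
                 p_female = p_female, icv_mean = icv_mean, icv_sd = icv_sd,
                 delta = delta, tau = tau, atrophy_targets = atrophy_targets,
                 mmse_slope = mmse_slope, mmse_noise_sd = mmse_noise_sd),
            class = "cohort_spec")
}

# fixed per-class generative constants: baseline levels per region
# (plausible FreeSurfer scales), measurement noise SD, covariate slopes,
# and hemispheric asymmetry SD
#' @keywords internal
class_params <- function() {
  ctx <- dk_cortical_regions()
  n <- length(ctx)
  list(
    thickness = list(base = seq(2.1, 3.0, length.out = n),
                     noise_sd = 0.12, age_slope = -0.010,
                     icv_slope = 0.00005, sex_slope = 0.02, asym_sd = 0.04),
    area = list(base = seq(1200, 4800, length.out = n),
                noise_sd = 200, age_slope = -6,
                icv_slope = 1.2, sex_slope = 40, asym_sd = 60),
    volume = list(base = c(amygdala = 1700, caudate = 3600,
                           hippocampus = 4300, pallidum = 1800,
                           putamen = 5200, thalamus = 7600),
                  noise_sd = 300, age_slope = -15,
                  icv_slope = 2.5, sex_slope = 80, asym_sd = 90)
  )
}

#' Generate a synthetic morphometric cohort
#'
#' Draws covariates per group, then per-subject hemisphere-resolved
#' features: `value = base + age_slope*(age - 65) + icv_slope*(icv -
#' 1420) + sex_slope*male + noise`, with the planted atrophy
#' `(delta + N(0, tau)) * noise_sd` added at target thickness nodes of
#' patients, and a small antisymmetric left/right split so that the
#' bilateral average recovers the generated value exactly. The output
#' passes all morphometry validations and is byte-identical across runs
#' with the same spec (R's RNG state is saved and restored).
#'
#' @param spec a [cohort_spec].
#' @return list with `features` (hemisphere-resolved [morph_table]),
#'   `covariates` (covariate table), `target_labels` (planted node
#'   labels, `<region>_thickness`), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed %% 2147483647, kind = "Mersenne-Twister")

  groups <- c(rep("control", spec$n_controls), rep("patient", spec$n_patients))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  age <- rnorm(n, spec$age_mean[groups], spec$age_sd[groups])
  age <- pmax(age, 40)
  female <- rbinom(n, 1, spec$p_female[groups])
  sex <- ifelse(female == 1, "female", "male")
  icv <- rnorm(n, spec$icv_mean[groups], spec$icv_sd[groups])
  icv <- pmax(icv, 900)

  roster <- node_roster()
  cp <- class_params()
  vals <- matrix(NA_real_, n, nrow(roster),
                 dimnames = list(ids, roster$label))
  burden <- numeric(n)  # mean planted deficit in SD units, per subject
  target_labels <- paste0(spec$atrophy_targets, "_thickness")
  for (r in seq_len(nrow(roster))) {
    p <- cp[[roster$feature_class[r]]]
    base <- if (roster$feature_class[r] == "volume")
      p$base[[roster$region[r]]]
    else p$base[match(roster$region[r], dk_cortical_regions())]
    v <- base + p$age_slope * (age - 65) + p$icv_slope * (icv - 1420) +
      p$sex_slope * (sex == "male") + rnorm(n, 0, p$noise_sd)
    if (roster$label[r] %in% target_labels) {
      shift_units <- ifelse(groups == "patient",
                            spec$delta + rnorm(n, 0, spec$tau), 0)
      v <- v + shift_units * p$noise_sd
      burden <- burden - shift_units / length(target_labels)
    }
    vals[, r] <- pmax(v, 0.05 * base)  # morphometry is strictly positive
  }

  # hemisphere split: lh = v + a, rh = v - a so the bilateral mean is exact
  lh <- rh <- vals
  for (r in seq_len(nrow(roster))) {
    a <- rnorm(n, 0, cp[[roster$feature_class[r]]]$asym_sd)
    a <- pmin(abs(a), 0.4 * vals[, r]) * sign(a)  # keep both sides positive
    lh[, r] <- vals[, r] + a
    rh[, r] <- vals[, r] - a
  }
  hemi_vals <- cbind(lh, rh)
  colnames(hemi_vals) <- c(paste0(roster$label, "_lh"), paste0(roster$label, "_rh"))
  feats <- data.frame(
    region = rep(roster$region, 2),
    feature_class = rep(roster$feature_class, 2),
    hemisphere = rep(c("left", "right"), each = nrow(roster)),
    stringsAsFactors = FALSE)
  features <- morph_table(hemi_vals, feats,
                          data.frame(subject_id = ids, group = groups,
                                     stringsAsFactors = FALSE))

  mmse <- 28 - spec$mmse_slope * burden + rnorm(n, 0, spec$mmse_noise_sd)
  mmse <- round(pmin(pmax(mmse, 0), 30), 1)
  fab <- -0.55 - 2.8 * burden + rnorm(n, 0, 0.9)
  duration <- ifelse(groups == "patient",
                     round(rlnorm(n, log(2.5), 0.55), 1), NA_real_)
  covariates <- data.frame(subject_id = ids, age = round(age, 1), sex = sex,
                           icv = round(icv, 1), group = groups,
                           mmse = mmse, fab = round(fab, 2),
                           duration = duration, stringsAsFactors = FALSE)
  class(covariates) <- c("covariate_table", "data.frame")
  list(features = features, covariates = covariates,
       target_labels = target_labels, spec = spec)
}

#' Write a synthetic cohort to disk
#'
#' Writes the same plain-text formats the readers consume:
#' `features.csv` (wide, hemisphere-resolved), `covariates.csv`, and the
#' generating spec as `cohort_spec.json`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_feature_table(cohort$features, file.path(dir, "features.csv"))
  write_covariates(cohort$covariates, file.path(dir, "covariates.csv"))
  jsonlite::write_json(unclass(cohort$spec),
                       file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Check recovery of a planted atrophy effect
#'
#' Summarizes, from a pipeline result on a cohort with known targets,
#' whether the FDR-significant nodal local-efficiency reductions overlap
#' the planted target set, and the direction of the global efficiency
#' (and, when available, small-world index) group differences.
#'
#' @param result a [run_pipeline()] result.
#' @param target_labels planted node labels
#'   (`cohort$target_labels`).
#' @param alpha FDR significance level (default 0.05).
#' @return list: `significant_nodes` (FDR-significant local-efficiency
#'   reductions, patients < controls), `hits` (their intersection with
#'   the targets), `n_hits`, `eglob_lower_in_patients`,
#'   `sigma_lower_in_patients` (NA without small-world metrics).
#' @export
planted_effect_check <- function(result, target_labels, alpha = 0.05) {
  nod <- result$nodal_comparisons
  le <- nod[nod$metric == "local_efficiency", , drop = FALSE]
  sig <- le$variable[le$p_fdr < alpha & le$mean_1 > le$mean_2]
  glob <- result$global_comparisons
  eg <- glob[glob$variable == "eglob", , drop = FALSE]
  sg <- glob[glob$variable == "sigma", , drop = FALSE]
  list(significant_nodes = sig,
       hits = intersect(sig, target_labels),
       n_hits = length(intersect(sig, target_labels)),
       eglob_lower_in_patients = if (nrow(eg)) eg$mean_2 < eg$mean_1 else NA,
       sigma_lower_in_patients = if (nrow(sg)) sg$mean_2 < sg$mean_1 else NA)
}
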