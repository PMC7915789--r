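#' Morphometric feature tables
#'
#' A `morph_table` holds one row per subject of regional morphometric
#' measurements (cortical thickness in mm, cortical surface area in mm^2,
#' subcortical volume in mm^3), either hemisphere-resolved or bilaterally
#' averaged. It is the input container for the covariance-network pipeline.
#'
#' @param values numeric matrix, subjects x features, rownames = subject ids.
#' @param features data.frame with one row per column of `values` and
#'   columns `region`, `feature_class` (`thickness`/`area`/`volume`) and
#'   `hemisphere` (`left`/`right`/`bilateral`).
#' @param subjects data.frame with columns `subject_id` and `group`
#'   (`control`/`patient`), one row per row of `values`.
#' @return an object of class `morph_table`.
#' @export
morph_table <- function(values, features, subjects) {
  stopifnot(is.matrix(values), nrow(features) == ncol(values),
            nrow(subjects) == nrow(values))
  rownames(values) <- subjects$subject_id
  colnames(values) <- ifelse(features$hemisphere == "bilateral",
                             paste(features$region, features$feature_class, sep = "_"),
                             paste(features$region, features$feature_class,
                                   c(left = "lh", right = "rh")[features$hemisphere],
                                   sep = "_"))
  x <- structure(list(values = values, features = features, subjects = subjects),
                 class = "morph_table")
  validate_morph_table(x)
  x
}

#' @export
print.morph_table <- function(x, ...) {
  hemi <- if (all(x$features$hemisphere == "bilateral")) "bilateral"
          else "hemisphere-resolved"
  cat(sprintf("morph_table: %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values), hemi))
  invisible(x)
}

#' @keywords internal
validate_morph_table <- function(x) {
  v <- x$values
  bad <- which(!is.finite(v) | v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive or non-finite value at subject '%s', feature '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  }
  if (anyDuplicated(x$subjects$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(x$subjects$subject_id[duplicated(x$subjects$subject_id)]),
               collapse = ", "))
  if (!all(x$subjects$group %in% c("control", "patient")))
    stop("group labels must be 'control' or 'patient'")
  roster <- node_roster()
  ft <- x$features
  key <- paste(ft$region, ft$feature_class)
  known <- paste(roster$region, roster$feature_class)
  if (any(!key %in% known))
    stop("unknown (region, feature_class): ",
         paste(unique(key[!key %in% known]), collapse = ", "))
  # completeness: each roster node must be covered bilaterally or by both
  # hemispheres
  missing <- character(0)
  for (r in seq_len(nrow(roster))) {
    sel <- key == known[r]
    hemi <- ft$hemisphere[sel]
    ok <- ("bilateral" %in% hemi) || all(c("left", "right") %in% hemi)
    if (!ok) missing <- c(missing, known[r])
  }
  if (length(missing) > 0)
    stop("missing region/hemisphere coverage for: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(paste(key, ft$hemisphere)))
    stop("duplicate feature columns")
  invisible(x)
}

#' @keywords internal
is_bilateral <- function(x) all(x$features$hemisphere == "bilateral")

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character")
}

num_or_stop <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(is.na(x) | x %in% c("", "NA")))
  if (length(bad) > 0)
    stop(sprintf("non-numeric value '%s' in %s (row %d)", x[bad[1]], what, bad[1]))
  out
}

#' Read a regional morphometric feature table
#'
#' Two plain-text layouts (comma- or tab-separated, detected from the
#' header line) are supported:
#' \describe{
#'   \item{wide}{columns `subject_id`, `group`, then one column per
#'     feature named `<region>_<class>` for bilateral values or
#'     `<region>_<class>_lh` / `<region>_<class>_rh` for
#'     hemisphere-resolved values (`class` is `thickness`, `area`, or
#'     `volume`). FreeSurfer-style hemisphere prefixes such as
#'     `ctx-lh-precuneus_thickness` are also understood.}
#'   \item{long}{columns `subject_id`, `region`, `hemisphere`
#'     (`left`/`right`/`lh`/`rh`/`bilateral`), `feature_class`, `value`,
#'     and optionally `group`.}
#' }
#' Region names are matched case-insensitively after stripping
#' non-alphanumeric characters; a small alias map covers common
#' FreeSurfer spellings (e.g. `Thalamus-Proper` -> `thalamus`).
#'
#' @param path file path.
#' @param layout `"wide"` or `"long"`.
#' @return a [morph_table]; hemisphere-resolved tables still need
#'   [bilateral_average()] before network construction.
#' @export
read_feature_table <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- read_delim_auto(path)
  if (layout == "wide") parse_wide_features(df) else parse_long_features(df)
}

#' @keywords internal
parse_wide_features <- function(df) {
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("wide feature table must have columns: ", paste(need, collapse = ", "))
  featcols <- setdiff(names(df), need)
  if (length(featcols) == 0) stop("no feature columns found")
  reg <- cls <- hemi <- character(length(featcols))
  for (k in seq_along(featcols)) {
    nm <- tolower(featcols[k])
    h <- NA_character_
    if (grepl("_(lh|left)$", nm)) { h <- "left";  nm <- sub("_(lh|left)$", "", nm) }
    if (grepl("_(rh|right)$", nm)) { h <- "right"; nm <- sub("_(rh|right)$", "", nm) }
    m <- regmatches(nm, regexec("^(.*)_(thickness|area|volume)$", nm))[[1]]
    if (length(m) == 0)
      stop("cannot parse feature column name: ", featcols[k])
    pre <- split_hemisphere_prefix(m[2])
    if (!is.na(pre$hemisphere)) h <- pre$hemisphere
    reg[k] <- pre$region
    cls[k] <- m[3]
    hemi[k] <- if (is.na(h)) "bilateral" else h
  }
  vals <- sapply(featcols, function(cn) num_or_stop(df[[cn]], paste0("column '", cn, "'")))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(df$subject_id, featcols))
  morph_table(vals,
              data.frame(region = reg, feature_class = cls, hemisphere = hemi,
                         stringsAsFactors = FALSE),
              data.frame(subject_id = df$subject_id, group = tolower(df$group),
                         stringsAsFactors = FALSE))
}

#' @keywords internal
parse_long_features <- function(df) {
  need <- c("subject_id", "region", "hemisphere", "feature_class", "value")
  if (!all(need %in% names(df)))
    stop("long feature table must have columns: ", paste(need, collapse = ", "))
  hemi_map <- c(left = "left", lh = "left", l = "left",
                right = "right", rh = "right", r = "right",
                bilateral = "bilateral", both = "bilateral")
  hemi <- hemi_map[tolower(df$hemisphere)]
  if (any(is.na(hemi)))
    stop("unknown hemisphere code: ",
         df$hemisphere[which(is.na(hemi))[1]])
  region <- canonical_region(df$region)
  cls <- tolower(df$feature_class)
  value <- num_or_stop(df$value, "column 'value'")
  group <- if ("group" %in% names(df)) tolower(df$group) else NA_character_
  subj <- unique(data.frame(subject_id = df$subject_id, group = group,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(subj$subject_id))
    stop("subject with inconsistent group label: ",
         subj$subject_id[duplicated(subj$subject_id)][1])
  if (all(is.na(subj$group))) subj$group <- "control"  # filled later from covariates
  feat <- unique(data.frame(region = region, feature_class = cls,
                            hemisphere = hemi, stringsAsFactors = FALSE))
  feat <- feat[order(match(feat$feature_class, feature_classes()),
                     feat$region, feat$hemisphere), , drop = FALSE]
  key_all <- paste(region, cls, hemi)
  key_feat <- paste(feat$region, feat$feature_class, feat$hemisphere)
  vals <- matrix(NA_real_, nrow(subj), nrow(feat),
                 dimnames = list(subj$subject_id, key_feat))
  idx <- cbind(match(df$subject_id, subj$subject_id), match(key_all, key_feat))
  if (anyDuplicated(idx))
    stop("duplicate (subject, region, hemisphere, feature_class) rows")
  vals[idx] <- value
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value for subject '%s', feature '%s'",
                 rownames(vals)[miss[1]], colnames(vals)[miss[2]]))
  }
  morph_table(vals, feat, subj)
}

#' Bilaterally average a hemisphere-resolved morphometric table
#'
#' Each (region, feature class) pair's bilateral value is the unweighted
#' arithmetic mean of its left and right measurements (surface areas are
#' averaged like thickness and volume, not summed). The operation is the
#' identity on tables that are already bilateral, so it is idempotent.
#' The output columns follow the fixed node-roster order and number
#' exactly 74 per subject.
#'
#' @param x a [morph_table].
#' @return a bilateral [morph_table] with 74 features per subject.
#' @export
bilateral_average <- function(x) {
  stopifnot(inherits(x, "morph_table"))
  roster <- node_roster()
  if (is_bilateral(x)) {
    ord <- match(roster$label, colnames(x$values))
    if (anyNA(ord)) stop("missing features: ",
                         paste(roster$label[is.na(ord)], collapse = ", "))
    return(morph_table(x$values[, ord, drop = FALSE],
                       data.frame(region = roster$region,
                                  feature_class = roster$feature_class,
                                  hemisphere = "bilateral",
                                  stringsAsFactors = FALSE),
                       x$subjects))
  }
  key <- paste(x$features$region, x$features$feature_class, x$features$hemisphere)
  out <- matrix(NA_real_, nrow(x$values), nrow(roster),
                dimnames = list(rownames(x$values), roster$label))
  for (r in seq_len(nrow(roster))) {
    kb <- paste(roster$region[r], roster$feature_class[r], "bilateral")
    kl <- paste(roster$region[r], roster$feature_class[r], "left")
    kr <- paste(roster$region[r], roster$feature_class[r], "right")
    if (kb %in% key) {
      out[, r] <- x$values[, match(kb, key)]
    } else {
      il <- match(kl, key); ir <- match(kr, key)
      if (is.na(il) || is.na(ir))
        stop("missing hemisphere for ", roster$label[r])
      out[, r] <- (x$values[, il] + x$values[, ir]) / 2
    }
  }
  morph_table(out,
              data.frame(region = roster$region,
                         feature_class = roster$feature_class,
                         hemisphere = "bilateral", stringsAsFactors = FALSE),
              x$subjects)
}

#' Write a morphometric table in the wide plain-text layout
#'
#' @param x a [morph_table].
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated. Round-trips through [read_feature_table()] at full
#'   double precision.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "morph_table"))
  df <- data.frame(subject_id = x$subjects$subject_id,
                   group = x$subjects$group, stringsAsFactors = FALSE)
  vals <- as.data.frame(x$values)
  for (j in seq_along(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  df <- cbind(df, vals)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a subject covariates table
#'
#' Expects a comma- or tab-separated file with header columns
#' `subject_id`, `age` (years), `sex` (`male`/`female`/`m`/`f`),
#' `icv` (total intracranial volume, ml), `group` (`control`/`patient`),
#' and optionally `mmse` (0-30), `fab` (z-score), `duration` (years).
#'
#' @param path file path.
#' @return a data.frame (class `covariate_table`) with typed columns.
#' @export
read_covariates <- function(path) {
  df <- read_delim_auto(path)
  need <- c("subject_id", "age", "sex", "icv", "group")
  if (!all(need %in% names(df)))
    stop("covariates table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in covariates: ",
         df$subject_id[duplicated(df$subject_id)][1])
  sex_map <- c(male = "male", m = "male", female = "female", f = "female")
  sex <- sex_map[tolower(df$sex)]
  if (any(is.na(sex)))
    stop("unknown sex code: ", df$sex[which(is.na(sex))[1]])
  group <- tolower(df$group)
  if (!all(group %in% c("control", "patient")))
    stop("unknown group label: ",
         df$group[which(!group %in% c("control", "patient"))[1]])
  out <- data.frame(subject_id = df$subject_id,
                    age = num_or_stop(df$age, "column 'age'"),
                    sex = unname(sex),
                    icv = num_or_stop(df$icv, "column 'icv'"),
                    group = group, stringsAsFactors = FALSE)
  if (any(!is.finite(out$age) | out$age <= 0)) stop("ages must be positive")
  if (any(!is.finite(out$icv) | out$icv <= 0))
    stop("non-positive icv for subject ",
         out$subject_id[which(out$icv <= 0)[1]])
  for (opt in c("mmse", "fab", "duration"))
    out[[opt]] <- if (opt %in% names(df))
      num_or_stop(df[[opt]], paste0("column '", opt, "'")) else NA_real_
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' @keywords internal
check_subjects_covered <- function(features, covariates) {
  miss <- setdiff(features$subjects$subject_id, covariates$subject_id)
  if (length(miss) > 0)
    stop("subjects missing from covariates: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Write a covariates table
#' @param covariates a covariate data.frame as returned by [read_covariates()].
#' @param path output path (`.csv` comma-separated, else tab).
#' @export
write_covariates <- function(covariates, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(covariates, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
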