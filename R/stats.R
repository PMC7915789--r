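#' Shapiro-Wilk normality gate for a two-group comparison
#'
#' A variable is routed to the parametric t-test only if neither group
#' rejects normality: the gate returns `"non_normal"` when the
#' Shapiro-Wilk p-value is below `alpha` in either group, `"normal"`
#' otherwise. Degenerate (constant) samples, for which Shapiro-Wilk is
#' undefined, are classified `"non_normal"`.
#'
#' @param values numeric vector.
#' @param groups factor/character vector of two group labels.
#' @param alpha gate level (default 0.05).
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  gl <- unique(groups)
  if (length(gl) != 2) stop("need exactly 2 groups")
  p <- vapply(gl, function(g) {
    x <- values[groups == g]
    if (length(x) < 3) stop("need >= 3 values per group for the normality gate")
    if (sd(x) == 0) return(0)  # constant sample: treat as non-normal
    shapiro.test(x)$p.value
  }, 0)
  if (any(p < alpha)) "non_normal" else "normal"
}

# Wilcoxon-Mann-Whitney with normal approximation and tie correction;
# returns the z statistic (group1 vs group2, positive when group1 ranks
# higher) and the two-sided p-value
#' @keywords internal
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  v <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
  if (v <= 0) return(list(statistic = 0, p = 1))
  z <- (U - mu) / sqrt(v)
  list(statistic = z, p = 2 * pnorm(-abs(z)))
}

#' Compare one variable between two groups
#'
#' Normally distributed variables (per [normality_gate()]) are compared
#' with a two-sided two-sample Student t-test (pooled variance by
#' default; `welch = TRUE` for the unequal-variance form);
#' non-normal variables with the Wilcoxon-Mann-Whitney test reported as
#' the tie-corrected normal-approximation z. The statistic is oriented
#' as `reference` group minus/versus the other group.
#'
#' @param values numeric vector.
#' @param groups two-level group labels aligned with `values`.
#' @param gate `"normal"`, `"non_normal"`, or `NULL` to run
#'   [normality_gate()] internally.
#' @param reference the group taken first (default `"control"` when
#'   present, else the first level encountered).
#' @param welch use Welch's t instead of the pooled-variance Student t.
#' @return data.frame row: `test_used`, `statistic`, `p_raw`, group
#'   means and SDs, group ns.
#' @export
compare_groups <- function(values, groups, gate = NULL, reference = NULL,
                           welch = FALSE) {
  stopifnot(length(values) == length(groups))
  gl <- unique(as.character(groups))
  if (length(gl) != 2) stop("need exactly 2 non-empty groups")
  if (is.null(reference)) reference <- if ("control" %in% gl) "control" else gl[1]
  other <- setdiff(gl, reference)
  x <- values[groups == reference]; y <- values[groups == other]
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (is.null(gate)) gate <- normality_gate(values, groups)
  if (gate == "normal") {
    if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
      stat <- 0; p <- 1; test <- "t"
    } else {
      tt <- t.test(x, y, var.equal = !welch)
      stat <- unname(tt$statistic); p <- tt$p.value; test <- "t"
    }
  } else {
    mw <- mann_whitney_z(x, y)
    stat <- mw$statistic; p <- mw$p; test <- "mann_whitney"
  }
  data.frame(test_used = test, statistic = stat, p_raw = p,
             mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
             mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y),
             group_1 = reference, group_2 = other,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' One degree of freedom, no continuity correction (the form that
#' reproduces printed sex-by-group statistics in the source cohort
#' tables). Invariant to transposing the table.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1, p = ct$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length/order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Group comparison over a family of variables with FDR correction
#'
#' Applies [normality_gate()] + [compare_groups()] to each column of
#' `mat` and adjusts the raw p-values with Benjamini-Hochberg across the
#' family (all columns).
#'
#' @param mat numeric matrix, subjects x variables.
#' @param groups group labels aligned with rows.
#' @param welch see [compare_groups()].
#' @return data.frame with one row per variable: `variable`,
#'   `test_used`, `statistic`, `p_raw`, `p_fdr`, group summaries.
#' @export
compare_groups_family <- function(mat, groups, welch = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) == length(groups))
  rows <- lapply(seq_len(ncol(mat)), function(j) {
    r <- compare_groups(mat[, j], groups, welch = welch)
    cbind(variable = colnames(mat)[j], r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out
}

#' Pearson correlations between network metrics and clinical scores
#'
#' Correlates each metric column with each clinical column over the same
#' subjects (intended for patients only), reporting Pearson r and the
#' two-sided p-value, with Benjamini-Hochberg adjustment across each
#' metric's family of tested pairs.
#'
#' @param metrics numeric matrix, subjects x metric variables (e.g.
#'   nodal AUC values).
#' @param clinical numeric matrix or data.frame, subjects x clinical
#'   scores; pairs with fewer than 3 complete observations are skipped.
#' @return data.frame: `metric`, `clinical`, `n`, `pearson_r`, `p_raw`,
#'   `p_fdr`.
#' @export
correlate_clinical <- function(metrics, clinical) {
  metrics <- as.matrix(metrics)
  clinical <- as.data.frame(clinical)
  stopifnot(nrow(metrics) == nrow(clinical))
  rows <- list()
  for (j in seq_len(ncol(metrics))) {
    for (k in seq_len(ncol(clinical))) {
      x <- metrics[, j]; y <- clinical[[k]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) next
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
        stop("zero variance in correlation pair ",
             colnames(metrics)[j], " x ", names(clinical)[k])
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1]] <-
        data.frame(metric = colnames(metrics)[j],
                   clinical = names(clinical)[k], n = sum(ok),
                   pearson_r = unname(ct$estimate), p_raw = ct$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(metric = character(0), clinical = character(0),
                      n = integer(0), pearson_r = numeric(0),
                      p_raw = numeric(0), p_fdr = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out
}
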