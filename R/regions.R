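#' Region rosters and the 74-node network roster
#'
#' The cortical roster is the 34-region Desikan-Killiany parcellation
#' (per hemisphere); the subcortical roster contains the six structures
#' used for volumetry (putamen, caudate, thalamus, pallidum, hippocampus,
#' amygdala). After bilateral averaging, a subject contributes one network
#' node per (region, feature class): 34 cortical thickness nodes, 34
#' cortical surface-area nodes, and 6 subcortical volume nodes, 74 in all.
#'
#' Node order is fixed and documented: thickness nodes in alphabetical
#' region order (1-34), then area nodes (35-68), then volume nodes
#' (69-74). The same roster ships as a plain-text file in
#' `inst/extdata/node_roster.tsv`.
#'
#' @return `dk_cortical_regions()` and `subcortical_regions()` return
#'   character vectors of canonical (lower-case, alphanumeric) region
#'   names. `node_roster()` returns a data.frame with columns
#'   `node` (1-74), `region`, `feature_class`, and `label`
#'   (`"<region>_<feature_class>"`).
#' @examples
#' nrow(node_roster())   # 74
#' @export
dk_cortical_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' @rdname dk_cortical_regions
#' @export
subcortical_regions <- function() {
  c("amygdala", "caudate", "hippocampus", "pallidum", "putamen", "thalamus")
}

#' @rdname dk_cortical_regions
#' @export
node_roster <- function() {
  ctx <- dk_cortical_regions()
  sub <- subcortical_regions()
  region <- c(ctx, ctx, sub)
  feature_class <- c(rep("thickness", length(ctx)), rep("area", length(ctx)),
                     rep("volume", length(sub)))
  data.frame(node = seq_along(region), region = region,
             feature_class = feature_class,
             label = paste(region, feature_class, sep = "_"),
             stringsAsFactors = FALSE)
}

#' @keywords internal
feature_classes <- function() c("thickness", "area", "volume")

# canonicalize a region token: lower-case, strip non-alphanumerics, apply
# the alias map for common FreeSurfer spellings
#' @keywords internal
canonical_region <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  aliases <- c(thalamusproper = "thalamus",
               transversetemporalgyrus = "transversetemporal")
  hit <- match(key, names(aliases))
  ifelse(is.na(hit), key, unname(aliases[hit]))
}

# split a region token that may carry a hemisphere prefix such as
# "ctx-lh-precuneus", "Left-Thalamus-Proper", "lh_bankssts".
# Returns list(region=..., hemisphere = "left"/"right"/NA)
#' @keywords internal
split_hemisphere_prefix <- function(x) {
  low <- tolower(x)
  hemi <- rep(NA_character_, length(x))
  rest <- low
  pat_l <- "^(ctx[-_.]?)?(lh|left)[-_.]"
  pat_r <- "^(ctx[-_.]?)?(rh|right)[-_.]"
  is_l <- grepl(pat_l, low)
  is_r <- grepl(pat_r, low)
  hemi[is_l] <- "left"
  hemi[is_r] <- "right"
  rest[is_l] <- sub(pat_l, "", low[is_l])
  rest[is_r] <- sub(pat_r, "", low[is_r])
  list(region = canonical_region(rest), hemisphere = hemi)
}
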