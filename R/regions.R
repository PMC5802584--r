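#' Define the set of analysis regions and the reference region
#'
#' A `region_set` fixes the ordered list of analysis regions (the columns of a
#' cohort DVR table and the rows/columns of every correlation matrix) together
#' with the reference region used as the DVR denominator. The reference region
#' is never itself an analysis region.
#'
#' @param names Character vector of unique region labels (length >= 1;
#'   pairwise operations additionally require >= 2).
#' @param reference Single region label used as the reference (default
#'   `"cerebellum"`); must not appear in `names`.
#' @return An object of class `region_set` with elements `names` and
#'   `reference`.
#' @seealso [default_regions()] for the shipped 36-region atlas ordering.
#' @export
#' @examples
#' rs <- region_set(c("amygdala", "hippocampus"))
#' rs$reference
region_set <- function(names, reference = "cerebellum") {
  names <- as.character(names)
  if (length(names) < 1L) stop_("a region set needs at least 1 region")
  if (anyDuplicated(names)) stop_("region names must be unique")
  if (!is.character(reference) || length(reference) != 1L)
    stop_("'reference' must be a single region label")
  if (reference %in% names)
    stop_("reference region '", reference, "' must not be an analysis region")
  structure(list(names = names, reference = reference), class = "region_set")
}

#' Default 36-region atlas-style region set
#'
#' Hammers-atlas-style labels for the 36 analysis regions used by the default
#' cohort configuration, with the cerebellum as reference. The first ten are
#' the temporal-lobe structures with distinct default group means; the
#' remainder are frontal, cingulate, parietal, occipital, insular and
#' subcortical structures. Any region set of >= 2 unique labels can be
#' substituted via [region_set()].
#'
#' @return A `region_set` of length 36.
#' @export
default_regions <- function() {
  region_set(c(
    # temporal lobe
    "hippocampus",
    "amygdala",
    "anterior_temporal_lobe_medial",
    "anterior_temporal_lobe_lateral",
    "parahippocampal_ambient_gyri",
    "superior_temporal_gyrus_posterior",
    "middle_inferior_temporal_gyrus",
    "fusiform_gyrus",
    "posterior_temporal_lobe",
    "superior_temporal_gyrus_anterior",
    # cingulate / orbitofrontal
    "anterior_cingulate_gyrus",
    "subgenual_anterior_cingulate",
    "presubgenual_frontal_cortex",
    "posterior_cingulate_gyrus",
    "straight_gyrus",
    "middle_orbitofrontal_cortex",
    "posterior_orbitofrontal_cortex",
    "anterior_orbital_gyrus",
    "lateral_orbital_gyrus",
    # frontal
    "superior_frontal_gyrus",
    "middle_frontal_gyrus",
    "inferior_frontal_gyrus",
    "precentral_gyrus",
    # parietal
    "postcentral_gyrus",
    "superior_parietal_gyrus",
    "inferiolateral_parietal_lobe",
    # occipital
    "cuneus",
    "lingual_gyrus",
    "lateral_occipital_lobe",
    # insula and subcortical
    "insula",
    "nucleus_accumbens",
    "caudate",
    "putamen",
    "pallidum",
    "thalamus",
    "substantia_nigra"
  ), reference = "cerebellum")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", length(x$names), " analysis regions, reference: ",
      x$reference, "\n", sep = "")
  cat(" ", paste(utils::head(x$names, 6), collapse = ", "),
      if (length(x$names) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_region_names <- function(regions) {
  if (inherits(regions, "region_set")) regions$names else as.character(regions)
}

#' Enumerate unique region pairs
#'
#' All R(R-1)/2 unordered region pairs, emitted in deterministic
#' lexicographic-by-index order (pair (i, j) with i < j in region-set order).
#' For the default 36-region set this yields 630 pairs, the unit of the
#' per-pair correlation comparison.
#'
#' @param regions A `region_set` or character vector of >= 2 region labels.
#' @return A data frame with columns `region_a`, `region_b` (character) in
#'   region-set order, `region_a` preceding `region_b`.
#' @export
#' @examples
#' nrow(unique_pairs(default_regions()))  # 630
unique_pairs <- function(regions) {
  nm <- as_region_names(regions)
  r <- length(nm)
  if (r < 2L) stop_("need at least 2 regions to form pairs")
  idx <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(region_a = nm[idx[, 1L]], region_b = nm[idx[, 2L]],
             stringsAsFactors = FALSE)
}
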