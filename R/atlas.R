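# AAL-90 region table and reduced-atlas helpers.

# The 45 bilateral structures of the AAL parcellation (cerebellum excluded),
# in conventional atlas order, with the lobe-like block each belongs to.
# Blocks drive the default community structure of the synthetic generator.
.aal_structures <- data.frame(
  name = c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  ),
  abbreviation = c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING", "SOG",
    "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG", "PCUN", "PCL",
    "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup", "MTG", "TPOmid",
    "ITG"
  ),
  block = c(
    "sensorimotor", "prefrontal", "orbitofrontal", "prefrontal",
    "orbitofrontal", "prefrontal", "prefrontal", "orbitofrontal",
    "sensorimotor", "sensorimotor", "orbitofrontal", "prefrontal",
    "orbitofrontal", "orbitofrontal", "limbic", "limbic", "limbic",
    "limbic", "limbic", "limbic", "limbic", "occipital", "occipital",
    "occipital", "occipital", "occipital", "occipital", "occipital",
    "sensorimotor", "parietal", "parietal", "parietal", "parietal",
    "parietal", "sensorimotor", "subcortical", "subcortical",
    "subcortical", "subcortical", "temporal", "temporal", "temporal",
    "temporal", "temporal", "temporal"
  ),
  stringsAsFactors = FALSE
)

#' The built-in AAL 90-region atlas
#'
#' Returns the 90-region automated anatomical labeling (AAL) parcellation of
#' the cerebrum (cerebellum excluded): 45 bilateral structures, interleaved so
#' that the left region of each homotopic pair immediately precedes its right
#' homolog (odd `region_id` = left, even = right).
#'
#' @return A `region_atlas`: a data frame with one row per region and columns
#'   `region_id` (1..90), `name` (structure name, e.g. `"Precentral"`),
#'   `abbreviation` (unique, hemisphere-suffixed, e.g. `"PreCG.L"`),
#'   `hemisphere` (`"L"` or `"R"`), `homotopic_partner_id` (the region id of
#'   the mirror-image region in the opposite hemisphere) and `block` (one of
#'   eight lobe-like community labels, mirrored across hemispheres).
#' @examples
#' atlas <- aal_region_table()
#' table(atlas$hemisphere)
#' @export
aal_region_table <- function() {
  s <- .aal_structures
  n <- nrow(s)
  atlas <- data.frame(
    region_id = seq_len(2L * n),
    name = rep(s$name, each = 2L),
    abbreviation = paste(rep(s$abbreviation, each = 2L),
                         rep(c("L", "R"), n), sep = "."),
    hemisphere = rep(c("L", "R"), n),
    homotopic_partner_id = as.integer(
      seq_len(2L * n) + rep(c(1L, -1L), n)),
    block = rep(s$block, each = 2L),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' Validate a region atlas
#'
#' Checks the structural invariants any atlas used by the pipeline must hold:
#' unique ids and abbreviations, hemisphere-balanced, and homotopic pairing an
#' involution into the opposite hemisphere.
#'
#' @param atlas a data frame with the columns of [aal_region_table()].
#' @return the atlas, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_atlas <- function(atlas) {
  required <- c("region_id", "name", "abbreviation", "hemisphere",
                "homotopic_partner_id")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0L)
    stop("atlas is missing column(s): ", paste(missing, collapse = ", "))
  n <- nrow(atlas)
  if (anyDuplicated(atlas$region_id) || anyDuplicated(atlas$abbreviation))
    stop("atlas region ids and abbreviations must be unique")
  if (!all(atlas$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  if (sum(atlas$hemisphere == "L") != n / 2)
    stop("atlas must have equally many regions per hemisphere")
  idx <- match(atlas$homotopic_partner_id, atlas$region_id)
  if (anyNA(idx))
    stop("homotopic_partner_id must reference a region in the atlas")
  if (!all(atlas$homotopic_partner_id[idx] == atlas$region_id))
    stop("homotopic pairing must be an involution")
  if (any(atlas$hemisphere[idx] == atlas$hemisphere))
    stop("homotopic partners must lie in opposite hemispheres")
  invisible(atlas)
}

#' Build a reduced atlas from a subset of regions
#'
#' Keeps whole homotopic pairs so the reduced atlas preserves the pairing
#' involution. Useful for fast simulation studies on a handful of regions.
#'
#' @param n_pairs number of homotopic pairs to keep (the first `n_pairs`
#'   structures in atlas order).
#' @param atlas the full atlas to subset; defaults to [aal_region_table()].
#' @return a `region_atlas` with `2 * n_pairs` rows and renumbered ids.
#' @export
reduced_atlas <- function(n_pairs, atlas = aal_region_table()) {
  stopifnot(n_pairs >= 1L, 2L * n_pairs <= nrow(atlas))
  out <- atlas[seq_len(2L * n_pairs), , drop = FALSE]
  out$region_id <- seq_len(nrow(out))
  out$homotopic_partner_id <- as.integer(
    out$region_id + rep(c(1L, -1L), n_pairs))
  rownames(out) <- NULL
  class(out) <- c("region_atlas", "data.frame")
  validate_atlas(out)
  out
}

# Number of unordered region pairs for an atlas of n regions.
n_region_pairs <- function(atlas) {
  n <- nrow(atlas)
  n * (n - 1L) / 2L
}
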