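#' Parameter keys of the multiparametric mutation score
#'
#' Eighteen missense parameters (two stability, two conservation, eight
#' location, six amino-acid-property changes) plus four non-missense allele
#' parameters used for compound heterozygotes.
#'
#' @param include_nonmissense Include the four non-missense keys (default
#'   TRUE).
#' @return Character vector of parameter keys.
#' @export
mms_parameters <- function(include_nonmissense = TRUE) {
  p <- c("destabilizing", "stabilizing", "cons_residue", "cons_substitution",
         "helix", "sheet", "c_term", "active_site", "active_region",
         "nterm_plp", "h_interface", "dimer_interface",
         "d_polarity", "d_charge", "d_aromaticity", "d_proline",
         "d_codon", "d_size")
  if (include_nonmissense) {
    p <- c(p, "deletion", "nonsense_frameshift", "intronic_splice",
           "mito_leader")
  }
  p
}

#' Unit weights of the unweighted score
#'
#' Every parameter carries weight +1 except conservation of substitution,
#' which counts -1 (a substitution that evolution tolerates argues against
#' pathogenicity).
#'
#' @return Named numeric vector over [mms_parameters()].
#' @export
unit_weights <- function() {
  w <- stats::setNames(rep(1, length(mms_parameters())), mms_parameters())
  w["cons_substitution"] <- -1
  w
}

#' Feature-derivation configuration
#'
#' Thresholds that turn the raw annotation facts into binary parameters.
#' Defaults are calibrated against the published worked examples: a
#' destabilizing call below -1.5 kcal/mol; conserved residue at grade >= 7
#' of 9; conserved substitution at BLOSUM62 >= 0 (so A->V counts, R->S and
#' T->M do not); C-terminal span from residue 506 (R515 is described as
#' C-terminal); codon-availability change at |delta codons| >= 4 (T->M,
#' delta 3, must not trigger); size change at |delta volume| >= 50 A^3
#' (A->V 51.4 and R->S 84.4 trigger, T->M 46.8 does not).
#'
#' @param ddg_destabilizing ddG below which a mutation is destabilizing
#'   (kcal/mol).
#' @param ddg_stabilizing ddG at or above which a mutation is stabilizing.
#' @param conserved_grade Minimum conservation grade (1-9 scale) for the
#'   conserved-residue parameter.
#' @param blosum_conserved Minimum BLOSUM62 score for the
#'   conserved-substitution parameter.
#' @param c_term_start First position counted as C-terminal.
#' @param codon_delta Minimum absolute codon-count change.
#' @param size_delta Minimum absolute residue-volume change (A^3).
#' @param protein_length Precursor length (mitochondrial leader included).
#' @return A list of class `gp_feature_config`.
#' @export
feature_config <- function(ddg_destabilizing = -1.5,
                           ddg_stabilizing = 1.5,
                           conserved_grade = 7,
                           blosum_conserved = 0,
                           c_term_start = 506,
                           codon_delta = 4,
                           size_delta = 50,
                           protein_length = 1020) {
  cfg <- list(ddg_destabilizing = ddg_destabilizing,
              ddg_stabilizing = ddg_stabilizing,
              conserved_grade = conserved_grade,
              blosum_conserved = blosum_conserved,
              c_term_start = c_term_start,
              codon_delta = codon_delta,
              size_delta = size_delta,
              protein_length = protein_length)
  class(cfg) <- "gp_feature_config"
  cfg
}

#' Classify a predicted stability effect
#'
#' Bins the predicted folding free-energy change: below -5 kcal/mol very
#' destabilizing; -5 to -1.5 destabilizing; the closed band -1.5 to 1.5
#' negligible; 1.5 to 5 stabilizing; above 5 very stabilizing.
#'
#' @param ddg Numeric vector of predicted ddG (kcal/mol).
#' @return Factor with the five ordered bins.
#' @examples
#' classify_stability(c(-2.47, 0, 6))
#' @export
classify_stability <- function(ddg) {
  if (any(!is.finite(ddg))) stop("ddg must be finite")
  cut(ddg, breaks = c(-Inf, -5, -1.5, 1.5, 5, Inf),
      labels = c("very_destabilizing", "destabilizing", "negligible",
                 "stabilizing", "very_stabilizing"),
      right = FALSE) -> bins
  # closed negligible band: -1.5 and 1.5 are negligible; cut(right = FALSE)
  # already places -1.5 in negligible, move exact 1.5 down from stabilizing
  bins[ddg == 1.5] <- "negligible"
  # the stabilizing band is closed above: exactly 5 is stabilizing, not very
  bins[ddg == 5] <- "stabilizing"
  bins
}

#' Derive the 18-parameter indicator vector of a missense mutation
#'
#' Applies the thresholds of [feature_config()] to one annotation row and
#' returns the full 22-slot parameter vector (the four non-missense slots
#' are zero for a missense allele).
#'
#' @param ann A single-row annotation data frame (see
#'   [read_annotation_table()]) or a list with the same fields.
#' @param cfg A [feature_config()].
#' @return Named numeric vector over [mms_parameters()] with entries 0/1.
#' @examples
#' ann <- read_annotation_table(system.file("extdata",
#'   "annotations_synthetic_examples.tsv", package = "glypheno"))
#' v <- derive_parameter_vector(ann[ann$mutation == "R515S", ])
#' names(v)[v == 1]
#' @export
derive_parameter_vector <- function(ann, cfg = feature_config()) {
  ann <- as.list(ann)
  if (!valid_aa(ann$ref_aa) || !valid_aa(ann$alt_aa)) {
    stop("unknown amino-acid letter: ", ann$ref_aa, "/", ann$alt_aa)
  }
  props <- aa_properties()
  ref <- ann$ref_aa; alt <- ann$alt_aa
  v <- stats::setNames(numeric(length(mms_parameters())), mms_parameters())
  v["destabilizing"]   <- as.numeric(ann$ddg_kcal_mol < cfg$ddg_destabilizing)
  v["stabilizing"]     <- as.numeric(ann$ddg_kcal_mol >= cfg$ddg_stabilizing)
  v["cons_residue"]    <- as.numeric(ann$conservation_grade >= cfg$conserved_grade)
  v["cons_substitution"] <- as.numeric(ann$blosum62 >= cfg$blosum_conserved)
  v["helix"]           <- as.numeric(ann$sec_struct == "helix")
  v["sheet"]           <- as.numeric(ann$sec_struct == "sheet")
  v["c_term"]          <- as.numeric(ann$position >= cfg$c_term_start)
  v["active_site"]     <- as.numeric(isTRUE_vec(ann$active_site))
  v["active_region"]   <- as.numeric(isTRUE_vec(ann$active_region_7A))
  v["nterm_plp"]       <- as.numeric(isTRUE_vec(ann$nterm_plp))
  v["h_interface"]     <- as.numeric(isTRUE_vec(ann$h_interface))
  v["dimer_interface"] <- as.numeric(isTRUE_vec(ann$dimer_interface))
  v["d_polarity"]      <- as.numeric(props$polar[ref] != props$polar[alt])
  v["d_charge"]        <- as.numeric(props$charge[ref] != props$charge[alt])
  v["d_aromaticity"]   <- as.numeric(props$aromatic[ref] != props$aromatic[alt])
  v["d_proline"]       <- as.numeric(ref == "P" || alt == "P")
  v["d_codon"]         <- as.numeric(abs(props$codons[ref] - props$codons[alt]) >= cfg$codon_delta)
  v["d_size"]          <- as.numeric(abs(props$volume[alt] - props$volume[ref]) >= cfg$size_delta)
  v
}

#' Allele specification
#'
#' A patient allele: either a missense mutation carrying an annotation row,
#' or one of the four non-missense classes (which carry no annotation and
#' score only on their class parameter).
#'
#' @param class One of `"missense"`, `"deletion"`, `"nonsense_frameshift"`,
#'   `"intronic_splice"`, `"mito_leader"`.
#' @param annotation Single-row annotation (required iff missense).
#' @return A list of class `gp_allele`.
#' @export
allele_spec <- function(class, annotation = NULL) {
  class <- match.arg(class, allele_classes())
  if (class == "missense" && is.null(annotation)) {
    stop("a missense allele requires an annotation")
  }
  if (class != "missense" && !is.null(annotation)) {
    stop("a non-missense allele carries no annotation")
  }
  structure(list(class = class, annotation = annotation),
            class = "gp_allele")
}

allele_vector <- function(allele, cfg = feature_config()) {
  v <- stats::setNames(numeric(length(mms_parameters())), mms_parameters())
  if (allele$class == "missense") {
    v <- derive_parameter_vector(allele$annotation, cfg)
  } else {
    v[allele$class] <- 1
  }
  v
}

check_parvec <- function(v) {
  keys <- mms_parameters()
  if (!all(keys %in% names(v))) stop("parameter vector has missing keys")
  v[keys]
}

#' Multiparametric mutation score of a homozygous genotype
#'
#' Signed sum of the 18 binary parameters (+1 each, -1 for the conserved
#' substitution parameter). Homozygous vectors must be 0/1 with all four
#' non-missense slots zero.
#'
#' @param v Parameter vector from [derive_parameter_vector()].
#' @return Numeric score (an integer value in -1..17).
#' @examples
#' ann <- read_annotation_table(system.file("extdata",
#'   "annotations_synthetic_examples.tsv", package = "glypheno"))
#' mms_homozygous(derive_parameter_vector(ann[1, ]))
#' @export
mms_homozygous <- function(v) {
  v <- check_parvec(v)
  if (!all(v %in% c(0, 1))) {
    stop("homozygous parameter vectors must be 0/1 (got a composite vector?)")
  }
  nm <- c("deletion", "nonsense_frameshift", "intronic_splice", "mito_leader")
  if (any(v[nm] != 0)) {
    stop("homozygous vectors must have zero non-missense parameters")
  }
  sum(unit_weights() * v)
}

#' Composite parameter vector of a compound heterozygote
#'
#' Each of the 18 missense parameters scores 1 if both alleles meet the
#' condition, 0.5 if one does, 0 if neither; a non-missense allele
#' contributes nothing to the missense parameters and 0.5 to its own class
#' parameter. At least one allele must be missense.
#'
#' @param a1,a2 [allele_spec()] objects.
#' @param cfg A [feature_config()].
#' @return Composite parameter vector with entries in 0, 0.5, 1.
#' @export
combine_heterozygous <- function(a1, a2, cfg = feature_config()) {
  stopifnot(inherits(a1, "gp_allele"), inherits(a2, "gp_allele"))
  if (a1$class != "missense" && a2$class != "missense") {
    stop("unsupported genotype: at least one allele must be missense")
  }
  0.5 * (allele_vector(a1, cfg) + allele_vector(a2, cfg))
}

#' Multiparametric mutation score of any parameter vector
#'
#' Unit-weighted signed sum; for a composite heterozygous vector this equals
#' the mean of the two per-allele scores (a non-missense allele scores 1 on
#' its class parameter).
#'
#' @param v Parameter vector (homozygous 0/1 or composite 0/0.5/1).
#' @return Numeric score.
#' @export
mms_score <- function(v) {
  v <- check_parvec(v)
  sum(unit_weights() * v)
}

#' Severity band of a mutation score
#'
#' Scores of 1-2 are mild, 3-4 moderate, and 5 or more severe; composite
#' half-point scores fall in the band below their ceiling (2.5 is mild, 4.5
#' moderate). Scores below 1 are reported distinctly as `below_scale`.
#'
#' @param score Numeric MMS/WMMS values.
#' @return Factor with levels below_scale, mild, moderate, severe.
#' @examples
#' classify_mms(c(0, 2.5, 3.5, 5))
#' @export
classify_mms <- function(score) {
  if (any(!is.finite(score))) stop("score must be finite")
  out <- ifelse(score < 1, "below_scale",
         ifelse(score < 3, "mild",
         ifelse(score < 5, "moderate", "severe")))
  factor(out, levels = c("below_scale", "mild", "moderate", "severe"))
}
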