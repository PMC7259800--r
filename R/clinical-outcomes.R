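#' Legal score sets for the four major disease domains
#'
#' Severity in each of the four major NKH disease domains is scored on a
#' Likert-like 0-3 scale. Cognitive disorders and muscle/movement control are
#' linear 0-3; seizures step non-linearly from 1 (controlled) to 3
#' (intractable) with no value 2; brain malformation is a presence/absence
#' binary scored 0 or 3.
#'
#' @return Named list of integer vectors, one per domain.
#' @export
domain_scales <- function() {
  list(
    seizures = c(0L, 1L, 3L),
    cognitive = 0:3,
    brain_malformation = c(0L, 3L),
    muscle_movement = 0:3
  )
}

domain_names <- function() names(domain_scales())

#' Symptom vocabulary
#'
#' The packaged vocabulary maps the 58 unique symptom terms collected from
#' published NKH case reports to eleven disease categories. A user-supplied
#' TSV with columns `term` and `category` can replace or extend it.
#'
#' @param path Optional path to a TSV (`term`, `category`) overriding the
#'   packaged vocabulary.
#' @return A data frame with columns `term` and `category`.
#' @export
symptom_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_symptoms.tsv", package = "glypheno")
  }
  voc <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "category") %in% names(voc)))
  if (anyDuplicated(tolower(voc$term))) {
    stop("symptom vocabulary contains duplicated terms")
  }
  voc
}

#' Map a free-text symptom to its disease category
#'
#' Lookup is exact up to case folding and surrounding whitespace; terms not
#' in the vocabulary return `"unclassified"` rather than a guess (no fuzzy
#' matching).
#'
#' @param term Character vector of symptom terms.
#' @param vocabulary A vocabulary data frame from [symptom_vocabulary()].
#' @return Character vector of categories.
#' @examples
#' map_symptom_to_domain("Intractable seizures")
#' map_symptom_to_domain("Hypotonia")
#' @export
map_symptom_to_domain <- function(term, vocabulary = symptom_vocabulary()) {
  key <- tolower(trimws(term))
  idx <- match(key, tolower(trimws(vocabulary$term)))
  out <- vocabulary$category[idx]
  out[is.na(idx)] <- "unclassified"
  out
}

validate_domain_scores <- function(df, context = "cohort") {
  scales <- domain_scales()
  for (d in names(scales)) {
    v <- df[[d]]
    bad <- which(!is.na(v) & !(v %in% scales[[d]]))
    if (length(bad)) {
      stop(sprintf("illegal %s value %s in %s row %d (legal: %s)",
                   d, v[bad[1]], context, bad[1],
                   paste(scales[[d]], collapse = ",")))
    }
  }
  invisible(df)
}

#' Clinical outcome score (COS)
#'
#' Sums the scored (non-missing) domain values of each patient record. The
#' score is not rescaled for unscored domains: a patient scored 3/NA/3/3
#' receives COS 9. A record with all four domains unscored yields `NA`.
#' Maximal score is 12 (all four domains at 3).
#'
#' @param cohort Data frame with columns `seizures`, `cognitive`,
#'   `brain_malformation`, `muscle_movement` (NA = unscored).
#' @return Integer vector of COS values (NA where undefined).
#' @examples
#' compute_cos(data.frame(seizures = 3, cognitive = NA,
#'                        brain_malformation = 3, muscle_movement = 3))
#' @export
compute_cos <- function(cohort) {
  validate_domain_scores(cohort)
  m <- as.matrix(cohort[, domain_names(), drop = FALSE])
  n_scored <- rowSums(!is.na(m))
  cos <- rowSums(m, na.rm = TRUE)
  cos[n_scored == 0] <- NA
  as.integer(cos)
}

#' Cohort eligibility filter
#'
#' Applies the study's two exclusion rules in order: records of deceased
#' patients are removed first (death can follow a single acute event that
#' need not reflect multi-domain severity), then records with fewer than two
#' scored domains. Row order of survivors is preserved; the filter is
#' idempotent.
#'
#' @param cohort A cohort data frame (see [read_cohort_table()]).
#' @param min_domains Minimum number of scored domains to retain (default 2).
#' @return A list with `eligible` (the retained rows) and `log` (data frame
#'   of `patient_id`, `reason` for each exclusion, in exclusion order).
#' @export
filter_cohort <- function(cohort, min_domains = 2) {
  m <- as.matrix(cohort[, domain_names(), drop = FALSE])
  n_scored <- rowSums(!is.na(m))
  deceased <- isTRUE_vec(cohort$deceased)
  log1 <- data.frame(patient_id = as.character(cohort$patient_id[deceased]),
                     reason = rep("deceased", sum(deceased)),
                     stringsAsFactors = FALSE)
  keep1 <- !deceased
  few <- keep1 & n_scored < min_domains
  log2 <- data.frame(patient_id = as.character(cohort$patient_id[few]),
                     reason = rep(sprintf("fewer than %d scored domains", min_domains),
                                  sum(few)),
                     stringsAsFactors = FALSE)
  list(eligible = cohort[keep1 & !few, , drop = FALSE],
       log = rbind(log1, log2))
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(logical(0))
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Severity class from a clinical outcome score
#'
#' COS 0 is asymptomatic, 1 up to `attenuated_max` is attenuated, and above
#' `attenuated_max` is severe. The default boundary (5) follows the gating
#' used for the allele-by-allele display of compound heterozygotes
#' (attenuated = COS 1-5, severe = COS > 5).
#'
#' @param cos Integer vector of COS values in 0..12.
#' @param attenuated_max Upper COS bound of the attenuated class (default 5).
#' @return Factor with levels asymptomatic, attenuated, severe.
#' @examples
#' classify_severity(c(0, 5, 12))
#' @export
classify_severity <- function(cos, attenuated_max = 5) {
  if (any(!is.na(cos) & (cos < 0 | cos > 12))) {
    stop("COS out of range 0..12")
  }
  out <- rep(NA_character_, length(cos))
  out[!is.na(cos) & cos == 0] <- "asymptomatic"
  out[!is.na(cos) & cos >= 1 & cos <= attenuated_max] <- "attenuated"
  out[!is.na(cos) & cos > attenuated_max] <- "severe"
  factor(out, levels = c("asymptomatic", "attenuated", "severe"))
}

#' Mean clinical outcome score per homozygous mutation
#'
#' Where several patients are homozygous for the same mutation an average
#' COS is taken; a mutation seen in one patient keeps that patient's COS.
#'
#' @param cohort Homozygous cohort data frame (allele1 == allele2).
#' @return Named numeric vector: mutation -> mean COS.
#' @examples
#' hom <- load_fixture("table4_homozygous_cos")
#' aggregate_homozygous_cos(hom)["Y164H"]
#' @export
aggregate_homozygous_cos <- function(cohort) {
  stopifnot(all(cohort$zygosity == "homozygous"))
  cos <- compute_cos(cohort)
  keep <- !is.na(cos)
  tapply(cos[keep], cohort$allele1[keep], mean)
}
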