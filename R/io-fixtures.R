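cohort_columns <- function() {
  c("patient_id", "zygosity", "allele1", "allele2",
    "allele1_class", "allele2_class", "sex", "age_years", "deceased",
    "seizures", "cognitive", "brain_malformation", "muscle_movement")
}

allele_classes <- function() {
  c("missense", "deletion", "nonsense_frameshift", "intronic_splice",
    "mito_leader")
}

#' Read a patient cohort table
#'
#' Reads a TSV/CSV cohort with the standard column set and validates it.
#' Blank domain cells are read as `NA` ("unscored"); an explicit 0 means the
#' domain was reported asymptomatic. The two states are distinct and blanks
#' are never coerced to 0.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param source_label Label recorded on the returned table (e.g. a table
#'   name or `"synthetic"`).
#' @return A `gp_cohort` data frame with a `source_label` attribute.
#' @export
read_cohort_table <- function(path, dialect = c("tsv", "csv"),
                              source_label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  as_gp_cohort(df, source_label = source_label)
}

#' Validate and classify a cohort data frame
#'
#' @param df Data frame with the columns of [cohort_columns()].
#' @param source_label Provenance label.
#' @return The validated data frame with class `gp_cohort`.
#' @export
as_gp_cohort <- function(df, source_label = "unspecified") {
  df$patient_id <- as.character(df$patient_id)
  if (nrow(df) && anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id in cohort table: ",
         df$patient_id[anyDuplicated(df$patient_id)])
  }
  bad_zyg <- !(df$zygosity %in% c("homozygous", "compound_heterozygous"))
  if (any(bad_zyg)) {
    stop("illegal zygosity in row ", which(bad_zyg)[1], ": ",
         df$zygosity[which(bad_zyg)[1]])
  }
  for (col in c("allele1_class", "allele2_class")) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% allele_classes())
    if (any(bad)) {
      stop("illegal ", col, " in row ", which(bad)[1], ": ",
           df[[col]][which(bad)[1]])
    }
  }
  hom <- df$zygosity == "homozygous"
  if (any(hom & df$allele1 != df$allele2)) {
    stop("homozygous record with differing alleles in row ",
         which(hom & df$allele1 != df$allele2)[1])
  }
  for (d in domain_names()) df[[d]] <- as.integer(df[[d]])
  df$deceased <- isTRUE_vec(df$deceased)
  validate_domain_scores(df, context = source_label)
  class(df) <- c("gp_cohort", "data.frame")
  attr(df, "source_label") <- source_label
  df
}

#' Write a cohort table
#'
#' Writes TSV with unscored domains as empty cells, so that
#' `read_cohort_table(write_cohort_table(x))` round-trips every cell.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.gp_cohort <- function(x, ...) {
  cat(sprintf("Patient cohort (%s): %d records (%d homozygous, %d compound heterozygous)\n",
              attr(x, "source_label") %||% "unlabelled", nrow(x),
              sum(x$zygosity == "homozygous"),
              sum(x$zygosity == "compound_heterozygous")))
  print(as.data.frame(x), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_files <- function() {
  c(table1_regions = "table1_regions.tsv",
    table2_symptoms = "table2_symptoms.tsv",
    table4_homozygous_cos = "table4_homozygous_cos.tsv",
    table5_heterozygous_cos = "table5_heterozygous_cos.tsv",
    table6_homozygous_mms = "table6_homozygous_mms.tsv",
    table7_heterozygous_mms = "table7_heterozygous_mms.tsv",
    table8_exac_controls = "table8_exac_controls.tsv",
    table9_dbgap_controls = "table9_dbgap_controls.tsv",
    table10_weights = "table10_weights.tsv")
}

#' Load a packaged data table
#'
#' Verbatim transcriptions of the published cohort, control and weight
#' tables ship with the package. Patient identifiers are preserved per table
#' (they drift between the clinical-score and mutation-score tables in the
#' source) and no cross-table reconciliation is attempted; each table
#' carries its own `source_label`.
#'
#' @param name One of `table1_regions`, `table2_symptoms`,
#'   `table4_homozygous_cos`, `table5_heterozygous_cos`,
#'   `table6_homozygous_mms`, `table7_heterozygous_mms`,
#'   `table8_exac_controls`, `table9_dbgap_controls`, `table10_weights`.
#' @return A data frame; the two cohort tables are returned as `gp_cohort`.
#' @examples
#' load_fixture("table10_weights")[1:3, ]
#' @export
load_fixture <- function(name) {
  files <- fixture_files()
  if (!name %in% names(files)) {
    stop("unknown fixture '", name, "'; valid keys: ",
         paste(names(files), collapse = ", "))
  }
  path <- system.file("extdata", files[[name]], package = "glypheno")
  if (name %in% c("table4_homozygous_cos", "table5_heterozygous_cos")) {
    return(read_cohort_table(path, source_label = name))
  }
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                    quote = "")
}

#' Read a mutation annotation table
#'
#' One row per missense mutation with the structural, conservation and
#' stability facts from which the 18 parameters are derived. Region flag
#' columns are logical; `ddg_kcal_mol` is the externally predicted folding
#' free-energy change.
#'
#' @param path TSV path.
#' @return Data frame of annotations, validated.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  req <- c("mutation", "position", "ref_aa", "alt_aa", "ddg_kcal_mol",
           "conservation_grade", "blosum62", "sec_struct", "active_site",
           "active_region_7A", "nterm_plp", "h_interface", "dimer_interface")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("active_site", "active_region_7A", "nterm_plp",
                "h_interface", "dimer_interface")) {
    df[[col]] <- isTRUE_vec(df[[col]])
  }
  validate_annotations(df)
  df
}

validate_annotations <- function(df, protein_length = 1020) {
  stopifnot(is.numeric(df$position), is.numeric(df$ddg_kcal_mol))
  if (any(!valid_aa(df$ref_aa)) || any(!valid_aa(df$alt_aa))) {
    stop("unknown amino-acid letter in annotation table")
  }
  if (any(df$ref_aa == df$alt_aa)) stop("ref_aa equals alt_aa")
  if (any(df$position < 1 | df$position > protein_length)) {
    stop("position outside 1..", protein_length)
  }
  if (any(!df$conservation_grade %in% 1:9)) {
    stop("conservation_grade outside 1..9")
  }
  if (any(!df$sec_struct %in% c("helix", "sheet", "loop"))) {
    stop("sec_struct must be helix, sheet or loop")
  }
  if (any(df$active_site & df$active_region_7A)) {
    stop("active_site and active_region_7A are mutually exclusive")
  }
  invisible(df)
}
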