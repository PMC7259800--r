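#' Run the scoring pipeline end to end
#'
#' Thin orchestration over the package's functions: score clinical outcomes,
#' derive mutation scores, train weights, predict, and summarise statistics,
#' writing plain-text outputs. Deterministic given a fixed configuration and
#' seed.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{cohort}{a `gp_cohort` or a TSV path readable by
#'       [read_cohort_table()]}
#'     \item{annotations}{annotation data frame or TSV path (required for
#'       the mms/train/predict stages)}
#'     \item{regions}{optional region table (as
#'       `load_fixture("table1_regions")`) for the stats stage}
#'     \item{stages}{character subset of `c("cos", "mms", "train",
#'       "predict", "stats")`; empty gives an empty report}
#'     \item{train_on}{`"homozygous"` (default) or `"heterozygous"`:
#'       which genotype class supplies the training design}
#'     \item{out}{optional output directory; when given, the report is
#'       written as TSV/JSON files}
#'   }
#' @param seed Integer seed applied before any stochastic stage.
#' @return A report list (invisible when `config$out` is set).
#' @export
run_pipeline <- function(config, seed = 1) {
  stages <- config$stages %||% character(0)
  known <- c("cos", "mms", "train", "predict", "stats")
  if (length(setdiff(stages, known))) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if ("predict" %in% stages && !"train" %in% stages) {
    stop("stage dependency unmet: 'predict' requires 'train'")
  }
  if (any(c("mms", "train") %in% stages) && is.null(config$annotations)) {
    stop("stages mms/train need an annotation table")
  }
  set.seed(seed)
  report <- list(seed = seed, stages = stages)
  if (!length(stages)) return(maybe_write_report(report, config$out))

  cohort <- config$cohort
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  ann <- config$annotations
  if (is.character(ann)) ann <- read_annotation_table(ann)
  cfg_feat <- config$feature_config %||% feature_config()

  flt <- filter_cohort(cohort)
  eligible <- flt$eligible
  report$exclusions <- flt$log

  if ("cos" %in% stages) {
    eligible$cos <- compute_cos(eligible)
    eligible$severity <- as.character(classify_severity(eligible$cos))
    report$cos <- eligible[, c("patient_id", "cos", "severity")]
    report$severity_counts <- table(eligible$severity)
  }
  if ("mms" %in% stages) {
    scored <- predict_cohort(eligible, ann, unit_weights(), cfg_feat,
                             cutpoint = 4.5)
    names(scored)[names(scored) == "wmms"] <- "mms"
    report$mms <- scored[, c("patient_id", "cos", "mms")]
  }
  fit <- NULL
  if ("train" %in% stages) {
    train_on <- config$train_on %||% "homozygous"
    sub <- eligible[eligible$zygosity ==
                      if (train_on == "homozygous") "homozygous"
                      else "compound_heterozygous", , drop = FALSE]
    d <- if (train_on == "homozygous") design_homozygous(sub, ann, cfg_feat)
         else design_heterozygous(sub, ann, cfg_feat)
    if (!is.null(config$controls)) d <- stack_designs(d, config$controls)
    fit <- wmms_fit(d, provenance = paste0(train_on, "_trained"))
    report$weights <- fit$weights
    report$intercept <- fit$intercept
    report$r2 <- fit$r2
  }
  if ("predict" %in% stages) {
    report$predictions <- predict_cohort(eligible, ann, fit, cfg_feat)
  }
  if ("stats" %in% stages) {
    if (!is.null(config$regions)) {
      regions <- config$regions
      if (is.character(regions)) regions <- utils::read.delim(regions)
      report$enrichment <- region_enrichment(regions)
    }
    if (!is.null(fit)) {
      cls <- classify_severity(pmin(12L, pmax(0L, round(fit$design$y))))
      if (all(table(cls)[c("attenuated", "severe")] >= 2)) {
        report$separation <- severity_separation_ttest(predict(fit), cls)
      }
    }
  }
  maybe_write_report(report, config$out)
}

maybe_write_report <- function(report, out = NULL) {
  if (is.null(out)) return(report)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("cos", "mms", "exclusions", "predictions", "enrichment")) {
    if (!is.null(report[[nm]])) {
      utils::write.table(report[[nm]], file.path(out, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
  }
  scalars <- report[!vapply(report, is.data.frame, logical(1))]
  scalars <- lapply(scalars, function(x) {
    if (inherits(x, "gp_separation")) unclass(x) else
      if (is.table(x)) as.list(x) else x
  })
  jsonlite::write_json(scalars, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
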