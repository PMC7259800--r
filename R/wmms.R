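#' Named weight sets for scoring
#'
#' Returns a 22-slot weight vector keyed by [mms_parameters()]. The
#' `"unweighted"` set is the unit-sign vector; the two trained sets are the
#' published least-squares weights for the 18 missense parameters (the
#' trained non-missense weights were not published and are `NA` there).
#'
#' @param provenance `"unweighted"`, `"homozygous_trained"` or
#'   `"heterozygous_trained"`.
#' @return Named numeric vector with attribute `provenance`.
#' @examples
#' weight_set("homozygous_trained")["active_site"]
#' @export
weight_set <- function(provenance = c("unweighted", "homozygous_trained",
                                      "heterozygous_trained")) {
  provenance <- match.arg(provenance)
  if (provenance == "unweighted") {
    w <- unit_weights()
  } else {
    tab <- load_fixture("table10_weights")
    col <- provenance
    w <- stats::setNames(rep(NA_real_, length(mms_parameters())),
                         mms_parameters())
    w[tab$parameter] <- tab[[col]]
  }
  attr(w, "provenance") <- provenance
  w
}

#' Score a parameter vector against a weight set
#'
#' The weighted multiparametric mutation score is the dot product of the
#' parameter vector and the weights; a fitted intercept is never added (the
#' published per-mutation scores equal the bare weighted sums).
#'
#' @param v Parameter vector (keys in [mms_parameters()]).
#' @param w Weight set from [weight_set()] or [coef()] of a fitted model.
#' @return Numeric score.
#' @examples
#' ann <- read_annotation_table(system.file("extdata",
#'   "annotations_synthetic_examples.tsv", package = "glypheno"))
#' v <- derive_parameter_vector(ann[ann$mutation == "T269M", ])
#' wmms_score(v, weight_set("homozygous_trained"))
#' @export
wmms_score <- function(v, w) {
  if (is.null(names(v)) || !all(names(v) %in% names(w))) {
    stop("parameter vector and weight set do not share the same keys")
  }
  keys <- intersect(mms_parameters(), names(v))
  if (!length(keys)) {
    stop("parameter vector and weight set do not share the same keys")
  }
  used <- keys[v[keys] != 0]
  if (any(is.na(w[used]))) {
    stop("weight set has no weight for active parameter(s): ",
         paste(used[is.na(w[used])], collapse = ", "))
  }
  sum(w[used] * v[used])
}

#' Assemble a training design
#'
#' Stacks parameter vectors (one row per training unit) with their clinical
#' outcome responses. Homozygous designs use one row per unique mutation
#' with the mean COS across its patients; heterozygous designs use one row
#' per patient. Zero-COS control rows (population variants from healthy
#' individuals) are appended with [rbind()]-like semantics via the
#' `controls` argument.
#'
#' @param x Numeric matrix (units x parameters) or list of parameter
#'   vectors.
#' @param response Numeric COS per row, each in 0..12.
#' @param labels Optional row labels.
#' @return Object of class `wmms_design`.
#' @export
wmms_design <- function(x, response, labels = NULL) {
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  keys <- mms_parameters()
  if (!all(keys %in% colnames(x))) {
    stop("design must have one column per parameter key")
  }
  x <- x[, keys, drop = FALSE]
  if (length(response) != nrow(x)) stop("response length != rows")
  if (any(response < 0 | response > 12)) stop("response outside 0..12")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  rownames(x) <- labels
  structure(list(x = x, y = as.numeric(response), labels = labels),
            class = "wmms_design")
}

#' @rdname wmms_design
#' @param cohort A homozygous `gp_cohort`.
#' @param annotations Annotation table covering every allele in the cohort.
#' @param cfg A [feature_config()].
#' @export
design_homozygous <- function(cohort, annotations, cfg = feature_config()) {
  stopifnot(all(cohort$zygosity == "homozygous"))
  mean_cos <- aggregate_homozygous_cos(cohort)
  muts <- names(mean_cos)
  rows <- lapply(muts, function(m) {
    ann <- annotations[annotations$mutation == m, , drop = FALSE]
    if (nrow(ann) == 0) stop("no annotation for mutation ", m)
    derive_parameter_vector(ann[1, ], cfg)
  })
  wmms_design(rows, as.numeric(mean_cos), labels = muts)
}

#' @rdname wmms_design
#' @export
design_heterozygous <- function(cohort, annotations, cfg = feature_config()) {
  stopifnot(all(cohort$zygosity == "compound_heterozygous"))
  cos <- compute_cos(cohort)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    a1 <- cohort_allele(cohort[i, ], 1, annotations)
    a2 <- cohort_allele(cohort[i, ], 2, annotations)
    combine_heterozygous(a1, a2, cfg)
  })
  wmms_design(rows, cos, labels = cohort$patient_id)
}

#' @rdname wmms_design
#' @param d1,d2 Two `wmms_design` objects to stack (e.g. cases + controls).
#' @export
stack_designs <- function(d1, d2) {
  wmms_design(rbind(d1$x, d2$x), c(d1$y, d2$y),
              labels = make.unique(c(d1$labels, d2$labels)))
}

cohort_allele <- function(row, which_allele, annotations) {
  cls <- row[[paste0("allele", which_allele, "_class")]]
  name <- row[[paste0("allele", which_allele)]]
  if (cls == "missense") {
    ann <- annotations[annotations$mutation == name, , drop = FALSE]
    if (nrow(ann) == 0) stop("no annotation for mutation ", name)
    allele_spec("missense", ann[1, ])
  } else {
    allele_spec(cls)
  }
}

#' Fit parameter weights by least squares of COS on parameter vectors
#'
#' Ordinary least squares of the clinical outcome score on the parameter
#' matrix. Columns that are zero in every training row cannot be estimated;
#' their weights are pinned to 0 and recorded. A rank-deficient design is
#' solved by the minimum-norm least-squares solution and flagged. The
#' intercept is fitted by default but excluded from reported scores (see
#' [wmms_score()]).
#'
#' @param design A [wmms_design()].
#' @param fit_intercept Fit an intercept (default TRUE).
#' @param provenance Label stored on the fit.
#' @return Object of class `wmms`, with `weights` (22, pinned zeros
#'   included), `intercept`, `r2`, `fitted`, `residuals`, `pinned`,
#'   `degenerate`, `design`.
#' @examples
#' set.seed(1)
#' sim <- simulate_cohort(sim_config(seed = 1, n_patients = 60))
#' d <- design_homozygous(sim$cohort[sim$cohort$zygosity == "homozygous", ],
#'                        sim$annotations)
#' fit <- wmms_fit(d)
#' fit
#' @export
wmms_fit <- function(design, fit_intercept = TRUE,
                     provenance = "trained") {
  stopifnot(inherits(design, "wmms_design"))
  X <- design$x
  y <- design$y
  if (nrow(X) < 2) stop("training needs at least 2 rows")
  pinned <- colnames(X)[colSums(abs(X)) == 0]
  keep <- setdiff(colnames(X), pinned)
  Xk <- X[, keep, drop = FALSE]
  Xf <- if (fit_intercept) cbind(`(Intercept)` = 1, Xk) else Xk
  fit <- stats::lm.fit(Xf, y)
  degenerate <- fit$rank < ncol(Xf)
  if (degenerate) {
    warning("rank-deficient design; using the minimum-norm least-squares solution")
    beta <- drop(MASS::ginv(Xf) %*% y)
    names(beta) <- colnames(Xf)
  } else {
    beta <- fit$coefficients
  }
  intercept <- if (fit_intercept) unname(beta["(Intercept)"]) else 0
  w <- stats::setNames(numeric(length(mms_parameters())), mms_parameters())
  w[keep] <- beta[keep]
  fitted_full <- drop(X %*% w) + intercept
  res <- y - fitted_full
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(weights = w, intercept = intercept,
                 provenance = provenance, r2 = r2,
                 fitted = stats::setNames(fitted_full, design$labels),
                 residuals = stats::setNames(res, design$labels),
                 sigma = sqrt(sum(res^2) / max(1, nrow(X) - length(beta))),
                 pinned = pinned, degenerate = degenerate,
                 fit_intercept = fit_intercept, design = design),
            class = "wmms")
}

#' @export
print.wmms <- function(x, ...) {
  cat("Weighted multiparametric mutation score fit (", x$provenance, ")\n",
      sep = "")
  cat(sprintf("  training rows: %d   R-squared: %.3f   intercept: %.3f%s\n",
              nrow(x$design$x), x$r2, x$intercept,
              if (x$fit_intercept) " (excluded from scores)" else ""))
  if (length(x$pinned)) {
    cat("  pinned to 0 (no training support):",
        paste(x$pinned, collapse = ", "), "\n")
  }
  if (x$degenerate) cat("  note: rank-deficient design, minimum-norm solution\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' @export
summary.wmms <- function(object, ...) {
  out <- list(weights = object$weights, intercept = object$intercept,
              r2 = object$r2, sigma = object$sigma,
              n = nrow(object$design$x), pinned = object$pinned,
              degenerate = object$degenerate,
              provenance = object$provenance)
  class(out) <- "summary.wmms"
  out
}

#' @export
print.summary.wmms <- function(x, ...) {
  cat(sprintf("WMMS fit (%s): n = %d, R2 = %.3f, residual sd = %.3f\n",
              x$provenance, x$n, x$r2, x$sigma))
  print(data.frame(weight = round(x$weights, 3)))
  invisible(x)
}

#' @export
coef.wmms <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$weights)
}

#' @export
residuals.wmms <- function(object, ...) object$residuals

#' @export
fitted.wmms <- function(object, ...) object$fitted

#' Predict weighted scores for new parameter vectors
#'
#' @param object A fitted `wmms` model.
#' @param newdata Matrix or `wmms_design` of parameter vectors; omitted =
#'   training rows.
#' @param include_intercept Add the fitted intercept (default FALSE: the
#'   reported WMMS is the bare weighted sum).
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.wmms <- function(object, newdata = NULL, include_intercept = FALSE,
                         ...) {
  if (is.null(newdata)) {
    X <- object$design$x
  } else if (inherits(newdata, "wmms_design")) {
    X <- newdata$x
  } else {
    X <- as.matrix(newdata)[, mms_parameters(), drop = FALSE]
  }
  drop(X %*% object$weights) + if (include_intercept) object$intercept else 0
}

#' @export
plot.wmms <- function(x, ...) {
  plot(predict(x), x$design$y,
       xlab = "WMMS (weighted score)", ylab = "COS",
       main = sprintf("COS vs WMMS (R2 = %.2f)", x$r2), ...)
  graphics::abline(stats::lm(x$design$y ~ predict(x)), lty = 2)
  invisible(x)
}

#' Simulate clinical outcome scores from a fitted model
#'
#' Draws Gaussian noise at the residual scale around the fitted weighted
#' scores, then rounds and clips to the legal 0..12 range of the outcome
#' scale.
#'
#' @param object A fitted `wmms` model.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated COS.
#' @export
simulate.wmms <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- replicate(nsim, pmin(12, pmax(0, round(mu + stats::rnorm(length(mu),
                                                                  0, object$sigma)))))
  as.data.frame(out, row.names = names(mu))
}

#' Score a cohort with a weight set
#'
#' Per patient: the composite WMMS, the two per-allele WMMS values (each
#' allele's own vector scored at full weight), and a predicted severity
#' class from a WMMS cutpoint. Patients whose missense allele lacks an
#' annotation are skipped with a logged reason.
#'
#' @param cohort A `gp_cohort`.
#' @param annotations Annotation table.
#' @param w Weight set (named vector) or fitted `wmms` model.
#' @param cfg A [feature_config()].
#' @param cutpoint WMMS above which the predicted class is `"severe"`; the
#'   default, `NULL`, uses the midpoint of the severe and attenuated class
#'   means when `w` is a fitted model (and errors otherwise).
#' @return Data frame (one row per scored patient) with attribute
#'   `skipped`.
#' @export
predict_cohort <- function(cohort, annotations, w, cfg = feature_config(),
                           cutpoint = NULL) {
  if (inherits(w, "wmms")) {
    if (is.null(cutpoint)) {
      cls <- classify_severity(pmin(12, pmax(0, round(w$design$y))))
      m <- tapply(predict(w), cls, mean)
      if (any(is.na(m[c("attenuated", "severe")]))) {
        stop("training data lacks both severity classes; give a cutpoint")
      }
      cutpoint <- mean(m[c("attenuated", "severe")])
    }
    w <- w$weights
  }
  if (is.null(cutpoint)) stop("cutpoint required when w is a bare weight set")
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    ok <- tryCatch({
      a1 <- cohort_allele(rec, 1, annotations)
      a2 <- cohort_allele(rec, 2, annotations)
      TRUE
    }, error = function(e) {
      skipped <<- c(skipped, sprintf("%s: %s", rec$patient_id,
                                     conditionMessage(e)))
      FALSE
    })
    if (!ok) next
    if (rec$zygosity == "homozygous") {
      v <- allele_vector(a1, cfg)
      s1 <- s2 <- wmms_score(v, w)
      comp <- s1
    } else {
      s1 <- wmms_score(allele_vector(a1, cfg), w)
      s2 <- wmms_score(allele_vector(a2, cfg), w)
      comp <- wmms_score(combine_heterozygous(a1, a2, cfg), w)
    }
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = rec$patient_id, zygosity = rec$zygosity,
      cos = compute_cos(rec), wmms = comp,
      wmms_allele1 = s1, wmms_allele2 = s2,
      predicted = if (comp > cutpoint) "severe" else "attenuated",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), zygosity = character(0),
               cos = integer(0), wmms = numeric(0),
               wmms_allele1 = numeric(0), wmms_allele2 = numeric(0),
               predicted = character(0), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  attr(out, "cutpoint") <- cutpoint
  out
}
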