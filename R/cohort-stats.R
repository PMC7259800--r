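#' Mutation rate of a residue region
#'
#' Fraction of a region's residues carrying at least one observed missense
#' mutation.
#'
#' @param region_residues Integer vector of residue positions in the region.
#' @param mutated_positions Integer vector of mutated residue positions.
#' @return Numeric rate in `[0, 1]`.
#' @examples
#' region_mutation_rate(1:30, c(2, 5, 7))
#' @export
region_mutation_rate <- function(region_residues, mutated_positions) {
  region_residues <- unique(region_residues)
  if (length(region_residues) == 0) stop("empty region")
  length(intersect(region_residues, unique(mutated_positions))) /
    length(region_residues)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `k` mutated residues in a region of
#' size `n`, when `K` of the protein's `N` residues are mutated, under the
#' hypergeometric null (tail inclusive of the observed count). Tests whether
#' the region's mutation rate exceeds the whole-protein rate.
#'
#' @param N Protein length (total residues).
#' @param K Mutated residues in the whole protein.
#' @param n Region size.
#' @param k Mutated residues in the region.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @examples
#' hypergeom_enrichment(1020, 213, 30, 10)
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  stopifnot(N >= 1, K >= 0, K <= N, n >= 1, n <= N, k >= 0)
  if (k > min(K, n)) stop("k cannot exceed min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Region enrichment summary
#'
#' Computes rate and upper-tail hypergeometric probability for each region
#' of a region table (columns `region`, `total_residues`, `mutated`), using
#' the first row as the whole-protein background.
#'
#' @param regions Data frame as returned by
#'   `load_fixture("table1_regions")`.
#' @return Data frame with `rate` and `p_upper` per region (background row
#'   gets `NA` for `p_upper`).
#' @export
region_enrichment <- function(regions = load_fixture("table1_regions")) {
  N <- regions$total_residues[1]
  K <- regions$mutated[1]
  regions$rate <- regions$mutated / regions$total_residues
  regions$p_upper <- c(NA_real_, vapply(seq_len(nrow(regions))[-1],
    function(i) hypergeom_enrichment(N, K, regions$total_residues[i],
                                     regions$mutated[i]), numeric(1)))
  regions
}

#' Phi coefficient of two binary vectors
#'
#' Pearson correlation specialised to two binary variables,
#' `(n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`. Composite heterozygous
#' parameter values (0.5) are binarised at "> 0" before computing. Constant
#' vectors have no defined phi and return `NA` with a warning.
#'
#' @param x,y Vectors of equal length; values are binarised at `> 0`.
#' @return Phi in `[-1, 1]`, or `NA` if either vector is constant.
#' @examples
#' phi_coefficient(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
phi_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  x <- as.numeric(x) > 0
  y <- as.numeric(y) > 0
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("phi undefined for a constant vector")
    return(NA_real_)
  }
  n11 <- sum(x & y); n00 <- sum(!x & !y)
  n10 <- sum(x & !y); n01 <- sum(!x & y)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

#' Pairwise phi matrix of a parameter table
#'
#' @param x Matrix or data frame of parameter indicator columns.
#' @return Symmetric matrix of phi coefficients (unit diagonal).
#' @export
phi_matrix <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(x), colnames(x))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      out[i, j] <- out[j, i] <- suppressWarnings(
        phi_coefficient(x[, i], x[, j]))
    }
  }
  out
}

#' Severity separation t-test
#'
#' Two-sample Student's t-test (pooled variance by default, two-sided) of
#' per-patient scores in the severe versus the attenuated class; also
#' reports the mean score of all three classes.
#'
#' @param scores Numeric per-patient scores (e.g. WMMS).
#' @param classes Severity labels (levels of [classify_severity()]).
#' @param welch Use the Welch unequal-variance test instead of pooled.
#' @return List of class `gp_separation` with `means`, `sizes`, `t`, `p`.
#' @export
severity_separation_ttest <- function(scores, classes, welch = FALSE) {
  classes <- factor(as.character(classes),
                    levels = c("asymptomatic", "attenuated", "severe"))
  sizes <- table(classes)
  for (cl in c("attenuated", "severe")) {
    if (sizes[[cl]] < 2) stop("class '", cl, "' has fewer than 2 patients")
  }
  tt <- stats::t.test(scores[classes == "severe"],
                      scores[classes == "attenuated"],
                      var.equal = !welch)
  structure(list(means = tapply(scores, classes, mean),
                 sizes = as.vector(sizes), t = unname(tt$statistic),
                 p = tt$p.value, welch = welch),
            class = "gp_separation")
}

#' @export
print.gp_separation <- function(x, ...) {
  cat(sprintf("Severe vs attenuated %s t-test: t = %.3f, p = %.3g\n",
              if (x$welch) "Welch" else "Student (pooled)", x$t, x$p))
  print(round(x$means, 3))
  invisible(x)
}

#' COS/MMS concordance counts
#'
#' Cross-tabulates the clinical severity class (attenuated = COS at or below
#' `attenuated_max`, severe above it; zero-COS patients are grouped with the
#' attenuated class, as in the published tables) with whether the mutation
#' score reaches `mms_cut`.
#'
#' @param cos Integer COS per patient.
#' @param mms Numeric MMS per patient.
#' @param attenuated_max Upper COS bound of the attenuated class (default 5).
#' @param mms_cut MMS threshold for a "high" score (default 5).
#' @return A 2x2 integer matrix (`attenuated`/`severe` x `low_mms`/`high_mms`).
#' @examples
#' t6 <- load_fixture("table6_homozygous_mms")
#' concordance_counts(t6$cos, t6$mms)
#' @export
concordance_counts <- function(cos, mms, attenuated_max = 5, mms_cut = 5) {
  stopifnot(length(cos) == length(mms))
  keep <- !is.na(cos) & !is.na(mms)
  cls <- factor(ifelse(cos[keep] > attenuated_max, "severe", "attenuated"),
                levels = c("attenuated", "severe"))
  high <- factor(ifelse(mms[keep] >= mms_cut, "high_mms", "low_mms"),
                 levels = c("low_mms", "high_mms"))
  out <- table(cls, high)
  m <- matrix(as.integer(out), 2, 2,
              dimnames = list(c("attenuated", "severe"),
                              c("low_mms", "high_mms")))
  m
}

#' Mutation survey summary
#'
#' Counts unique mutations and unique mutated residues and ranks positions
#' by how many distinct substitutions they carry (ties broken by ascending
#' position).
#'
#' @param mutations Data frame with columns `position`, `ref_aa`, `alt_aa`.
#' @param top_k How many top positions to report (default 10).
#' @return List with `n_mutations`, `n_residues`, `top_positions` (data
#'   frame of `position`, `count`).
#' @export
mutation_survey <- function(mutations, top_k = 10) {
  key <- paste(mutations$position, mutations$ref_aa, mutations$alt_aa)
  uniq <- mutations[!duplicated(key), , drop = FALSE]
  counts <- table(uniq$position)
  ord <- order(-as.vector(counts), as.integer(names(counts)))
  top <- utils::head(data.frame(position = as.integer(names(counts))[ord],
                                count = as.vector(counts)[ord]), top_k)
  list(n_mutations = nrow(uniq),
       n_residues = length(unique(uniq$position)),
       top_positions = top)
}
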