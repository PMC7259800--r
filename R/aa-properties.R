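#' Amino-acid property tables
#'
#' Physicochemical lookup tables over the 20 standard amino acids used to
#' derive the six amino-acid-property parameters of the multiparametric
#' mutation score: polarity class, charge class, aromaticity, standard
#' genetic-code codon counts, and residue volumes (Zamyatnin scale, cubic
#' Angstroms).
#'
#' Histidine is classed as polar and positively charged and is excluded from
#' the aromatic set; both choices can be overridden through
#' [feature_config()].
#'
#' @return `aa_properties()` returns a list with components `polar` (named
#'   logical), `charge` (named character: `"positive"`, `"negative"`,
#'   `"neutral"`), `aromatic` (named logical), `codons` (named integer) and
#'   `volume` (named numeric, A^3), each keyed by one-letter amino-acid code.
#' @examples
#' aa_properties()$volume[c("A", "V")]
#' @export
aa_properties <- function() {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  polar_set <- c("S","T","N","Q","Y","C","D","E","K","R","H")
  positive <- c("R","K","H")
  negative <- c("D","E")
  aromatic_set <- c("F","W","Y")
  codons <- c(A = 4L, R = 6L, N = 2L, D = 2L, C = 2L, Q = 2L, E = 2L,
              G = 4L, H = 2L, I = 3L, L = 6L, K = 2L, M = 1L, F = 2L,
              P = 4L, S = 6L, T = 4L, W = 1L, Y = 2L, V = 4L)
  # Zamyatnin (1972) residue volumes
  volume <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
              Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
              L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
              S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  charge <- stats::setNames(rep("neutral", length(aa)), aa)
  charge[positive] <- "positive"
  charge[negative] <- "negative"
  list(
    polar = stats::setNames(aa %in% polar_set, aa),
    charge = charge,
    aromatic = stats::setNames(aa %in% aromatic_set, aa),
    codons = codons[aa],
    volume = volume[aa]
  )
}

# Standard BLOSUM62 substitution matrix; used by the synthetic annotation
# generator to fill the blosum62 input column (real annotation tables carry
# the score as an input).
blosum62_matrix <- function() {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  m <- matrix(c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4
  ), nrow = 20, byrow = TRUE, dimnames = list(aa, aa))
  m
}

valid_aa <- function(x) {
  x %in% c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
}
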