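#' Read a multi-model two-chain docking decoy file
#'
#' Parses a (possibly multi-MODEL) PDB file into one atom table per decoy.
#' Waters are dropped; heteroatoms are retained. Each decoy must contain at
#' least two chains.
#'
#' @param path PDB file path.
#' @return List of `gp_docking_model` objects, each with `model_id` and an
#'   `atoms` data frame (`chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`).
#' @export
read_docking_models <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  keep <- !(atoms$resid %in% c("HOH", "WAT", "DOD"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    df <- data.frame(chain = atoms$chain, resno = atoms$resno,
                     resid = atoms$resid, elety = atoms$elety,
                     x = co[, 1], y = co[, 2], z = co[, 3],
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
    models[[m]] <- docking_model(sprintf("model_%03d", m), df)
  }
  models
}

#' @rdname read_docking_models
#' @param model_id Identifier for the decoy.
#' @param atoms Atom data frame (`chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`).
#' @export
docking_model <- function(model_id, atoms) {
  stopifnot(all(c("chain", "resno", "elety", "x", "y", "z") %in%
                  names(atoms)))
  if (length(unique(atoms$chain)) < 2) {
    stop("a docking model needs at least 2 chains")
  }
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates")
  }
  structure(list(model_id = model_id, atoms = atoms),
            class = "gp_docking_model")
}

#' Interface residues of a two-chain decoy
#'
#' A residue of one chain is interfacial when any of its atoms lies within
#' `cutoff` Angstroms of any atom of the partner chain (and symmetrically).
#'
#' @param model A `gp_docking_model`.
#' @param chain_a,chain_b Chain identifiers.
#' @param cutoff Contact distance in Angstroms (default 4).
#' @return List with integer residue sets `a` and `b`.
#' @export
interface_residues <- function(model, chain_a, chain_b, cutoff = 4) {
  at <- model$atoms
  A <- at[at$chain == chain_a, , drop = FALSE]
  B <- at[at$chain == chain_b, , drop = FALSE]
  if (!nrow(A) || !nrow(B)) stop("chain not present in model")
  ca <- as.matrix(A[, c("x", "y", "z")])
  cb <- as.matrix(B[, c("x", "y", "z")])
  # all-pairs squared distances, vectorised
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * tcrossprod(ca, cb)
  close <- d2 <= cutoff^2 + 1e-9
  list(a = sort(unique(A$resno[rowSums(close) > 0])),
       b = sort(unique(B$resno[colSums(close) > 0])))
}

#' Read a per-residue conservation table
#'
#' TSV with columns `chain`, `resno`, `grade` (grades 1..9).
#'
#' @param path TSV path.
#' @return Named list: chain -> named numeric vector (residue -> grade).
#' @export
read_conservation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chain", "resno", "grade") %in% names(df)))
  if (any(!df$grade %in% 1:9)) stop("conservation grades must be 1..9")
  split_df <- split(df, df$chain)
  lapply(split_df, function(d) stats::setNames(as.numeric(d$grade),
                                               as.character(d$resno)))
}

#' Mean conservation of an interface residue set
#'
#' @param residues Integer residue numbers.
#' @param grades Named numeric vector (residue -> grade) for the chain.
#' @param aggregate Aggregation function (default mean).
#' @return Aggregate grade, or `NA` for an empty set.
#' @export
conservation_parameter <- function(residues, grades, aggregate = mean) {
  if (length(residues) == 0) return(NA_real_)
  g <- grades[as.character(residues)]
  if (anyNA(g)) {
    warning(sum(is.na(g)), " interface residue(s) missing from the conservation table")
    g <- g[!is.na(g)]
  }
  if (!length(g)) return(NA_real_)
  aggregate(g)
}

#' Ligand-to-site distance parameter
#'
#' Euclidean distance from one designated ligand atom (by default the
#' lipoyllysine side-chain nitrogen of the shuttle protein) to the centroid
#' of the alpha carbons of a designated site residue set on the partner
#' chain (the active-site tunnel entry).
#'
#' @param model A `gp_docking_model`.
#' @param ligand List `(chain, resno, atom)` naming the reference atom.
#' @param site_chain Chain carrying the site.
#' @param site_residues Integer residue numbers of the site.
#' @return Distance in Angstroms, or `NA` (with a warning) if the ligand
#'   atom is absent.
#' @export
distance_parameter <- function(model, ligand, site_chain, site_residues) {
  stopifnot(length(site_residues) > 0)
  at <- model$atoms
  la <- at[at$chain == ligand$chain & at$resno == ligand$resno &
             at$elety == ligand$atom, , drop = FALSE]
  if (nrow(la) == 0) {
    warning("ligand atom not found in model ", model$model_id)
    return(NA_real_)
  }
  site <- at[at$chain == site_chain & at$resno %in% site_residues &
               at$elety == "CA", , drop = FALSE]
  if (nrow(site) == 0) stop("no alpha carbons found for the site residues")
  centroid <- colMeans(site[, c("x", "y", "z")])
  sqrt(sum((unlist(la[1, c("x", "y", "z")]) - centroid)^2))
}

#' Raw ranking parameters for a decoy set
#'
#' For each decoy: mean conservation of each chain's interface residues and
#' (optionally) the ligand-to-site distance.
#'
#' @param models List of `gp_docking_model`.
#' @param conservation Conservation list from [read_conservation_table()].
#' @param chain_a,chain_b The two chain identifiers (a = fixed/receptor,
#'   b = mobile/ligand chain).
#' @param cutoff Interface contact cutoff (Angstroms).
#' @param ligand,site_residues Passed to [distance_parameter()]; set
#'   `ligand = NULL` to skip the distance parameter.
#' @param aggregate Conservation aggregation function.
#' @return Data frame of raw parameters, one row per decoy.
#' @export
score_docking_models <- function(models, conservation, chain_a, chain_b,
                                 cutoff = 4, ligand = NULL,
                                 site_residues = NULL, aggregate = mean) {
  rows <- lapply(models, function(m) {
    iface <- interface_residues(m, chain_a, chain_b, cutoff)
    data.frame(
      model_id = m$model_id,
      raw_cons_a = conservation_parameter(iface$a, conservation[[chain_a]],
                                          aggregate),
      raw_cons_b = conservation_parameter(iface$b, conservation[[chain_b]],
                                          aggregate),
      raw_distance = if (is.null(ligand)) NA_real_ else
        distance_parameter(m, ligand, chain_a, site_residues),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Min-max normalise and rank raw decoy scores
#'
#' Each parameter is scaled to `[0, 1]` across the decoy set, oriented so
#' that 1 is best: the most conserved interface scores 1, and the shortest
#' ligand-to-site distance scores 1. Ties at the extreme share the 1/0
#' value; a parameter constant across the set is dropped with a warning
#' rather than divided by zero. The total is the sum of available
#' normalised parameters; decoys are ranked by descending total with ties
#' broken by model id.
#'
#' @param raw Data frame from [score_docking_models()].
#' @param use_distance Include the distance parameter (default TRUE when
#'   present).
#' @return Data frame with normalised columns, `total` and `rank`, ordered
#'   by rank.
#' @export
normalize_and_rank <- function(raw, use_distance = TRUE) {
  if (nrow(raw) < 2) stop("ranking needs at least 2 models")
  out <- raw
  norm_cols <- character(0)
  minmax <- function(v, invert = FALSE) {
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(diff(rng)) || diff(rng) == 0) return(NULL)
    s <- (v - rng[1]) / diff(rng)
    if (invert) 1 - s else s
  }
  for (spec in list(c("raw_cons_a", "norm_cons_a", FALSE),
                    c("raw_cons_b", "norm_cons_b", FALSE),
                    c("raw_distance", "norm_distance", TRUE))) {
    rc <- spec[1]; nc <- spec[2]; inv <- as.logical(spec[3])
    if (rc == "raw_distance" && (!use_distance || all(is.na(raw[[rc]])))) next
    s <- minmax(raw[[rc]], invert = inv)
    if (is.null(s)) {
      warning("parameter ", rc, " is constant across the set; dropped")
      next
    }
    out[[nc]] <- s
    norm_cols <- c(norm_cols, nc)
  }
  if (!length(norm_cols)) stop("no rankable parameter varies across the set")
  out$total <- rowSums(out[, norm_cols, drop = FALSE], na.rm = TRUE)
  ord <- order(-out$total, out$model_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

chain_centroid <- function(model, chain) {
  at <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  colMeans(at[, c("x", "y", "z")])
}

#' Second-round constrained rescoring
#'
#' Retains the decoys whose mobile-chain centroid lies within `radius`
#' Angstroms of the anchor decoy's mobile-chain centroid (the top region of
#' a first scoring round), then recomputes the min-max normalisation on the
#' retained subset.
#'
#' @param models List of `gp_docking_model` (the full set).
#' @param anchor_id `model_id` of the anchor from the first round.
#' @param radius Constraint radius in Angstroms (default 20).
#' @param mobile_chain The chain that moves between decoys.
#' @param ... Passed on to [score_docking_models()].
#' @param use_distance Passed to [normalize_and_rank()].
#' @return Ranked data frame over the retained subset; if fewer than 2
#'   decoys survive, the raw subset is returned unranked with a warning.
#' @export
constrained_rescore <- function(models, anchor_id, radius = 20,
                                mobile_chain, ..., use_distance = TRUE) {
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (!anchor_id %in% ids) stop("anchor model not in the set")
  cents <- t(vapply(models, chain_centroid, numeric(3),
                    chain = mobile_chain))
  anchor_c <- cents[ids == anchor_id, ]
  d <- sqrt(rowSums((cents - matrix(anchor_c, nrow(cents), 3,
                                    byrow = TRUE))^2))
  keep <- models[d <= radius]
  raw <- score_docking_models(keep, ...)
  if (nrow(raw) < 2) {
    warning("fewer than 2 models within the constraint radius; returning unranked")
    return(raw)
  }
  normalize_and_rank(raw, use_distance = use_distance)
}
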