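#' Simulation configuration
#'
#' Settings for the synthetic annotation, cohort and docking generators.
#' Defaults mirror the study conditions: a 1020-residue precursor, region
#' sizes of 30 (active site), 20 (N-terminal PLP pocket) and 17 (H-protein
#' interface), 251 scoreable missense mutations whose stability effects fall
#' in the five ddG bins with the published frequencies (42 very
#' destabilizing, 63 destabilizing, 96 negligible, 35 stabilizing, 15 very
#' stabilizing), a 74-patient cohort splitting 24 homozygous / 50 compound
#' heterozygous, and 32 of the 50 heterozygotes carrying one non-missense
#' allele.
#'
#' @param seed Integer RNG seed (the generators are fully deterministic
#'   given the seed).
#' @param protein_length Precursor length.
#' @param region_sizes Named integer vector of disjoint region sizes
#'   (`active_site`, `active_region`, `nterm_plp`, `h_interface`,
#'   `dimer_interface`).
#' @param n_mutations Number of distinct missense mutations to draw.
#' @param ddg_props Proportions of the five stability bins (must sum to 1).
#' @param true_weights Generative weights over [mms_parameters()] (default
#'   the unit signs).
#' @param noise_sd Gaussian noise sd added to the latent outcome before
#'   rounding/clipping.
#' @param n_patients Cohort size.
#' @param zygosity_mix Named proportions for `homozygous` and
#'   `compound_heterozygous` (must sum to 1).
#' @param nonmissense_fraction Fraction of compound heterozygotes whose
#'   second allele is non-missense.
#' @return List of class `gp_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       protein_length = 1020,
                       region_sizes = c(active_site = 30, active_region = 40,
                                        nterm_plp = 20, h_interface = 17,
                                        dimer_interface = 60),
                       n_mutations = 251,
                       ddg_props = c(very_destabilizing = 42,
                                     destabilizing = 63,
                                     negligible = 96,
                                     stabilizing = 35,
                                     very_stabilizing = 15) / 251,
                       true_weights = unit_weights(),
                       noise_sd = 1,
                       n_patients = 74,
                       zygosity_mix = c(homozygous = 24,
                                        compound_heterozygous = 50) / 74,
                       nonmissense_fraction = 32 / 50) {
  stopifnot(abs(sum(ddg_props) - 1) < 1e-8,
            abs(sum(zygosity_mix) - 1) < 1e-8,
            noise_sd >= 0,
            sum(region_sizes) <= protein_length)
  tw <- stats::setNames(numeric(length(mms_parameters())), mms_parameters())
  tw[names(true_weights)] <- true_weights
  cfg <- list(seed = as.integer(seed), protein_length = protein_length,
              region_sizes = region_sizes, n_mutations = n_mutations,
              ddg_props = ddg_props, true_weights = tw, noise_sd = noise_sd,
              n_patients = n_patients, zygosity_mix = zygosity_mix,
              nonmissense_fraction = nonmissense_fraction)
  class(cfg) <- "gp_sim_config"
  cfg
}

sample_regions <- function(cfg) {
  pos <- sample.int(cfg$protein_length, sum(cfg$region_sizes))
  split(pos, rep(names(cfg$region_sizes), cfg$region_sizes))
}

#' Simulate a mutation annotation table
#'
#' Draws distinct missense substitutions uniformly over the substitution
#' space of a random reference sequence, assigns disjoint structural
#' regions, draws ddG from the five-bin mixture (uniform within bin),
#' conservation grades and secondary structure from categorical
#' distributions, and fills the BLOSUM62 column from the standard matrix.
#'
#' @param cfg A [sim_config()]. The RNG is seeded from `cfg$seed`.
#' @return List with `annotations` (data frame accepted by
#'   [validate_annotations()]) and `regions` (the sampled region sets).
#' @export
simulate_annotations <- function(cfg = sim_config()) {
  if (cfg$n_mutations > cfg$protein_length * 19) {
    stop("n_mutations exceeds the substitution space")
  }
  set.seed(cfg$seed)
  aa <- names(aa_properties()$volume)
  regions <- sample_regions(cfg)
  ref_seq <- sample(aa, cfg$protein_length, replace = TRUE)
  # index the (position, alternative) substitution space and draw without
  # replacement so mutation names are unique
  idx <- sample.int(cfg$protein_length * 19, cfg$n_mutations)
  pos <- (idx - 1) %/% 19 + 1
  alt_k <- (idx - 1) %% 19 + 1
  ref <- ref_seq[pos]
  alt <- vapply(seq_along(pos),
                function(i) setdiff(aa, ref[i])[alt_k[i]], character(1))
  bins <- sample(names(cfg$ddg_props), cfg$n_mutations, replace = TRUE,
                 prob = cfg$ddg_props)
  lo <- c(very_destabilizing = -9, destabilizing = -5, negligible = -1.5,
          stabilizing = 1.5, very_stabilizing = 5)
  hi <- c(very_destabilizing = -5.01, destabilizing = -1.51,
          negligible = 1.5, stabilizing = 5, very_stabilizing = 9)
  ddg <- stats::runif(cfg$n_mutations, lo[bins], hi[bins])
  b62 <- blosum62_matrix()
  ann <- data.frame(
    mutation = paste0(ref, pos, alt),
    position = pos, ref_aa = ref, alt_aa = alt,
    ddg_kcal_mol = round(ddg, 2),
    conservation_grade = sample(1:9, cfg$n_mutations, replace = TRUE),
    blosum62 = b62[cbind(ref, alt)],
    sec_struct = sample(c("helix", "sheet", "loop"), cfg$n_mutations,
                        replace = TRUE, prob = c(0.35, 0.2, 0.45)),
    active_site = pos %in% regions$active_site,
    active_region_7A = pos %in% regions$active_region,
    nterm_plp = pos %in% regions$nterm_plp,
    h_interface = pos %in% regions$h_interface,
    dimer_interface = pos %in% regions$dimer_interface,
    stringsAsFactors = FALSE)
  validate_annotations(ann, cfg$protein_length)
  list(annotations = ann, regions = regions)
}

# deterministic allocation of a total outcome score onto the four legal
# domain scales (brain first when the remainder allows a 3, then seizures on
# the {0,1,3} scale, then cognitive, then muscle/movement)
decompose_cos <- function(total) {
  total <- as.integer(total)
  vapply(total, function(c0) {
    brain <- if (c0 >= 3) 3L else 0L
    rem <- c0 - brain
    seiz <- if (rem >= 3) 3L else min(rem, 1L)
    rem <- rem - seiz
    cog <- min(rem, 3L)
    rem <- rem - cog
    mus <- min(rem, 3L)
    c(seizures = seiz, cognitive = cog, brain_malformation = brain,
      muscle_movement = as.integer(mus))
  }, integer(4))
}

#' Simulate a patient cohort with latent ground truth
#'
#' Samples genotypes from a (simulated or supplied) annotation table, builds
#' the corresponding parameter vectors, draws a latent clinical outcome
#' `clip(round(w* . v + eps), 0, 12)` with Gaussian noise entering before
#' rounding, and decomposes each outcome deterministically onto the four
#' legal domain scales. The generative truth is returned alongside the
#' cohort for parameter-recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param annotations Optional annotation table; simulated from `cfg` when
#'   omitted.
#' @return List with `cohort` (a `gp_cohort`), `annotations`, and `truth`
#'   (list: `true_weights`, `noise`, `latent`, `vectors` matrix).
#' @export
simulate_cohort <- function(cfg = sim_config(), annotations = NULL) {
  if (is.null(annotations)) {
    annotations <- simulate_annotations(cfg)$annotations
  }
  set.seed(cfg$seed + 1L)
  n <- cfg$n_patients
  zyg <- sample(names(cfg$zygosity_mix), n, replace = TRUE,
                prob = cfg$zygosity_mix)
  nonmiss_classes <- setdiff(allele_classes(), "missense")
  vectors <- matrix(0, n, length(mms_parameters()),
                    dimnames = list(NULL, mms_parameters()))
  a1 <- a2 <- cls1 <- cls2 <- character(n)
  cfg_feat <- feature_config(protein_length = cfg$protein_length)
  for (i in seq_len(n)) {
    m1 <- annotations[sample.int(nrow(annotations), 1), ]
    if (zyg[i] == "homozygous") {
      a1[i] <- a2[i] <- m1$mutation
      cls1[i] <- cls2[i] <- "missense"
      vectors[i, ] <- derive_parameter_vector(m1, cfg_feat)
    } else {
      s1 <- allele_spec("missense", m1)
      if (stats::runif(1) < cfg$nonmissense_fraction) {
        cls <- sample(nonmiss_classes, 1)
        s2 <- allele_spec(cls)
        a2[i] <- cls
      } else {
        m2 <- annotations[sample(setdiff(seq_len(nrow(annotations)),
                                         which(annotations$mutation == m1$mutation)), 1), ]
        s2 <- allele_spec("missense", m2)
        a2[i] <- m2$mutation
      }
      a1[i] <- m1$mutation
      cls1[i] <- "missense"
      cls2[i] <- s2$class
      vectors[i, ] <- combine_heterozygous(s1, s2, cfg_feat)
    }
  }
  latent <- drop(vectors %*% cfg$true_weights)
  noise <- stats::rnorm(n, 0, cfg$noise_sd)
  cos <- pmin(12, pmax(0, round(latent + noise)))
  dom <- t(decompose_cos(cos))
  cohort <- data.frame(
    patient_id = sprintf("SIM%04d", seq_len(n)),
    zygosity = zyg, allele1 = a1, allele2 = a2,
    allele1_class = cls1, allele2_class = cls2,
    sex = sample(c("M", "F"), n, replace = TRUE),
    age_years = round(stats::runif(n, 0, 20), 1),
    deceased = FALSE,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(dom))
  cohort <- as_gp_cohort(cohort, source_label = "synthetic")
  list(cohort = cohort,
       annotations = annotations,
       truth = list(true_weights = cfg$true_weights, noise = noise,
                    latent = latent, vectors = vectors))
}

rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  u %o% u * (1 - c_) + diag(c_, 3) +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) * s_
}

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

format_atom <- function(serial, elety, resid, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, elety, resid, chain, resno, xyz[1], xyz[2], xyz[3])
}

#' Simulate a docking decoy set with a planted true pose
#'
#' Builds a fixed receptor chain (alpha-carbon pseudo-protein on a sphere)
#' carrying a small highly conserved surface patch, and a mobile 6-residue
#' ligand chain whose "true" pose contacts the patch with its own conserved
#' face and places its reference atom (a lysine side-chain nitrogen,
#' standing in for the lipoyllysine) at minimal distance from the patch.
#' Decoys are rigid random placements elsewhere on the receptor surface,
#' rejection-sampled to avoid clashes. The geometry is a toy: it reproduces
#' the statistical structure the rescoring assumes, not real structures.
#'
#' @param n_models Number of decoys including the planted pose (>= 2).
#' @param seed RNG seed.
#' @param dir Directory receiving `decoys.pdb` and `conservation.tsv`.
#' @param max_iter Rejection-sampling cap per decoy.
#' @return List with `models`, `pdb_path`, `conservation_path`,
#'   `conservation`, `planted_id`, `chain_a`, `chain_b`, `ligand`,
#'   `site_residues`.
#' @export
simulate_docking_set <- function(n_models = 20, seed = 1,
                                 dir = tempdir(), max_iter = 1000) {
  stopifnot(n_models >= 2)
  set.seed(seed)
  n_a <- 40
  r_a <- 15
  A <- fibonacci_sphere(n_a, r_a)
  # conserved patch: the receptor residues nearest the +x pole
  patch <- order(-A[, 1])[1:5]
  grades_a <- sample(1:5, n_a, replace = TRUE)
  grades_a[patch] <- 9L
  # mobile chain local frame: conserved face (residues 1-3) at local -x
  B_local <- rbind(c(-1.5, -1.2, 0), c(-1.5, 1.2, 0), c(-1.5, 0, 1.2),
                   c(1.5, -1.2, 0), c(1.5, 1.2, 0), c(1.5, 0, 1.2))
  nz_local <- c(-2.8, 0, 0)
  grades_b <- c(9L, 9L, 9L, 2L, 2L, 2L)
  place <- function(dir_u, rot) {
    centroid <- dir_u * (r_a + 3.6)
    list(B = sweep(B_local %*% t(rot), 2, centroid, `+`),
         nz = drop(rot %*% nz_local) + centroid)
  }
  planted_u <- colMeans(A[patch, , drop = FALSE])
  planted_u <- planted_u / sqrt(sum(planted_u^2))
  # rotate local -x onto -planted_u so the conserved face looks at the patch
  align_rot <- function(u) {
    from <- c(-1, 0, 0); to <- -u
    ax <- c(from[2] * to[3] - from[3] * to[2],
            from[3] * to[1] - from[1] * to[3],
            from[1] * to[2] - from[2] * to[1])
    ang <- acos(max(-1, min(1, sum(from * to))))
    if (sqrt(sum(ax^2)) < 1e-8) return(diag(3))
    rotation_matrix(ax, ang)
  }
  poses <- vector("list", n_models)
  poses[[1]] <- place(planted_u, align_rot(planted_u))
  min_cross <- function(B) {
    min(sqrt(pmax(0, outer(rowSums(B^2), rowSums(A^2), `+`) -
                    2 * tcrossprod(B, A))))
  }
  for (m in 2:n_models) {
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      if (sum(u * planted_u) > 0.55) next  # keep decoys off the patch
      ax <- stats::rnorm(3)
      rot <- rotation_matrix(ax, stats::runif(1, 0, 2 * pi)) %*%
        rotation_matrix(c(0, 0, 1), stats::runif(1, 0, 2 * pi))
      cand <- place(u, rot)
      # slide radially so the closest approach sits near the contact window
      shift <- (min_cross(cand$B) - 3.2) * u
      cand$B <- sweep(cand$B, 2, shift, `-`)
      cand$nz <- cand$nz - shift
      dmin <- min_cross(cand$B)
      if (dmin >= 2.4 && dmin <= 3.9) { poses[[m]] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("rejection sampling failed to place decoy ", m)
  }
  models <- lapply(seq_len(n_models), function(m) {
    p <- poses[[m]]
    atoms <- rbind(
      data.frame(chain = "A", resno = seq_len(n_a), resid = "ALA",
                 elety = "CA", x = A[, 1], y = A[, 2], z = A[, 3],
                 stringsAsFactors = FALSE),
      data.frame(chain = "B", resno = 1:6,
                 resid = c("LYS", rep("GLY", 5)), elety = "CA",
                 x = p$B[, 1], y = p$B[, 2], z = p$B[, 3],
                 stringsAsFactors = FALSE),
      data.frame(chain = "B", resno = 1, resid = "LYS", elety = "NZ",
                 x = p$nz[1], y = p$nz[2], z = p$nz[3],
                 stringsAsFactors = FALSE))
    docking_model(sprintf("model_%03d", m), atoms)
  })
  pdb_path <- file.path(dir, "decoys.pdb")
  con <- file(pdb_path, "w")
  for (m in seq_len(n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    at <- models[[m]]$atoms
    writeLines(vapply(seq_len(nrow(at)), function(i) {
      format_atom(i, at$elety[i], at$resid[i], at$chain[i], at$resno[i],
                  c(at$x[i], at$y[i], at$z[i]))
    }, character(1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  cons <- data.frame(chain = c(rep("A", n_a), rep("B", 6)),
                     resno = c(seq_len(n_a), 1:6),
                     grade = c(grades_a, grades_b))
  cons_path <- file.path(dir, "conservation.tsv")
  utils::write.table(cons, cons_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(models = models, pdb_path = pdb_path,
       conservation_path = cons_path,
       conservation = read_conservation_table(cons_path),
       planted_id = "model_001", chain_a = "A", chain_b = "B",
       ligand = list(chain = "B", resno = 1, atom = "NZ"),
       site_residues = patch)
}
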