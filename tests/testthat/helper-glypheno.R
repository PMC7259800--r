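# Shared helpers for the test suite.

# A fully specified annotation row with overridable fields.
make_ann <- function(mutation = "A100V", position = 100, ref_aa = "A",
                     alt_aa = "V", ddg_kcal_mol = 0, conservation_grade = 1,
                     blosum62 = 0, sec_struct = "loop", active_site = FALSE,
                     active_region_7A = FALSE, nterm_plp = FALSE,
                     h_interface = FALSE, dimer_interface = FALSE) {
  data.frame(mutation = mutation, position = position, ref_aa = ref_aa,
             alt_aa = alt_aa, ddg_kcal_mol = ddg_kcal_mol,
             conservation_grade = conservation_grade, blosum62 = blosum62,
             sec_struct = sec_struct, active_site = active_site,
             active_region_7A = active_region_7A, nterm_plp = nterm_plp,
             h_interface = h_interface, dimer_interface = dimer_interface,
             stringsAsFactors = FALSE)
}

# A minimal legal cohort row with overridable fields.
make_patient <- function(patient_id = "P1", zygosity = "homozygous",
                         allele1 = "A100V", allele2 = allele1,
                         allele1_class = "missense",
                         allele2_class = "missense", sex = "F",
                         age_years = 5, deceased = FALSE, seizures = 0L,
                         cognitive = 0L, brain_malformation = 0L,
                         muscle_movement = 0L) {
  data.frame(patient_id = patient_id, zygosity = zygosity,
             allele1 = allele1, allele2 = allele2,
             allele1_class = allele1_class, allele2_class = allele2_class,
             sex = sex, age_years = age_years, deceased = deceased,
             seizures = seizures, cognitive = cognitive,
             brain_malformation = brain_malformation,
             muscle_movement = muscle_movement, stringsAsFactors = FALSE)
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric
# probability, using only choose().
hyper_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# O(n^2) brute-force interface oracle.
iface_oracle <- function(model, chain_a, chain_b, cutoff = 4) {
  at <- model$atoms
  A <- at[at$chain == chain_a, , drop = FALSE]
  B <- at[at$chain == chain_b, , drop = FALSE]
  ra <- integer(0)
  rb <- integer(0)
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      if (d <= cutoff) {
        ra <- c(ra, A$resno[i])
        rb <- c(rb, B$resno[j])
      }
    }
  }
  list(a = sort(unique(ra)), b = sort(unique(rb)))
}

# Random two-chain CA-only docking model in a small box so that some atom
# pairs fall inside the contact cutoff and some do not.
random_model <- function(id = "m1", n_a = 15, n_b = 12, box = 12) {
  docking_model(id, data.frame(
    chain = c(rep("A", n_a), rep("B", n_b)),
    resno = c(seq_len(n_a), seq_len(n_b)),
    resid = "ALA", elety = "CA",
    x = stats::runif(n_a + n_b, 0, box),
    y = stats::runif(n_a + n_b, 0, box),
    z = stats::runif(n_a + n_b, 0, box),
    stringsAsFactors = FALSE))
}

# A random raw decoy-score table for normalisation properties.
random_raw <- function(n) {
  data.frame(model_id = sprintf("m%03d", seq_len(n)),
             raw_cons_a = stats::runif(n, 1, 9),
             raw_cons_b = stats::runif(n, 1, 9),
             raw_distance = stats::runif(n, 3, 40),
             stringsAsFactors = FALSE)
}
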