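test_that("parameter keys and unit weights are as documented", {
  expect_length(mms_parameters(), 22)
  expect_length(mms_parameters(include_nonmissense = FALSE), 18)
  w <- unit_weights()
  expect_equal(unname(w["cons_substitution"]), -1)
  expect_true(all(w[setdiff(names(w), "cons_substitution")] == 1))
})

test_that("stability bins respect the documented boundaries", {
  got <- classify_stability(c(-6, -5, -5.01, -1.5, -1.51, 0, 1.5, 1.51,
                              5, 5.01, 6))
  expect_identical(as.character(got),
                   c("very_destabilizing", "destabilizing",
                     "very_destabilizing", "negligible", "destabilizing",
                     "negligible", "negligible", "stabilizing",
                     "stabilizing", "very_stabilizing", "very_stabilizing"))
  expect_error(classify_stability(NA_real_), "finite")
})

test_that("worked-example parameter vectors trigger exactly the documented flags", {
  ann <- read_annotation_table(system.file(
    "extdata", "annotations_synthetic_examples.tsv", package = "glypheno"))
  get <- function(m) derive_parameter_vector(ann[ann$mutation == m, ])
  active <- function(v) names(v)[v != 0]

  r515s <- get("R515S")
  expect_setequal(active(r515s),
                  c("destabilizing", "cons_residue", "c_term", "d_charge",
                    "d_size"))
  a389v <- get("A389V")
  expect_setequal(active(a389v),
                  c("cons_residue", "helix", "d_size", "cons_substitution"))
  a802v <- get("A802V")
  expect_setequal(active(a802v),
                  c("c_term", "nterm_plp", "d_size", "cons_substitution"))
  t269m <- get("T269M")
  expect_setequal(active(t269m), "d_polarity")

  expect_equal(mms_homozygous(r515s), 5)
  expect_equal(mms_homozygous(a389v), 2)
  expect_equal(mms_homozygous(a802v), 2)
  expect_equal(mms_homozygous(t269m), 1)
})

test_that("feature thresholds act at their configured boundaries", {
  cfg <- feature_config()
  # ddg: strict below -1.5 destabilizing, at/above +1.5 stabilizing
  expect_equal(derive_parameter_vector(
    make_ann(ddg_kcal_mol = -1.5), cfg)[["destabilizing"]], 0)
  expect_equal(derive_parameter_vector(
    make_ann(ddg_kcal_mol = -1.51), cfg)[["destabilizing"]], 1)
  expect_equal(derive_parameter_vector(
    make_ann(ddg_kcal_mol = 1.5), cfg)[["stabilizing"]], 1)
  # conservation grade >= 7
  expect_equal(derive_parameter_vector(
    make_ann(conservation_grade = 7), cfg)[["cons_residue"]], 1)
  expect_equal(derive_parameter_vector(
    make_ann(conservation_grade = 6), cfg)[["cons_residue"]], 0)
  # C-terminal span from 506
  expect_equal(derive_parameter_vector(
    make_ann(position = 506), cfg)[["c_term"]], 1)
  expect_equal(derive_parameter_vector(
    make_ann(position = 505), cfg)[["c_term"]], 0)
  # proline involvement on either side
  expect_equal(derive_parameter_vector(
    make_ann(ref_aa = "P", alt_aa = "L", mutation = "P9L"),
    cfg)[["d_proline"]], 1)
  expect_equal(derive_parameter_vector(
    make_ann(ref_aa = "L", alt_aa = "P", mutation = "L9P"),
    cfg)[["d_proline"]], 1)
  # codon-count change: T->M is delta 3 and must not trigger at the default
  expect_equal(derive_parameter_vector(
    make_ann(ref_aa = "T", alt_aa = "M", mutation = "T9M"),
    cfg)[["d_codon"]], 0)
  expect_equal(derive_parameter_vector(
    make_ann(ref_aa = "L", alt_aa = "W", mutation = "L9W"),
    cfg)[["d_codon"]], 1)  # 6 vs 1 codons
  # histidine counts as polar and positively charged
  hv <- derive_parameter_vector(
    make_ann(ref_aa = "H", alt_aa = "A", mutation = "H9A"), cfg)
  expect_equal(hv[["d_polarity"]], 1)
  expect_equal(hv[["d_charge"]], 1)
  expect_error(derive_parameter_vector(make_ann(ref_aa = "Z")),
               "unknown amino-acid")
})

test_that("homozygous MMS is bounded and rejects composite vectors", {
  set.seed(11)
  sim <- simulate_annotations(sim_config(seed = 11, n_mutations = 200))
  for (i in sample(200, 25)) {
    v <- derive_parameter_vector(sim$annotations[i, ])
    s <- mms_homozygous(v)
    expect_gte(s, -1)
    expect_lte(s, 17)
    expect_equal(s, mms_score(v))
  }
  v <- derive_parameter_vector(sim$annotations[1, ])
  expect_error(mms_homozygous(v / 2), "0/1")
  v["deletion"] <- 1
  expect_error(mms_homozygous(v), "non-missense")
})

test_that("heterozygous composite equals the mean of per-allele scores", {
  sim <- simulate_annotations(sim_config(seed = 13, n_mutations = 100))
  ann <- sim$annotations
  set.seed(13)
  for (rep in 1:20) {
    i <- sample(100, 2)
    a1 <- allele_spec("missense", ann[i[1], ])
    a2 <- allele_spec("missense", ann[i[2], ])
    comp <- combine_heterozygous(a1, a2)
    expect_true(all(comp %in% c(0, 0.5, 1)))
    expect_equal(mms_score(comp),
                 mean(c(mms_homozygous(derive_parameter_vector(ann[i[1], ])),
                        mms_homozygous(derive_parameter_vector(ann[i[2], ])))))
  }
  # a non-missense partner allele scores 1 on its class parameter
  a1 <- allele_spec("missense", ann[1, ])
  for (cls in c("deletion", "nonsense_frameshift", "intronic_splice",
                "mito_leader")) {
    comp <- combine_heterozygous(a1, allele_spec(cls))
    expect_equal(unname(comp[cls]), 0.5)
    expect_equal(mms_score(comp),
                 mean(c(mms_homozygous(derive_parameter_vector(ann[1, ])), 1)))
  }
  expect_error(combine_heterozygous(allele_spec("deletion"),
                                    allele_spec("intronic_splice")),
               "at least one allele must be missense")
  expect_error(allele_spec("missense"), "requires an annotation")
  expect_error(allele_spec("deletion", ann[1, ]), "no annotation")
})

test_that("MMS bands split at 1, 3 and 5 with half scores below their ceiling", {
  got <- classify_mms(c(-1, 0, 0.5, 1, 2.5, 3, 4.5, 5, 17))
  expect_identical(as.character(got),
                   c("below_scale", "below_scale", "below_scale", "mild",
                     "mild", "moderate", "moderate", "severe", "severe"))
  expect_error(classify_mms(NaN), "finite")
})
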