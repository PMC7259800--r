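test_that("multi-model PDB files parse into per-decoy atom tables", {
  dk <- simulate_docking_set(n_models = 3, seed = 2, dir = tempdir())
  models <- read_docking_models(dk$pdb_path)
  expect_length(models, 3)
  expect_identical(vapply(models, `[[`, character(1), "model_id"),
                   sprintf("model_%03d", 1:3))
  expect_setequal(unique(models[[1]]$atoms$chain), c("A", "B"))
  expect_equal(nrow(models[[1]]$atoms), 47)  # 40 CA + 6 CA + 1 NZ
  # coordinates survive the fixed-width round trip to 1e-3
  expect_equal(models[[2]]$atoms$x, dk$models[[2]]$atoms$x,
               tolerance = 1e-3)
  expect_error(docking_model("m", data.frame(
    chain = "A", resno = 1, resid = "ALA", elety = "CA",
    x = 0, y = 0, z = 0)), "at least 2 chains")
  expect_error(docking_model("m", data.frame(
    chain = c("A", "B"), resno = 1:2, resid = "ALA", elety = "CA",
    x = c(0, NA), y = 0, z = 0)), "non-finite")
})

test_that("interface detection agrees with the O(n^2) brute-force oracle", {
  set.seed(33)
  for (rep in 1:12) {
    m <- random_model(sprintf("m%d", rep))
    got <- interface_residues(m, "A", "B", cutoff = 4)
    expect_identical(got, iface_oracle(m, "A", "B", cutoff = 4))
    # symmetric in the chain arguments
    swapped <- interface_residues(m, "B", "A", cutoff = 4)
    expect_identical(swapped, list(a = got$b, b = got$a))
  }
  m <- random_model("m0")
  expect_error(interface_residues(m, "A", "C"), "chain not present")
})

test_that("the distance parameter is a plain Euclidean distance", {
  m <- docking_model("m", data.frame(
    chain = c("A", "A", "B"), resno = c(1, 2, 1),
    resid = c("ALA", "ALA", "LYS"), elety = c("CA", "CA", "NZ"),
    x = c(1, -1, 3), y = c(0, 0, 4), z = c(0, 0, 0),
    stringsAsFactors = FALSE))
  # site centroid of CA(1,0,0) and CA(-1,0,0) is the origin; 3-4-5 triangle
  expect_equal(distance_parameter(
    m, list(chain = "B", resno = 1, atom = "NZ"), "A", c(1, 2)), 5)
  expect_warning(d <- distance_parameter(
    m, list(chain = "B", resno = 2, atom = "NZ"), "A", c(1, 2)),
    "ligand atom not found")
  expect_true(is.na(d))
})

test_that("conservation aggregation handles empty and unknown residues", {
  grades <- setNames(c(9, 5, 1), c("1", "2", "3"))
  expect_equal(conservation_parameter(c(1, 3), grades), 5)
  expect_equal(conservation_parameter(c(1, 3), grades, aggregate = min), 1)
  expect_true(is.na(conservation_parameter(integer(0), grades)))
  expect_warning(g <- conservation_parameter(c(1, 99), grades), "missing")
  expect_equal(g, 9)
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(chain = "A", resno = 1, grade = 12), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_conservation_table(path), "1..9")
})

test_that("min-max normalisation is bounded, oriented and order-invariant", {
  set.seed(44)
  raw <- random_raw(8)
  rk <- normalize_and_rank(raw)
  for (col in c("norm_cons_a", "norm_cons_b", "norm_distance")) {
    expect_true(all(rk[[col]] >= 0 & rk[[col]] <= 1))
  }
  expect_equal(rk$norm_cons_a[which.max(rk$raw_cons_a)], 1)
  expect_equal(rk$norm_distance[which.min(rk$raw_distance)], 1)  # inverted
  expect_identical(rk$rank, seq_len(8))
  expect_true(all(diff(rk$total) <= 0))
  # permuting the input rows leaves the ranked table unchanged
  perm <- sample(8)
  rk2 <- normalize_and_rank(raw[perm, ])
  rownames(rk2) <- NULL
  expect_equal(rk2, rk)
  # a constant parameter is dropped with a warning, not divided by zero
  raw$raw_cons_b <- 5
  expect_warning(rk3 <- normalize_and_rank(raw), "constant")
  expect_false("norm_cons_b" %in% names(rk3))
  expect_error(normalize_and_rank(raw[1, , drop = FALSE]),
               "at least 2 models")
  raw$raw_cons_a <- 1
  raw$raw_distance <- 2
  expect_error(suppressWarnings(normalize_and_rank(raw)), "no rankable")
  # ties in total break by model id
  tied <- data.frame(model_id = c("m2", "m1"), raw_cons_a = c(3, 1),
                     raw_cons_b = c(1, 3), raw_distance = c(2, 1))
  rt <- normalize_and_rank(tied, use_distance = FALSE)
  expect_equal(rt$total, c(1, 1))
  expect_identical(rt$model_id, c("m1", "m2"))
})

test_that("the planted pose outranks the decoys and survives rescoring", {
  dk <- simulate_docking_set(n_models = 15, seed = 6, dir = tempdir())
  raw <- score_docking_models(dk$models, dk$conservation, dk$chain_a,
                              dk$chain_b, ligand = dk$ligand,
                              site_residues = dk$site_residues)
  rk <- normalize_and_rank(raw)
  expect_identical(rk$model_id[1], dk$planted_id)
  # constrained second round keeps the anchor on top
  rk2 <- constrained_rescore(dk$models, dk$planted_id, radius = 25,
                             mobile_chain = dk$chain_b,
                             conservation = dk$conservation,
                             chain_a = dk$chain_a, chain_b = dk$chain_b,
                             ligand = dk$ligand,
                             site_residues = dk$site_residues)
  expect_lte(nrow(rk2), 15)
  expect_identical(rk2$model_id[1], dk$planted_id)
  # an infinite radius reproduces the unconstrained ranking
  rk3 <- constrained_rescore(dk$models, dk$planted_id, radius = Inf,
                             mobile_chain = dk$chain_b,
                             conservation = dk$conservation,
                             chain_a = dk$chain_a, chain_b = dk$chain_b,
                             ligand = dk$ligand,
                             site_residues = dk$site_residues)
  expect_equal(rk3, rk)
  # a zero radius leaves only the anchor: unranked with a warning
  expect_warning(one <- constrained_rescore(
    dk$models, dk$planted_id, radius = 0, mobile_chain = dk$chain_b,
    conservation = dk$conservation, chain_a = dk$chain_a,
    chain_b = dk$chain_b, ligand = dk$ligand,
    site_residues = dk$site_residues), "fewer than 2")
  expect_equal(nrow(one), 1)
  expect_error(constrained_rescore(dk$models, "model_999", 10, "B"),
               "anchor model not in the set")
})
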