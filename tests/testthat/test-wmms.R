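test_that("weight sets carry provenance and published values", {
  w <- weight_set("unweighted")
  expect_identical(attr(w, "provenance"), "unweighted")
  expect_equal(unname(w["cons_substitution"]), -1)
  wt <- weight_set("homozygous_trained")
  expect_equal(unname(wt["active_site"]), 2.48)
  expect_equal(unname(wt["cons_residue"]), 3.43)
  expect_true(all(is.na(wt[c("deletion", "nonsense_frameshift",
                             "intronic_splice", "mito_leader")])))
})

test_that("wmms_score is a bare dot product and guards NA weights", {
  v <- setNames(numeric(22), mms_parameters())
  v[c("c_term", "d_size")] <- 1
  w <- weight_set("homozygous_trained")
  expect_equal(wmms_score(v, w), unname(w["c_term"] + w["d_size"]))
  # unit weights reproduce the unweighted score for arbitrary vectors
  set.seed(2)
  for (rep in 1:10) {
    v <- setNames(sample(c(0, 0.5, 1), 22, replace = TRUE), mms_parameters())
    expect_equal(wmms_score(v, unit_weights()), mms_score(v))
  }
  v <- setNames(numeric(22), mms_parameters())
  v["deletion"] <- 1
  expect_error(wmms_score(v, weight_set("homozygous_trained")),
               "no weight for active parameter")
  expect_error(wmms_score(c(bogus = 1), unit_weights()), "keys")
})

test_that("noiseless linear data is recovered exactly with R2 = 1", {
  set.seed(101)
  n <- 60
  X <- matrix(rbinom(n * 22, 1, 0.4), n, 22,
              dimnames = list(NULL, mms_parameters()))
  w_true <- setNames(round(runif(22, -1, 2), 2), mms_parameters())
  y <- drop(X %*% w_true) + 1.5
  y <- pmin(12, pmax(0, y))  # keep the response legal
  # clipping may bite; regenerate smaller weights until it doesn't
  while (any(drop(X %*% w_true) + 1.5 != y)) {
    w_true <- setNames(round(runif(22, 0, 0.4), 2), mms_parameters())
    y <- pmin(12, pmax(0, drop(X %*% w_true) + 1.5))
  }
  fit <- wmms_fit(wmms_design(X, y))
  expect_equal(unname(fit$weights), unname(w_true), tolerance = 1e-8)
  expect_equal(fit$intercept, 1.5, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(unname(residuals(fit)), rep(0, n), tolerance = 1e-8)
})

test_that("the fit is a least-squares optimum and row-order invariant", {
  set.seed(7)
  n <- 40
  X <- matrix(rbinom(n * 22, 1, 0.5), n, 22,
              dimnames = list(NULL, mms_parameters()))
  y <- pmin(12, pmax(0, round(rowSums(X[, 1:5]) + rnorm(n))))
  d <- wmms_design(X, y)
  fit <- wmms_fit(d)
  sse <- function(w, b0) sum((y - drop(X %*% w) - b0)^2)
  base <- sse(fit$weights, fit$intercept)
  for (j in setdiff(mms_parameters(), fit$pinned)) {
    for (eps in c(-0.01, 0.01)) {
      w2 <- fit$weights
      w2[j] <- w2[j] + eps
      expect_gt(sse(w2, fit$intercept), base)
    }
  }
  expect_gt(sse(fit$weights, fit$intercept + 0.01), base)
  # permuting rows does not change the solution
  perm <- sample(n)
  fit2 <- wmms_fit(wmms_design(X[perm, ], y[perm]))
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-10)
  expect_equal(fit2$intercept, fit$intercept, tolerance = 1e-10)
  # the reported R2 matches its definition
  expect_equal(fit$r2, 1 - base / sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("all-zero columns are pinned and rank deficiency is flagged", {
  set.seed(9)
  X <- matrix(rbinom(30 * 22, 1, 0.5), 30, 22,
              dimnames = list(NULL, mms_parameters()))
  X[, "mito_leader"] <- 0
  y <- pmin(12, pmax(0, round(rowSums(X[, 1:4]) + rnorm(30, 0, 0.5))))
  fit <- wmms_fit(wmms_design(X, y))
  expect_true("mito_leader" %in% fit$pinned)
  expect_equal(unname(fit$weights["mito_leader"]), 0)
  expect_false(fit$degenerate)

  # duplicated columns -> rank deficient, minimum-norm solution still optimal
  X2 <- X
  X2[, "deletion"] <- X2[, "destabilizing"]
  d2 <- wmms_design(X2, y)
  expect_warning(fit2 <- wmms_fit(d2), "rank-deficient")
  expect_true(fit2$degenerate)
  sse2 <- sum((y - drop(X2 %*% fit2$weights) - fit2$intercept)^2)
  ref <- stats::lm.fit(cbind(1, X2[, colSums(abs(X2)) > 0]), y)
  expect_equal(sse2, sum(ref$residuals^2), tolerance = 1e-8)
})

test_that("design constructors validate and match hand computation", {
  expect_error(wmms_design(matrix(1, 2, 3)), "one column per parameter")
  X <- matrix(0, 2, 22, dimnames = list(NULL, mms_parameters()))
  expect_error(wmms_design(X, c(1, 13)), "outside 0..12")
  expect_error(wmms_design(X, 1), "length")
  expect_error(wmms_fit(wmms_design(X[1, , drop = FALSE], 1)),
               "at least 2 rows")

  ann <- rbind(make_ann("A100V", 100, "A", "V", conservation_grade = 9),
               make_ann("G200R", 200, "G", "R", ddg_kcal_mol = -3))
  coh <- as_gp_cohort(rbind(
    make_patient("P1", allele1 = "A100V", seizures = 3L),
    make_patient("P2", allele1 = "A100V", seizures = 1L),
    make_patient("P3", allele1 = "G200R", cognitive = 2L)))
  d <- design_homozygous(coh, ann)
  expect_equal(nrow(d$x), 2)  # one row per unique mutation
  expect_equal(d$y[d$labels == "A100V"], 2)  # mean of COS 3 and 1
  expect_equal(unname(d$x["A100V", ]),
               unname(derive_parameter_vector(ann[1, ])))

  het <- as_gp_cohort(make_patient(
    "P4", zygosity = "compound_heterozygous", allele1 = "A100V",
    allele2 = "intronic_splice", allele2_class = "intronic_splice",
    seizures = 3L, cognitive = 3L))
  dh <- design_heterozygous(het, ann)
  expect_equal(unname(dh$x[1, "intronic_splice"]), 0.5)
  expect_equal(dh$y, 6)

  stacked <- stack_designs(d, dh)
  expect_equal(nrow(stacked$x), 3)
  expect_error(design_homozygous(coh, ann[2, , drop = FALSE]),
               "no annotation for mutation A100V")
})

test_that("the fitted-model methods behave like the classic idiom", {
  sim <- simulate_cohort(sim_config(seed = 21, n_patients = 80))
  hom <- sim$cohort[sim$cohort$zygosity == "homozygous", ]
  fit <- wmms_fit(design_homozygous(hom, sim$annotations))
  expect_s3_class(fit, "wmms")
  expect_named(coef(fit), c("(Intercept)", mms_parameters()))
  expect_equal(unname(coef(fit)[-1]), unname(fit$weights))
  expect_equal(length(fitted(fit)), nrow(fit$design$x))
  expect_equal(unname(fitted(fit) - fit$intercept), unname(predict(fit)),
               tolerance = 1e-12)
  expect_equal(unname(fitted(fit) + residuals(fit)), fit$design$y,
               tolerance = 1e-10)
  expect_output(print(fit), "R-squared")
  expect_output(print(summary(fit)), "residual sd")
  grDevices::pdf(nullfile())
  expect_silent(plot(fit))
  grDevices::dev.off()

  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(as.matrix(s1) >= 0 & as.matrix(s1) <= 12))
  expect_true(all(as.matrix(s1) == round(as.matrix(s1))))

  # predict on new data equals the bare weighted sum
  v <- fit$design$x[1, , drop = FALSE]
  expect_equal(unname(predict(fit, newdata = v)),
               sum(fit$weights * v))
  expect_equal(unname(predict(fit, newdata = v, include_intercept = TRUE)),
               sum(fit$weights * v) + fit$intercept)
})

test_that("predict_cohort scores per allele and logs skipped patients", {
  sim <- simulate_cohort(sim_config(seed = 31, n_patients = 40))
  scored <- predict_cohort(sim$cohort, sim$annotations,
                           unit_weights(), cutpoint = 4.5)
  expect_equal(nrow(scored), 40)
  hom <- scored$zygosity == "homozygous"
  expect_equal(scored$wmms[hom], scored$wmms_allele1[hom])
  het <- !hom
  expect_equal(scored$wmms[het],
               (scored$wmms_allele1[het] + scored$wmms_allele2[het]) / 2,
               tolerance = 1e-12)
  expect_identical(scored$predicted, ifelse(scored$wmms > 4.5,
                                            "severe", "attenuated"))
  # unknown allele -> skipped with reason, not an error
  missing_ann <- sim$annotations[-match(sim$cohort$allele1[1],
                                        sim$annotations$mutation), ]
  scored2 <- predict_cohort(sim$cohort, missing_ann, unit_weights(),
                            cutpoint = 4.5)
  expect_true(length(attr(scored2, "skipped")) >= 1)
  expect_lt(nrow(scored2), 40)
  expect_error(predict_cohort(sim$cohort, sim$annotations, unit_weights()),
               "cutpoint required")
})
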