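med_kin <- compute_kinship_loco(big_genomes)
med_mk <- big_map$marker[20]

test_that("conditioning a trait on itself removes the QTL signal entirely", {
  st <- simulate_traits(big_genomes, big_covar,
                        list(traits = list(trait_spec(
                          "y", qtl_marker = med_mk, qtl_var = 0.25))),
                        seed = 141)
  mr <- mediation_scan(st$traits$y, st$traits$y, big_genomes, big_covar,
                       med_kin, med_mk)
  expect_equal(mr$lod_conditioned, 0, tolerance = 1e-8)
  expect_equal(mr$lod_drop, mr$lod_original, tolerance = 1e-8)
  expect_true(mr$passes_drop_threshold)
})

test_that("an independent mediator barely moves the LOD", {
  st <- simulate_traits(big_genomes, big_covar,
                        list(traits = list(trait_spec(
                          "y", qtl_marker = med_mk, qtl_var = 0.25))),
                        seed = 142)
  set.seed(143)
  small <- replicate(20, {
    mr <- mediation_scan(st$traits$y, rnorm(400), big_genomes, big_covar,
                         med_kin, med_mk)
    abs(mr$lod_drop) < 0.5
  })
  expect_gte(mean(small), 0.9)
})

test_that("a mediator collinear with the covariates is refused", {
  st <- simulate_traits(big_genomes, big_covar,
                        list(traits = list(trait_spec(
                          "y", qtl_marker = med_mk, qtl_var = 0.25))),
                        seed = 144)
  expect_error(mediation_scan(st$traits$y, big_covar$sex, big_genomes,
                              big_covar, med_kin, med_mk), "collinear")
})

test_that("causal model selection labels the generating architectures", {
  ## chain Q -> M -> T
  st1 <- simulate_traits(big_genomes, big_covar,
                         list(pairs = list(pair_spec(
                           "M", "T", "causal", marker_a = med_mk,
                           qtl_var = 0.3, med_var = 0.6))),
                         seed = 151)
  v1 <- causal_model_selection(st1$traits$T, st1$traits$M,
                               big_genomes$dosage[, med_mk, ], big_covar)
  expect_equal(v1$label, "causal")
  ## reverse chain Q -> T -> M
  st2 <- simulate_traits(big_genomes, big_covar,
                         list(pairs = list(pair_spec(
                           "M", "T", "reactive", marker_a = med_mk,
                           qtl_var = 0.3, med_var = 0.6))),
                         seed = 152)
  v2 <- causal_model_selection(st2$traits$T, st2$traits$M,
                               big_genomes$dosage[, med_mk, ], big_covar)
  expect_equal(v2$label, "reactive")
  ## shared locus, no trait-trait edge
  st3 <- simulate_traits(big_genomes, big_covar,
                         list(pairs = list(pair_spec(
                           "M", "T", "pleiotropic", marker_a = med_mk,
                           qtl_var = 0.3))),
                         seed = 153)
  v3 <- causal_model_selection(st3$traits$T, st3$traits$M,
                               big_genomes$dosage[, med_mk, ], big_covar)
  expect_equal(v3$label, "independent")
  ## tie band: whenever the top-two gap falls inside the margin the
  ## verdict is undecided, whatever the best-scoring model is
  set.seed(154)
  v4 <- causal_model_selection(rnorm(400), rnorm(400),
                               big_genomes$dosage[, med_mk, ], big_covar,
                               margin = Inf)
  expect_equal(v4$label, "undecided")
  v5 <- causal_model_selection(st1$traits$T, st1$traits$M,
                               big_genomes$dosage[, med_mk, ], big_covar,
                               margin = v1$gap + 1)
  expect_equal(v5$label, "undecided")
  expect_error(causal_model_selection(rep(1, 400), rnorm(400),
                                      big_genomes$dosage[, med_mk, ]),
               "zero-variance")
})

test_that("the bidirectional report rejects self-pairs and runs both ways", {
  st <- simulate_traits(big_genomes, big_covar,
                        list(pairs = list(pair_spec(
                          "a", "b", "pleiotropic", marker_a = med_mk,
                          qtl_var = 0.3))),
                        seed = 161)
  expect_error(bidirectional_report(st$traits$a, st$traits$a, big_genomes,
                                    big_covar, med_kin, med_mk),
               "self-pair")
  br <- bidirectional_report(st$traits$a, st$traits$b, big_genomes,
                             big_covar, med_kin, med_mk)
  expect_s3_class(br$a_on_b, "mediation_result")
  expect_s3_class(br$b_on_a, "mediation_result")
  expect_true(br$verdict$label %in%
                c("causal", "reactive", "independent", "undecided"))
})

test_that("an independent pair fails the drop criterion in both directions", {
  st <- simulate_traits(big_genomes, big_covar,
                        list(pairs = list(pair_spec(
                          "a", "b", "independent",
                          marker_a = med_mk,
                          marker_b = big_map$marker[100],
                          qtl_var = 0.25))),
                        seed = 162)
  br <- bidirectional_report(st$traits$a, st$traits$b, big_genomes,
                             big_covar, med_kin, med_mk)
  expect_false(br$a_on_b$passes_drop_threshold)
  expect_false(br$b_on_a$passes_drop_threshold)
})
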