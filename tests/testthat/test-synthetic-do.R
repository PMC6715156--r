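test_that("simulated maps are even grids with consistent physical positions", {
  map <- simulate_map(1, 6, 100, 2)
  expect_equal(map$pos_cM, seq(0, 100, by = 20))
  expect_equal(map$pos_Mbp, seq(0, 50, by = 10))
  expect_equal(nrow(simulate_map(19, 50, 90, 2)), 950)
  ## a 0.02-cM grid on a 10-cM toy chromosome
  fine <- simulate_map(1, chr_length_cM = 10, cM_per_Mbp = 2,
                       spacing_cM = 0.02)
  expect_equal(nrow(fine), 501)
  expect_equal(diff(fine$pos_cM)[1], 0.02)
  expect_error(simulate_map(1, 6, -5), "positive")
  expect_error(simulate_map(1, 1, 100), ">= 2 markers")
})

test_that("dosage slices sum to 2, with and without uncertainty smoothing", {
  d <- fix_genomes$dosage
  expect_true(all(d >= 0 & d <= 2))
  expect_lt(max(abs(apply(d, c(1, 2), sum) - 2)), 1e-8)
  sm <- simulate_do_genomes(fix_map, 30, smooth_w = 0.05, seed = 5)
  expect_lt(max(abs(apply(sm$dosage, c(1, 2), sum) - 2)), 1e-8)
  expect_true(all(sm$dosage >= 0 & sm$dosage <= 2))
})

test_that("zero switch density yields one founder pair per chromosome", {
  g <- simulate_do_genomes(fix_map, 25, switch_density_per_cM = 0, seed = 3)
  for (i in 1:25) for (ch in unique(fix_map$chr)) {
    idx <- which(fix_map$chr == ch)
    slice <- g$dosage[i, idx, , drop = TRUE]
    expect_lte(sum(colSums(slice) > 0), 2)               # <= 2 founders used
    expect_equal(slice, matrix(slice[1, ], nrow = length(idx),
                               ncol = 8, byrow = TRUE),
                 ignore_attr = TRUE)                     # constant along chr
  }
})

test_that("identical seeds give byte-identical simulations", {
  a <- simulate_do_genomes(fix_map, 15, seed = 77)
  b <- simulate_do_genomes(fix_map, 15, seed = 77)
  expect_identical(a, b)
  ta <- simulate_traits(fix_genomes, fix_covar,
                        list(traits = list(trait_spec("x", "microbial"))),
                        seed = 9)
  tb <- simulate_traits(fix_genomes, fix_covar,
                        list(traits = list(trait_spec("x", "microbial"))),
                        seed = 9)
  expect_identical(ta, tb)
})

test_that("founder frequencies are near 1/8 in a large population", {
  map1 <- simulate_map(1, 5, 40, 2)
  g <- simulate_do_genomes(map1, 2000, seed = 11)
  freq <- apply(g$dosage, c(2, 3), mean) / 2   # marker x founder
  se <- sqrt(0.125 * 0.875 / (2 * 2000))
  expect_true(all(abs(freq - 0.125) < 3 * se + 1e-12))
})

test_that("mosaic block counts follow the Poisson switch process", {
  map1 <- simulate_map(1, 201, 100, 2)   # 0.5 cM resolution
  pos <- map1$pos_cM
  set.seed(13)
  blocks <- replicate(1000, {
    fnd <- pleioscan:::sim_mosaic(pos, 100, 0.05)
    length(rle(fnd)$lengths)
  })
  expect_lt(abs(mean(blocks) - (1 + 0.05 * 100)), 0.3)
})

test_that("requested prevalence is hit within 0.05 at n = 400", {
  for (prev in c(0.25, 0.5, 0.9)) {
    st <- simulate_traits(big_genomes, NULL,
                          list(traits = list(trait_spec(
                            "m", "microbial", prevalence = prev))),
                          seed = round(1000 * prev))
    expect_lt(abs(mean(st$traits$m > 0) - prev), 0.05)
  }
})

test_that("a 20%-variance QTL gives trait-genotype correlation near sqrt(0.2)", {
  mk <- big_map$marker[20]
  st <- simulate_traits(big_genomes, NULL,
                        list(traits = list(trait_spec(
                          "y", "clinical", qtl_marker = mk, qtl_var = 0.2))),
                        seed = 21)
  g <- drop(big_genomes$dosage[, mk, ] %*% st$truth$y$effects)
  expect_lt(abs(cor(st$traits$y, g) - sqrt(0.2)), 0.07)
})

test_that("causal architecture d-separates target from locus given mediator", {
  mk <- big_map$marker[15]
  st <- simulate_traits(big_genomes, NULL,
                        list(pairs = list(pair_spec(
                          "M", "T", "causal", marker_a = mk,
                          qtl_var = 0.3, med_var = 0.6))),
                        seed = 31)
  g <- drop(big_genomes$dosage[, mk, ] %*% st$truth$M$effects)
  rT <- resid(lm(st$traits$T ~ st$traits$M))
  rG <- resid(lm(g ~ st$traits$M))
  expect_lt(abs(cor(rT, rG)), 0.15)    # ~3 standard errors at n = 400
})

test_that("polygenic-only traits track the kinship matrix (Mantel-style)", {
  map1 <- simulate_map(3, 25, 60, 2)
  g <- simulate_do_genomes(map1, 300, seed = 41)
  K <- compute_kinship(g)
  n_tr <- 150
  Y <- sapply(seq_len(n_tr), function(i)
    simulate_traits(g, NULL,
                    list(traits = list(trait_spec("p", "clinical",
                                                  h2 = 0.5))),
                    seed = 5000 + i)$traits$p)
  Ys <- scale(Y)
  C <- tcrossprod(Ys) / n_tr
  ut <- upper.tri(K)
  obs <- cor(C[ut], K[ut])
  set.seed(43)
  null <- replicate(199, {
    p <- sample(nrow(K))
    cor(C[ut], K[p, p][ut])
  })
  p_val <- (1 + sum(null >= obs)) / 200
  expect_lt(p_val, 0.05)
})

test_that("bad truth specifications are rejected", {
  expect_error(trait_spec("x", h2 = 1), "h2")
  expect_error(trait_spec("x", qtl_var = 0.6, h2 = 0.5), "budget")
  expect_error(simulate_traits(fix_genomes, NULL,
                               list(traits = list(trait_spec(
                                 "x", qtl_marker = "nope", qtl_var = 0.1)))),
               "not in map")
  expect_error(
    simulate_traits(fix_genomes, NULL,
                    list(pairs = list(structure(list(architecture = "odd"),
                                                class = "list")))),
    "pair_spec")
})
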