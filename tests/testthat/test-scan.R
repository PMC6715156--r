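test_that("kinship matches a direct double-loop summation", {
  g <- simulate_do_genomes(simulate_map(2, 8, 40, 2), 20, seed = 7)
  ks <- compute_kinship_loco(g)
  d <- g$dosage
  other <- which(g$map$chr != "1")
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    s <- 0
    for (m in other) for (f in 1:8) s <- s + d[i, m, f] / 2 * d[j, m, f] / 2
    oracle[i, j] <- s / length(other)
  }
  expect_lt(max(abs(oracle - ks$loco[["1"]])), 1e-10)
  ## symmetry / PSD / diagonal range
  for (K in ks$loco) {
    expect_lt(max(abs(K - t(K))), 1e-10)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    expect_true(all(diag(K) > 0 & diag(K) <= 1 + 1e-12))
  }
})

test_that("identical and disjoint ancestries give the expected kinship", {
  map <- simulate_map(2, 5, 30, 2)
  d <- array(0, dim = c(2, 10, 8),
             dimnames = list(c("i1", "i2"), map$marker, LETTERS[1:8]))
  d[1, , 1] <- 2                      # i1 homozygous founder A everywhere
  d[2, , 1] <- 2                      # i2 identical
  fd <- structure(list(dosage = d, individuals = c("i1", "i2"),
                       founders = LETTERS[1:8], map = map),
                  class = "founder_dosage")
  K <- compute_kinship(fd)
  expect_equal(K[1, 2], K[1, 1])
  d2 <- d
  d2[2, , 1] <- 0
  d2[2, , 2] <- 2                     # disjoint founder
  fd2 <- structure(list(dosage = d2, individuals = c("i1", "i2"),
                        founders = LETTERS[1:8], map = map),
                   class = "founder_dosage")
  expect_equal(compute_kinship(fd2)[1, 2], 0)
  expect_error(compute_kinship_loco(
    structure(list(dosage = d[, 1:5, , drop = FALSE],
                   individuals = c("i1", "i2"), founders = LETTERS[1:8],
                   map = map[map$chr == "1", ]),
              class = "founder_dosage")), "non-LOCO")
})

test_that("null LMM returns h2 = 0 for identity kinship and recovers h2 = 0.5", {
  set.seed(51)
  n <- 120
  X <- cbind(1, rnorm(n))
  fit <- fit_null_lmm(rnorm(n), X, diag(n))
  expect_equal(fit$h2, 0)
  ## parameter recovery under strong family structure
  K <- family_kinship(80, 5)
  L <- chol(K)
  Xb <- cbind(1, rnorm(400))
  err <- replicate(50, {
    u <- drop(crossprod(L, rnorm(400))) * sqrt(0.5)
    y <- drop(Xb %*% c(1, 0.5)) + u + rnorm(400, 0, sqrt(0.5))
    abs(fit_null_lmm(y, Xb, K)$h2 - 0.5)
  })
  expect_lt(median(err), 0.15)
  ## degenerate inputs
  expect_error(fit_null_lmm(drop(X %*% c(2, 1)), X, diag(n)),
               "zero residual variance")
  expect_error(fit_null_lmm(rnorm(n), cbind(X, X[, 2]), diag(n)),
               "rank deficient")
})

test_that("a constant phenotype scans to LOD 0 everywhere", {
  sc <- genome_scan(rep(3, 120), fix_genomes, fix_covar, fix_kinship)
  expect_true(all(sc$lod == 0))
})

test_that("with no kinship the scan equals brute-force ordinary regression", {
  X0 <- cbind(1, model.matrix(~ sex + wave + days_on_diet,
                              fix_covar)[, -1])
  set.seed(61)
  for (rep in 1:5) {
    y <- rnorm(120)
    sc <- genome_scan(y, fix_genomes, fix_covar, kinship = NULL)
    idx <- sample(nrow(fix_map), 8)
    for (k in idx) {
      expect_equal(sc$lod[k],
                   max(0, ols_lod(y, X0, fix_genomes$dosage[, k, ])),
                   tolerance = 1e-8)
    }
  }
})

test_that("LOD stays non-negative with irrelevant covariates", {
  set.seed(62)
  cov2 <- cbind(fix_covar, junk = rnorm(120))
  sc <- genome_scan(rnorm(120), fix_genomes, cov2, fix_kinship)
  expect_true(all(sc$lod >= 0))
  expect_true(all(is.finite(sc$lod)))
})

test_that("missing phenotypes are dropped trait-wise", {
  set.seed(63)
  y <- rnorm(120)
  y[c(5, 40)] <- NA
  sc <- genome_scan(y, fix_genomes, fix_covar, fix_kinship)
  expect_equal(attr(sc, "n"), 118)
  expect_error(genome_scan(rep(NA_real_, 120), fix_genomes), "all-missing")
  ybad <- setNames(rnorm(120), rev(fix_genomes$individuals))
  expect_error(genome_scan(ybad, fix_genomes), "misaligned")
})

test_that("permutation thresholds are monotone and id-label invariant", {
  set.seed(71)
  Y <- matrix(rnorm(120 * 4), 120, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  thr <- permutation_thresholds(Y, fix_genomes, fix_covar, fix_kinship,
                                n_perm = 40, alphas = c(0.05, 0.2, 0.5),
                                seed = 4242)
  expect_true(thr$thresholds["0.05"] >= thr$thresholds["0.2"])
  expect_true(thr$thresholds["0.2"] >= thr$thresholds["0.5"])
  ## renaming individuals changes nothing
  g2 <- fix_genomes
  g2$individuals <- sprintf("mouse_%03d", seq_along(g2$individuals))
  dimnames(g2$dosage)[[1]] <- g2$individuals
  k2 <- compute_kinship_loco(g2)
  thr2 <- permutation_thresholds(Y, g2, fix_covar, k2, n_perm = 40,
                                 alphas = c(0.05, 0.2, 0.5), seed = 4242)
  expect_equal(thr$thresholds, thr2$thresholds)
  expect_error(permutation_thresholds(Y, fix_genomes, n_perm = 5), ">= 10")
})

test_that("a planted QTL is found at the right marker", {
  mk <- big_map$marker[60]            # chr 2
  st <- simulate_traits(big_genomes, big_covar,
                        list(traits = list(trait_spec(
                          "y", qtl_marker = mk, qtl_var = 0.2, h2 = 0.2))),
                        seed = 81)
  kin <- compute_kinship_loco(big_genomes)
  sc <- genome_scan(st$traits$y, big_genomes, big_covar, kin)
  top <- sc[which.max(sc$lod), ]
  expect_equal(top$chr, "2")
  expect_lt(abs(top$pos_cM - big_map$pos_cM[big_map$marker == mk]), 5)
  expect_gt(max(sc$lod), 6)
})
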