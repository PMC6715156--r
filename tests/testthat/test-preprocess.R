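toy_counts <- function() {
  m <- rbind(c(3, 10, 0), c(0, 4, 0), c(0, 7, 0), c(0, 2, 0), c(0, 5, 0))
  dimnames(m) <- list(paste0("s", 1:5), c("f1", "f2", "f3"))
  m
}

test_that("prevalence filter keeps the inclusive boundary and drops absent features", {
  m <- toy_counts()                 # prevalences 0.2, 1.0, 0.0
  kept <- cmm_filter(m, 0.20)
  expect_identical(colnames(kept), c("f1", "f2"))
  expect_identical(cmm_filter(kept, 0.20), kept)       # idempotent
  ## 3-feature toy with prevalences {0.2, 0.4, 0.0}
  m2 <- cbind(f1 = c(1, 0, 0, 0, 0), f2 = c(1, 2, 0, 0, 0),
              f3 = rep(0, 5))
  expect_equal(ncol(cmm_filter(m2, 0.20)), 2)
  expect_error(cmm_filter(m[, 0, drop = FALSE]), "empty")
  expect_error(cmm_filter(m, 0), "min_prevalence")
})

test_that("agglomeration sums lineages and conserves totals", {
  counts <- matrix(c(3, 4, 5, 1, 2), 1, 5,
                   dimnames = list("s1", paste0("esv", 1:5)))
  tax <- setNames(c("k__B;p__F;c__C;o__O;f__L;g__X",
                    "k__B;p__F;c__C;o__O;f__L;g__X",
                    "k__B;p__F;c__C;o__O;f__R;g__Y",
                    "k__B;p__F;c__C;o__O;f__R;g__",
                    "k__B;p__F;c__C;o__O;f__R;g__Z"), paste0("esv", 1:5))
  gen <- agglomerate(counts, tax, "genus")
  expect_equal(unname(gen[1, "k__B;p__F;c__C;o__O;f__L;g__X"]), 7)
  expect_true("unclassified-f__R" %in% colnames(gen))
  fam <- agglomerate(counts, tax, "family")
  expect_equal(ncol(fam), 2)                            # 2 families
  expect_equal(sum(fam), sum(counts))                   # conservation
  phy <- agglomerate(counts, tax, "phylum")
  expect_equal(sum(phy), sum(counts))
  tax_bad <- tax
  tax_bad["esv2"] <- paste(rep("k__x", 9), collapse = ";")
  expect_error(agglomerate(counts, tax_bad, "genus"), "esv2")
})

test_that("CSS normalization matches the hand case and is scale invariant", {
  m <- matrix(c(10, 10, 10, 10), 1, 4,
              dimnames = list("s1", paste0("f", 1:4)))
  out <- css_normalize(m, 0.5, 1000)
  expect_equal(unname(out[1, ]), rep(250, 4))
  expect_identical(attr(out, "transform"), "css")

  set.seed(8)
  counts <- matrix(rnbinom(60, mu = 20, size = 1), 6, 10)
  counts[1, ] <- counts[1, ] + 1                  # ensure positive sample
  base <- css_normalize(counts)
  scaled <- counts
  scaled[1, ] <- scaled[1, ] * 7
  expect_equal(css_normalize(scaled)[1, ], base[1, ], tolerance = 1e-12)

  ## identical composition at library sizes 1e3 and 1e5
  comp <- c(1, 2, 3, 4)
  two <- rbind(a = comp * 100, b = comp * 10000)
  norm <- css_normalize(two)
  expect_equal(unname(norm[1, ]), unname(norm[2, ]))

  allzero <- rbind(a = c(1, 2), bad = c(0, 0))
  expect_error(css_normalize(allzero), "bad")
})

test_that("rank-inverse-normal matches quantile oracles and handles ties", {
  expect_equal(rank_inverse_normal(c(5, 1, 9))[1], 0)
  expect_equal(rank_inverse_normal(c(5, 1, 9))[2], qnorm(0.625 / 3.25),
               tolerance = 1e-6)
  tied <- rank_inverse_normal(c(2, 2, 5, 7))
  expect_equal(tied[1], tied[2])
  x <- c(0.3, -1, 2, 5, 4, 0.1, 9, -3)
  z <- rank_inverse_normal(x)
  expect_lt(abs(mean(z)), 1e-6)
  expect_true(all(diff(z[order(x)]) > 0))              # monotone
  withna <- rank_inverse_normal(c(1, NA, 3, 2))
  expect_true(is.na(withna[2]))
  expect_error(rank_inverse_normal(c(1, 1, 1)), "constant")
  expect_error(rank_inverse_normal(c(1, 2)), ">= 3")
})

test_that("internal-standard normalization reproduces the worked example", {
  m <- matrix(c(100, 200), 2, 1, dimnames = list(c("a", "b"), "met"))
  expect_equal(unname(internal_standard_normalize(m, c(10, 20))[, 1]),
               c(150, 150))
  ## equal IS areas: identity
  expect_equal(internal_standard_normalize(m, c(7, 7)), m)
  ## single sample: identity
  one <- m[1, , drop = FALSE]
  expect_equal(internal_standard_normalize(one, 42), one)
  ## zeros preserved
  mz <- matrix(c(0, 5), 2, 1, dimnames = list(c("a", "b"), "met"))
  expect_equal(unname(internal_standard_normalize(mz, c(10, 20))[1, 1]), 0)
  expect_error(internal_standard_normalize(m, c(10, 0)), "b")
  ## idempotent when re-run with a constant IS channel at the mean
  out <- internal_standard_normalize(m, c(10, 20))
  again <- internal_standard_normalize(out, rep(15, 2))
  expect_equal(again, out)
})

test_that("log2 transform obeys the log laws and rejects negatives", {
  expect_equal(log2_metabolites(8), 3)
  expect_equal(log2_metabolites(0, pseudo = 1), 0)
  x <- c(2, 5, 9)
  expect_equal(log2_metabolites(2 * x), log2_metabolites(x) + 1)
  expect_error(log2_metabolites(-1), "negative")
})
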