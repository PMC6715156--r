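## Small shared fixtures, built once per test run.  Sizes are deliberately
## modest; the heavier calibration/power simulations live in
## test-acceptance.R at their full stated sizes.

fix_map <- simulate_map(n_chromosomes = 2, markers_per_chr = 20,
                        chr_length_cM = 50, cM_per_Mbp = 2)
fix_genomes <- simulate_do_genomes(fix_map, 120, seed = 20240901)
fix_covar <- simulate_covariates(120, n_waves = 3, seed = 20240902)
fix_kinship <- compute_kinship_loco(fix_genomes)

## medium population for recovery-style unit tests
big_map <- simulate_map(n_chromosomes = 3, markers_per_chr = 40,
                        chr_length_cM = 80, cM_per_Mbp = 2)
big_genomes <- simulate_do_genomes(big_map, 400, seed = 20240903)
big_covar <- simulate_covariates(400, seed = 20240904)

## family-block kinship with unit diagonal: strong, well-identified
## structure for variance-component recovery tests
family_kinship <- function(n_fam, fam_size, rho = 0.5) {
  fam <- rho * matrix(1, fam_size, fam_size)
  diag(fam) <- 1
  kronecker(diag(n_fam), fam)
}

## independent brute-force LOD at one marker: ordinary regression via lm()
ols_lod <- function(y, X0, d8) {
  n <- length(y)
  f0 <- lm(y ~ X0 - 1)
  f1 <- lm(y ~ X0 + d8[, 1:7] - 1)
  (n / 2) * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
}
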