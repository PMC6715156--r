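#' Simulate Diversity Outbred style founder mosaic genomes
#'
#' Each individual carries, per chromosome, two independent founder mosaics.
#' Founder identity switches along the chromosome as a homogeneous Poisson
#' process on the centimorgan scale; after a switch the new founder is drawn
#' uniformly from the other seven (so every switch is a real block
#' boundary).  The returned founder dosage at a marker is the sum of the two
#' haplotype indicator tracks, an `individuals x markers x 8` array whose
#' slices sum to 2.  Optionally each slice is mixed with a symmetric
#' Dirichlet draw to emulate the soft haplotype probabilities produced by an
#' HMM reconstruction; the mixed slices still sum to 2.
#'
#' @param map a `genetic_map` from [simulate_map()] (or equivalent data
#'   frame).
#' @param n_individuals number of individuals.
#' @param switch_density_per_cM expected founder switches per cM per
#'   haplotype (default 0.2, approximating roughly 20 outbreeding
#'   generations' worth of block structure).
#' @param smooth_w weight in `[0, 1)` of the Dirichlet uncertainty
#'   component (0 = hard mosaics, the default).
#' @param smooth_alpha Dirichlet concentration for the uncertainty mix.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A list of class `"founder_dosage"` with elements `dosage`
#'   (n x m x 8 array, dimnames individual/marker/founder), `individuals`,
#'   `founders` (fixed `LETTERS[1:8]`, A/J through WSB order), and `map`.
#' @export
simulate_do_genomes <- function(map, n_individuals,
                                switch_density_per_cM = 0.2,
                                smooth_w = 0, smooth_alpha = 1,
                                seed = NULL) {
  validate_map(map)
  if (nrow(map) == 0L) stop("empty map")
  if (switch_density_per_cM < 0) stop("switch density must be >= 0")
  if (smooth_w < 0 || smooth_w >= 1) stop("smooth_w must be in [0, 1)")
  ids <- sprintf("DO%04d", seq_len(n_individuals))
  founders <- LETTERS[1:8]
  chrs <- unique(map$chr)

  dosage <- with_seed(seed, {
    d <- array(0, dim = c(n_individuals, nrow(map), 8),
               dimnames = list(ids, map$marker, founders))
    for (ch in chrs) {
      idx <- which(map$chr == ch)
      pos <- map$pos_cM[idx]
      len <- max(pos) - min(pos)
      for (i in seq_len(n_individuals)) {
        slice <- matrix(0, length(idx), 8)
        for (hap in 1:2) {
          fnd <- sim_mosaic(pos, len, switch_density_per_cM)
          slice[cbind(seq_along(idx), fnd)] <-
            slice[cbind(seq_along(idx), fnd)] + 1
        }
        d[i, idx, ] <- slice
      }
    }
    if (smooth_w > 0) {
      nm <- n_individuals * nrow(map)
      g <- matrix(rgamma(nm * 8, shape = smooth_alpha), nm, 8)
      dir <- g / rowSums(g)
      flat <- matrix(aperm(d, c(1, 2, 3)), nm, 8)
      flat <- (1 - smooth_w) * flat + smooth_w * 2 * dir
      d <- array(flat, dim = dim(d), dimnames = dimnames(d))
    }
    d
  })

  structure(list(dosage = dosage, individuals = ids, founders = founders,
                 map = map),
            class = "founder_dosage")
}

## founder index at each marker position for one simulated gamete
sim_mosaic <- function(pos, len, density) {
  n_sw <- if (density > 0 && len > 0) rpois(1, density * len) else 0L
  start <- sample.int(8, 1)
  if (n_sw == 0L) return(rep(start, length(pos)))
  brk <- sort(runif(n_sw, min(pos), max(pos)))
  fnd <- integer(n_sw + 1)
  fnd[1] <- start
  for (k in seq_len(n_sw))             # never return to the current founder
    fnd[k + 1] <- sample(setdiff(1:8, fnd[k]), 1)
  fnd[findInterval(pos, brk) + 1]
}

#' @export
print.founder_dosage <- function(x, ...) {
  cat(sprintf("founder_dosage: %d individuals, %d markers, %d founders, %d chromosomes\n",
              dim(x$dosage)[1], dim(x$dosage)[2], dim(x$dosage)[3],
              length(unique(x$map$chr))))
  invisible(x)
}

#' Simulate study covariates
#'
#' One row per individual: binary sex, experimental wave (categorical, up to
#' five levels) and days on diet drawn uniformly on 147--175 days (21--25
#' weeks).
#'
#' @param n_individuals number of individuals.
#' @param n_waves number of waves (<= 5).
#' @param seed integer seed.
#' @return data frame with columns `id`, `sex` (0/1), `wave` (factor),
#'   `days_on_diet` (integer).
#' @export
simulate_covariates <- function(n_individuals, n_waves = 5, seed = NULL) {
  if (n_waves > 5) stop("wave levels must be <= 5")
  with_seed(seed, data.frame(
    id = sprintf("DO%04d", seq_len(n_individuals)),
    sex = rbinom(n_individuals, 1, 0.5),
    wave = factor(sample.int(n_waves, n_individuals, replace = TRUE),
                  levels = seq_len(n_waves)),
    days_on_diet = sample(147:175, n_individuals, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}
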