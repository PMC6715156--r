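#' Declare a simulated trait
#'
#' Helper constructing one entry of a truth specification for
#' [simulate_traits()].  The latent trait is built on a unit-variance
#' budget: `qtl_var` (QTL) + `h2` (polygenic) + residual = 1, with optional
#' additive covariate effects added on top of that budget.
#'
#' @param name trait name.
#' @param class one of `"clinical"`, `"microbial"`, `"metabolite"`.
#' @param qtl_marker marker id carrying the QTL, or `NULL` for none.
#' @param effects 8-vector of founder effects (centered to mean 0); default
#'   is a balanced +/- split across the founders.
#' @param qtl_var fraction of latent variance explained by the QTL.
#' @param h2 polygenic heritability in `[0, 1)`.
#' @param covar_beta named numeric vector of effects on standardized
#'   covariate columns (names among `sex`, `days_on_diet`, `wave`).
#' @param prevalence target fraction of individuals with nonzero counts
#'   (microbial class only).
#' @param base_mean,dispersion negative-binomial mean scale and size
#'   (microbial class only).
#' @return list of class `"trait_spec"`.
#' @export
trait_spec <- function(name, class = c("clinical", "microbial", "metabolite"),
                       qtl_marker = NULL, effects = NULL, qtl_var = 0,
                       h2 = 0, covar_beta = NULL, prevalence = 0.9,
                       base_mean = 100, dispersion = 2) {
  class <- match.arg(class)
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0, 1)")
  if (qtl_var < 0 || qtl_var + h2 >= 1)
    stop("qtl_var + h2 must be < 1 (unit variance budget)")
  if (is.null(effects)) effects <- c(1, 1, 1, 1, -1, -1, -1, -1)
  if (length(effects) != 8) stop("effects must be an 8-vector")
  effects <- effects - mean(effects)
  structure(list(name = name, class = class, qtl_marker = qtl_marker,
                 effects = effects, qtl_var = qtl_var, h2 = h2,
                 covar_beta = covar_beta, prevalence = prevalence,
                 base_mean = base_mean, dispersion = dispersion),
            class = "trait_spec")
}

#' Declare a simulated trait pair with known causal architecture
#'
#' @param name_a,name_b trait names (a is the putative mediator/microbe
#'   side, b the target/metabolite side by convention).
#' @param architecture one of `"pleiotropic"` (one shared locus),
#'   `"linked"` (two distinct loci), `"causal"` (Q -> a -> b, no direct
#'   path), `"reactive"` (Q -> b -> a), `"independent"`.
#' @param marker_a,marker_b QTL marker ids (marker_b used by `linked` and
#'   `independent`).
#' @param qtl_var QTL variance fraction for the directly mapped trait(s).
#' @param med_var variance fraction of the downstream trait explained by
#'   the upstream trait (causal/reactive).
#' @param h2 polygenic heritability applied to directly mapped traits.
#' @param classes length-2 character of trait classes for a and b.
#' @param prevalence prevalence passed to a microbial-class member of the
#'   pair.
#' @param effects_a,effects_b founder effect 8-vectors (defaults as in
#'   [trait_spec()]; pleiotropic pairs share `effects_a`).
#' @return list of class `"pair_spec"`.
#' @export
pair_spec <- function(name_a, name_b,
                      architecture = c("pleiotropic", "linked", "causal",
                                       "reactive", "independent"),
                      marker_a, marker_b = NULL, qtl_var = 0.2,
                      med_var = 0.5, h2 = 0,
                      classes = c("clinical", "clinical"),
                      prevalence = 0.9,
                      effects_a = NULL, effects_b = NULL) {
  architecture <- match.arg(architecture)
  if (architecture %in% c("linked", "independent") && is.null(marker_b))
    stop("architecture '", architecture, "' needs marker_b")
  structure(list(name_a = name_a, name_b = name_b,
                 architecture = architecture,
                 marker_a = marker_a, marker_b = marker_b,
                 qtl_var = qtl_var, med_var = med_var, h2 = h2,
                 classes = classes, prevalence = prevalence,
                 effects_a = effects_a, effects_b = effects_b),
            class = "pair_spec")
}

#' Simulate traits over simulated genomes with known truth
#'
#' Latent traits are `dosage %*% founder effects + covariate effects +
#' polygenic term + Gaussian noise`, with the polygenic term drawn with
#' covariance proportional to the overall kinship matrix of the simulated
#' genomes.  Microbial-class traits pass the latent value through a
#' monotone log link into over-dispersed negative binomial counts with a
#' sample-specific library size; the requested prevalence is hit by zeroing
#' the lowest-latent individuals (structural zeros).  Metabolite-class
#' traits are exponentiated into log-normal peak areas and paired with an
#' internal-standard channel sharing the per-sample injection factor.
#'
#' @param dosage a `founder_dosage` object.
#' @param covariates optional covariate data frame from
#'   [simulate_covariates()].
#' @param truth_spec list with elements `traits` (list of [trait_spec()])
#'   and/or `pairs` (list of [pair_spec()]).
#' @param seed integer seed.
#' @return list of class `"sim_traits"`: `traits` (data frame, first column
#'   `id`), `classes` (named character), `truth` (per-trait marker, scaled
#'   effects, h2, latent values), `pairs` (architecture tags), `is_area`
#'   (internal-standard channel, present when any metabolite trait is
#'   simulated).
#' @export
simulate_traits <- function(dosage, covariates = NULL, truth_spec,
                            seed = NULL) {
  stopifnot(inherits(dosage, "founder_dosage"))
  specs <- expand_pairs(truth_spec, dosage$map)
  n <- length(dosage$individuals)
  markers <- dimnames(dosage$dosage)[[2]]
  for (s in specs$traits)
    if (!is.null(s$qtl_marker) && !(s$qtl_marker %in% markers))
      stop("qtl_marker '", s$qtl_marker, "' not in map")

  need_poly <- any(vapply(specs$traits, function(s) s$h2 > 0, logical(1)))
  Kchol <- NULL
  if (need_poly) {
    K <- compute_kinship(dosage)
    Kchol <- chol(K + diag(1e-6, n))
  }
  Xc <- if (!is.null(covariates)) covar_design(covariates, n) else NULL

  with_seed(seed, {
    latents <- list()
    truth <- list()
    ## upstream traits first so chain architectures can condition on them
    ord <- order(vapply(specs$traits, function(s) !is.null(s$upstream),
                        logical(1)))
    for (s in specs$traits[ord]) {
      g <- 0
      eff_scaled <- rep(0, 8)
      if (!is.null(s$upstream)) {             # downstream of a chain
        up <- std(latents[[s$upstream]])
        lat <- sqrt(s$med_var) * up +
          sqrt(1 - s$med_var) * rnorm(n)
      } else {
        resid_var <- 1 - s$qtl_var - s$h2
        if (!is.null(s$qtl_marker) && s$qtl_var > 0) {
          raw <- dosage$dosage[, s$qtl_marker, ] %*% s$effects
          sdr <- sd(raw)
          if (sdr < 1e-12) stop("QTL monomorphic at ", s$qtl_marker)
          g <- sqrt(s$qtl_var) * (raw - mean(raw)) / sdr
          eff_scaled <- s$effects * sqrt(s$qtl_var) / sdr
        }
        u <- if (s$h2 > 0) {
          z <- drop(crossprod(Kchol, rnorm(n)))
          sqrt(s$h2) * std(z)
        } else 0
        lat <- drop(g) + u + sqrt(resid_var) * rnorm(n)
      }
      if (!is.null(s$covar_beta) && !is.null(Xc)) {
        for (nmcb in names(s$covar_beta)) {
          cols <- grep(paste0("^", nmcb), colnames(Xc))
          if (!length(cols)) stop("covariate '", nmcb, "' not found")
          lat <- lat + rowSums(Xc[, cols, drop = FALSE]) * s$covar_beta[[nmcb]]
        }
      }
      latents[[s$name]] <- lat
      truth[[s$name]] <- list(class = s$class, qtl_marker = s$qtl_marker,
                              effects = eff_scaled, h2 = s$h2,
                              qtl_var = s$qtl_var, latent = lat)
    }

    ## observation layer
    any_metab <- any(vapply(specs$traits, function(s)
      s$class == "metabolite", logical(1)))
    any_micro <- any(vapply(specs$traits, function(s)
      s$class == "microbial", logical(1)))
    inj <- if (any_metab) exp(rnorm(n, 0, 0.3)) else NULL
    is_area <- if (any_metab) 1e4 * inj else NULL
    ## one sequencing depth per individual, shared by every microbial trait
    lib <- if (any_micro) exp(rnorm(n, 0, 0.5)) else NULL
    obs <- list()
    for (s in specs$traits) {
      lat <- latents[[s$name]]
      obs[[s$name]] <- switch(s$class,
        clinical = lat,
        metabolite = exp(log(1e5) + 0.5 * lat) * inj,
        microbial = {
          mu <- s$base_mean * exp(lat) * lib
          cnt <- rnbinom(n, size = s$dispersion, mu = mu)
          nzero <- floor((1 - s$prevalence) * n)
          if (nzero > 0) cnt[order(lat)[seq_len(nzero)]] <- 0L
          cnt
        })
    }
    traits <- data.frame(id = dosage$individuals, obs,
                         check.names = FALSE, stringsAsFactors = FALSE)
    structure(list(
      traits = traits,
      classes = vapply(specs$traits, function(s) s$class, character(1),
                       USE.NAMES = FALSE) |>
        setNames(vapply(specs$traits, function(s) s$name, character(1))),
      truth = truth, pairs = specs$pairs, is_area = is_area
    ), class = "sim_traits")
  })
}

## turn pair specs into per-trait specs plus architecture bookkeeping
expand_pairs <- function(truth_spec, map) {
  traits <- truth_spec$traits %||% list()
  pairs <- list()
  for (p in truth_spec$pairs %||% list()) {
    if (!inherits(p, "pair_spec"))
      stop("unknown architecture entry; use pair_spec()")
    a <- trait_spec(p$name_a, p$classes[1], qtl_marker = p$marker_a,
                    effects = p$effects_a, qtl_var = p$qtl_var, h2 = p$h2,
                    prevalence = p$prevalence %||% 0.9)
    b <- trait_spec(p$name_b, p$classes[2], effects = p$effects_b,
                    prevalence = p$prevalence %||% 0.9)
    switch(p$architecture,
      pleiotropic = {
        b$qtl_marker <- p$marker_a
        b$qtl_var <- p$qtl_var
        b$effects <- if (is.null(p$effects_b)) a$effects else b$effects
        b$h2 <- p$h2
      },
      linked = {
        b$qtl_marker <- p$marker_b
        b$qtl_var <- p$qtl_var
        b$h2 <- p$h2
      },
      causal = {                 # Q -> a -> b, no direct Q -> b edge
        b$upstream <- p$name_a
        b$med_var <- p$med_var
      },
      reactive = {               # Q -> b -> a
        b$qtl_marker <- p$marker_a
        b$qtl_var <- p$qtl_var
        b$h2 <- p$h2
        a$qtl_marker <- NULL
        a$qtl_var <- 0
        a$upstream <- p$name_b
        a$med_var <- p$med_var
      },
      independent = {
        b$qtl_marker <- p$marker_b
        b$qtl_var <- p$qtl_var
        b$h2 <- p$h2
      },
      stop("unknown architecture: ", p$architecture))
    traits <- c(traits, list(a, b))
    pairs[[length(pairs) + 1L]] <-
      list(name_a = p$name_a, name_b = p$name_b,
           architecture = p$architecture,
           marker_a = p$marker_a, marker_b = p$marker_b)
  }
  list(traits = traits, pairs = pairs)
}

std <- function(x) (x - mean(x)) / sd(x)

## model matrix (no intercept) with standardized numeric columns
covar_design <- function(covariates, n = nrow(covariates)) {
  stopifnot(nrow(covariates) == n)
  cols <- setdiff(names(covariates), "id")
  X <- model.matrix(~ . - 1, data = covariates[, cols, drop = FALSE])
  for (j in seq_len(ncol(X)))
    if (length(unique(X[, j])) > 2) X[, j] <- drop(scale(X[, j]))
  X
}
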