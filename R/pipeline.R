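#' Default pipeline configuration
#'
#' The configuration is a nested list (serializable to/from YAML) with one
#' block per stage.  Unknown keys are rejected by [run_pipeline()], and
#' every stochastic stage derives its own child seed from the global
#' `seed`, so a rerun with the same configuration is byte-identical.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "pleioscan_run",
    stages = list(simulate = TRUE, preprocess = TRUE, scan = TRUE,
                  permute = TRUE, peaks = TRUE, comap = TRUE,
                  pleiotropy = TRUE, mediation = TRUE, report = TRUE),
    simulate = list(
      n_individuals = 200L, n_chromosomes = 5L, markers_per_chr = 40L,
      chr_length_cM = 80, cM_per_Mbp = 2, switch_density_per_cM = 0.2,
      n_waves = 3L,
      pair = list(architecture = "pleiotropic", chr = "1",
                  marker_index = 20L, marker_index_b = NULL,
                  qtl_var = 0.5, med_var = 0.5, prevalence = 0.95,
                  classes = c("microbial", "metabolite")),
      background = list(n_microbial = 20L, n_metabolite = 4L, h2 = 0.3,
                        prevalence = 0.8)),
    input = list(map = NULL, dosage = NULL, traits = NULL,
                 covariates = NULL),
    preprocess = list(min_prevalence = 0.2, css_quantile = 0.5,
                      css_scale = 1000, log2_pseudo = 0,
                      rint_offset = 0.375),
    scan = list(use_kinship = TRUE),
    permute = list(n_perm = 100L, alphas = c(0.05, 0.2, 0.5),
                   pooled = TRUE),
    peaks = list(threshold = 6.1, min_separation_cM = 10,
                 interval_prob = 0.95),
    comap = list(lod_min = 6.1, q_cutoff = 0.01, abs_rho_cutoff = 0.35),
    pleiotropy = list(B = 200L, pad_cM = 2),
    mediation = list(drop_threshold = 2, margin = 2)
  )
}

validate_config <- function(config, defaults = default_config(),
                            path = character(0)) {
  if (!is.list(config)) stop("config must be a list (or YAML file path)")
  for (key in names(config)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", full, "'")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(config[[key]]))
      validate_config(config[[key]], defaults[[key]], c(path, key))
  }
  invisible(TRUE)
}

merge_config <- function(config, defaults = default_config()) {
  out <- defaults
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(config[[key]])) {
      out[[key]] <- merge_config(config[[key]], defaults[[key]])
    } else {
      out[[key]] <- config[[key]]
    }
  }
  out
}

#' Run the full co-mapping pipeline
#'
#' Sequences simulate/ingest, trait preparation, genome scans, permutation
#' thresholds, peak calling, microbe-metabolite co-mapping, the pleiotropy
#' bootstrap for each co-mapped pair, bidirectional mediation, and report
#' generation.  All tabular outputs are CSV/TSV/JSON in the run directory,
#' and a manifest records the md5 of every output, the seeds, the
#' thresholds actually applied, and the package version.  A stage failure
#' halts the run with the stage name; outputs of completed stages are kept.
#'
#' @param config nested list (see [default_config()]) or path to a YAML
#'   file; partial configurations are merged over the defaults.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return invisibly, a list with the stage results and `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_config(config)
  cfg <- merge_config(config)
  out <- out_dir %||% cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg, out_dir = out)
  stage <- function(name, enabled, fn) {
    if (!enabled) return(NULL)
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- simulate / ingest -------------------------------------------------
  res$data <- stage("simulate", TRUE, function() {
    if (cfg$stages$simulate) simulate_stage(cfg, out)
    else ingest_stage(cfg)
  })
  dat <- res$data

  ## ---- preprocess --------------------------------------------------------
  res$prepared <- stage("preprocess", cfg$stages$preprocess, function()
    preprocess_stage(dat, cfg, out))
  prepared <- res$prepared %||%
    list(traits = dat$traits$traits, classes = dat$traits$classes)

  ## ---- scans -------------------------------------------------------------
  res$scans <- stage("scan", cfg$stages$scan, function() {
    kin <- if (cfg$scan$use_kinship) compute_kinship_loco(dat$dosage)
    prep <- scan_prep(dat$dosage, dat$covariates, kin)
    Y <- count_matrix(prepared$traits)
    scans <- lapply(colnames(Y), function(tr)
      genome_scan(Y[, tr], dat$dosage, dat$covariates, kin, prep = prep))
    names(scans) <- colnames(Y)
    long <- do.call(rbind, lapply(names(scans), function(tr)
      data.frame(trait = tr, marker = scans[[tr]]$marker,
                 lod = scans[[tr]]$lod, stringsAsFactors = FALSE)))
    write.csv(long, file.path(out, "scans.csv"), row.names = FALSE)
    list(scans = scans, kinship = kin)
  })

  ## ---- permutation thresholds -------------------------------------------
  res$thresholds <- stage("permute", cfg$stages$permute, function() {
    thr <- permutation_thresholds(
      prepared$traits, dat$dosage, dat$covariates, res$scans$kinship,
      n_perm = cfg$permute$n_perm, alphas = cfg$permute$alphas,
      pooled = cfg$permute$pooled, seed = child_seed(cfg$seed, "permute"))
    jsonlite::write_json(
      list(alphas = thr$alphas, thresholds = unname(thr$thresholds),
           n_perm = thr$n_perm, pooled = thr$pooled),
      file.path(out, "thresholds.json"), auto_unbox = TRUE, digits = NA)
    thr
  })

  ## ---- peaks -------------------------------------------------------------
  res$peaks <- stage("peaks", cfg$stages$peaks, function() {
    Y <- count_matrix(prepared$traits)
    all_peaks <- do.call(rbind, lapply(names(res$scans$scans), function(tr) {
      pk <- find_peaks(res$scans$scans[[tr]], cfg$peaks$threshold,
                       cfg$peaks$min_separation_cM, cfg$peaks$interval_prob,
                       y = Y[, tr], dosage = dat$dosage,
                       covariates = dat$covariates,
                       kinship = res$scans$kinship)
      if (nrow(pk) == 0) return(NULL)
      cbind(trait = tr,
            trait_class = unname(prepared$classes[tr]),
            pk, stringsAsFactors = FALSE)
    }))
    if (is.null(all_peaks))
      all_peaks <- cbind(trait = character(0), trait_class = character(0),
                         find_peaks(res$scans$scans[[1]], 1e6))
    cols <- c("trait", "trait_class", "chr", "pos_Mbp", "pos_cM", "lod",
              "ci_lo", "ci_hi", paste0("coef_", LETTERS[1:8]))
    write.csv(all_peaks[, cols], file.path(out, "peaks.csv"),
              row.names = FALSE)
    all_peaks
  })

  ## ---- co-mapping --------------------------------------------------------
  res$comap <- stage("comap", cfg$stages$comap, function() {
    pk <- res$peaks
    mic <- pk[pk$trait_class == "microbial", , drop = FALSE]
    met <- pk[pk$trait_class == "metabolite", , drop = FALSE]
    pairs <- find_overlaps(mic, met, cfg$comap$lod_min)
    write.csv(pairs, file.path(out, "comap_pairs.csv"), row.names = FALSE)
    Y <- prepared$traits
    micnames <- names(prepared$classes)[prepared$classes == "microbial"]
    metnames <- names(prepared$classes)[prepared$classes == "metabolite"]
    screen <- if (length(micnames) && length(metnames))
      spearman_bh_screen(Y[, c("id", micnames), drop = FALSE],
                         Y[, c("id", metnames), drop = FALSE],
                         cfg$comap$q_cutoff, cfg$comap$abs_rho_cutoff)
    if (!is.null(screen))
      write.csv(screen, file.path(out, "screen.csv"), row.names = FALSE)
    list(pairs = pairs, screen = screen)
  })

  ## ---- pleiotropy per co-mapped pair ------------------------------------
  res$pleio <- stage("pleiotropy", cfg$stages$pleiotropy, function() {
    pairs <- res$comap$pairs
    if (is.null(pairs) || nrow(pairs) == 0) return(list())
    Y <- count_matrix(prepared$traits)
    map <- dat$dosage$map
    results <- lapply(seq_len(nrow(pairs)), function(i) {
      pr <- pairs[i, ]
      sel <- map$chr == pr$chr & map$pos_Mbp >= pr$overlap_lo &
        map$pos_Mbp <= pr$overlap_hi
      lo <- min(map$pos_cM[sel]); hi <- max(map$pos_cM[sel])
      mk <- interval_markers(map, pr$chr, lo, hi, cfg$pleiotropy$pad_cM)
      ## tight support intervals can leave a degenerate grid; widen around
      ## the overlap until the two-locus surface has room to move
      chr_mk <- map$marker[map$chr == pr$chr]
      while (length(mk) < min(8L, length(chr_mk))) {
        ctr <- match(mk[ceiling(length(mk) / 2)], chr_mk)
        lo_i <- max(1L, ctr - ceiling((length(mk) + 2) / 2))
        hi_i <- min(length(chr_mk), ctr + ceiling((length(mk) + 2) / 2))
        mk <- chr_mk[lo_i:hi_i]
      }
      bt <- bootstrap_pvalue(Y[, pr$trait_a], Y[, pr$trait_b], dat$dosage,
                             mk, dat$covariates, B = cfg$pleiotropy$B,
                             seed = child_seed(cfg$seed,
                                               paste0("pleio", i)))
      list(trait_a = pr$trait_a, trait_b = pr$trait_b, chr = pr$chr,
           interval = c(lo, hi), lrt = bt$lrt, B = bt$B, p = bt$p,
           argmax = bt$argmax, diag_argmax = bt$diag_argmax,
           n_nonconvergent = bt$n_nonconvergent)
    })
    jsonlite::write_json(results, file.path(out, "pleio_results.json"),
                         auto_unbox = TRUE, digits = NA)
    results
  })

  ## ---- mediation per co-mapped pair --------------------------------------
  res$mediation <- stage("mediation", cfg$stages$mediation, function() {
    pairs <- res$comap$pairs
    if (is.null(pairs) || nrow(pairs) == 0) return(list())
    Y <- count_matrix(prepared$traits)
    pk <- res$peaks
    med_rows <- list(); verdict_rows <- list(); reports <- list()
    for (i in seq_len(nrow(pairs))) {
      pr <- pairs[i, ]
      pka <- pk[pk$trait == pr$trait_a & pk$chr == pr$chr, ][1, ]
      pkb <- pk[pk$trait == pr$trait_b & pk$chr == pr$chr, ][1, ]
      locus <- if (pka$lod >= pkb$lod) pka$marker else pkb$marker
      rep_i <- bidirectional_report(
        Y[, pr$trait_a], Y[, pr$trait_b], dat$dosage, dat$covariates,
        res$scans$kinship, locus,
        drop_threshold = cfg$mediation$drop_threshold,
        margin = cfg$mediation$margin)
      reports[[i]] <- rep_i
      med_rows[[i]] <- data.frame(
        target = c(pr$trait_a, pr$trait_b),
        mediator = c(pr$trait_b, pr$trait_a),
        chr = pr$chr, locus = locus,
        lod_orig = c(rep_i$a_on_b$lod_original, rep_i$b_on_a$lod_original),
        lod_cond = c(rep_i$a_on_b$lod_conditioned,
                     rep_i$b_on_a$lod_conditioned),
        drop = c(rep_i$a_on_b$lod_drop, rep_i$b_on_a$lod_drop),
        pass = c(rep_i$a_on_b$passes_drop_threshold,
                 rep_i$b_on_a$passes_drop_threshold),
        stringsAsFactors = FALSE)
      verdict_rows[[i]] <- data.frame(
        pair = paste(pr$trait_a, pr$trait_b, sep = ":"),
        bic_m1 = rep_i$verdict$bic[["m1"]], bic_m2 = rep_i$verdict$bic[["m2"]],
        bic_m3 = rep_i$verdict$bic[["m3"]], bic_m4 = rep_i$verdict$bic[["m4"]],
        label = rep_i$verdict$label, margin = rep_i$verdict$gap,
        stringsAsFactors = FALSE)
    }
    write.csv(do.call(rbind, med_rows), file.path(out, "mediation.csv"),
              row.names = FALSE)
    write.csv(do.call(rbind, verdict_rows), file.path(out, "verdicts.csv"),
              row.names = FALSE)
    reports
  })

  ## ---- report + manifest -------------------------------------------------
  if (cfg$stages$report) make_report(out)
  manifest(out, cfg)
  invisible(res)
}

simulate_stage <- function(cfg, out) {
  sc <- cfg$simulate
  map <- simulate_map(sc$n_chromosomes, sc$markers_per_chr,
                      sc$chr_length_cM, sc$cM_per_Mbp)
  dosage <- simulate_do_genomes(map, sc$n_individuals,
                                sc$switch_density_per_cM,
                                seed = child_seed(cfg$seed, "genomes"))
  covariates <- simulate_covariates(sc$n_individuals, sc$n_waves,
                                    seed = child_seed(cfg$seed, "covar"))
  chr_mk <- map$marker[map$chr == as.character(sc$pair$chr)]
  marker_a <- chr_mk[sc$pair$marker_index]
  marker_b <- if (!is.null(sc$pair$marker_index_b))
    chr_mk[sc$pair$marker_index_b]
  bg <- sc$background
  bg_specs <- c(
    lapply(seq_len(bg$n_microbial), function(i)
      trait_spec(sprintf("microbe_bg%d", i), "microbial", h2 = bg$h2,
                 prevalence = bg$prevalence)),
    lapply(seq_len(bg$n_metabolite), function(i)
      trait_spec(sprintf("metabolite_bg%d", i), "metabolite", h2 = bg$h2)))
  spec <- list(
    traits = bg_specs,
    pairs = list(pair_spec(
      "microbe_1", "metabolite_1", architecture = sc$pair$architecture,
      marker_a = marker_a, marker_b = marker_b, qtl_var = sc$pair$qtl_var,
      med_var = sc$pair$med_var, classes = sc$pair$classes,
      prevalence = sc$pair$prevalence %||% 0.9)))
  traits <- simulate_traits(dosage, covariates, spec,
                            seed = child_seed(cfg$seed, "traits"))
  write_map_tsv(map, file.path(out, "map.tsv"))
  write.csv(covariates, file.path(out, "covariates.csv"), row.names = FALSE)
  write_trait_table(traits$traits, file.path(out, "traits.csv"),
                    classes = traits$classes,
                    transforms = setNames(rep("raw", length(traits$classes)),
                                          names(traits$classes)))
  jsonlite::write_json(
    list(pairs = traits$pairs,
         qtl = lapply(traits$truth, function(t)
           list(class = t$class, qtl_marker = t$qtl_marker, h2 = t$h2,
                qtl_var = t$qtl_var))),
    file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  list(map = map, dosage = dosage, covariates = covariates, traits = traits)
}

ingest_stage <- function(cfg) {
  ip <- cfg$input
  if (is.null(ip$map) || is.null(ip$dosage) || is.null(ip$traits))
    stop("with stages$simulate = FALSE, input$map, input$dosage and ",
         "input$traits paths are required")
  dosage <- read_dosage_csv(ip$dosage, ip$map)
  traits_df <- read.csv(ip$traits, check.names = FALSE,
                        stringsAsFactors = FALSE)
  side <- paste0(ip$traits, ".json")
  classes <- if (file.exists(side))
    unlist(jsonlite::read_json(side)$classes)
  else setNames(rep("clinical", ncol(traits_df) - 1),
                setdiff(names(traits_df), "id"))
  covariates <- if (!is.null(ip$covariates))
    read.csv(ip$covariates, stringsAsFactors = TRUE)
  list(map = dosage$map, dosage = dosage, covariates = covariates,
       traits = list(traits = traits_df, classes = classes,
                     is_area = NULL))
}

preprocess_stage <- function(dat, cfg, out) {
  pp <- cfg$preprocess
  traits <- dat$traits$traits
  classes <- dat$traits$classes
  transforms <- setNames(rep("raw", length(classes)), names(classes))
  mic <- names(classes)[classes == "microbial"]
  met <- names(classes)[classes == "metabolite"]
  cli <- names(classes)[classes == "clinical"]
  out_df <- traits["id"]
  if (length(mic)) {
    counts <- cmm_filter(traits[, c("id", mic), drop = FALSE],
                         pp$min_prevalence)
    css <- css_normalize(counts, pp$css_quantile, pp$css_scale)
    for (tr in setdiff(names(css), "id")) {
      out_df[[tr]] <- rank_inverse_normal(css[[tr]], pp$rint_offset)
      transforms[tr] <- "rint"
    }
  }
  if (length(met)) {
    mtab <- traits[, c("id", met), drop = FALSE]
    if (!is.null(dat$traits$is_area))
      mtab <- internal_standard_normalize(mtab, dat$traits$is_area)
    lg <- log2_metabolites(mtab, pp$log2_pseudo)
    for (tr in met) {
      out_df[[tr]] <- lg[[tr]]
      transforms[tr] <- "log2"
    }
  }
  for (tr in cli) {
    out_df[[tr]] <- rank_inverse_normal(traits[[tr]], pp$rint_offset)
    transforms[tr] <- "rint"
  }
  kept <- intersect(names(classes), names(out_df))
  classes <- classes[kept]
  transforms <- transforms[kept]
  write_trait_table(out_df, file.path(out, "traits_prepared.csv"),
                    classes = classes, transforms = transforms)
  list(traits = out_df, classes = classes, transforms = transforms)
}

#' Summarize a completed pipeline run as plain text
#'
#' Writes `report.txt` in the run directory: the peak table, co-mapped
#' pairs with their pleiotropy LRT and bootstrap p, and the mediation
#' verdicts.  Stages whose outputs are absent are marked "not run".  An
#' empty peak set is reported as zero peaks (success).
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir) {
  path <- function(f) file.path(run_dir, f)
  lines <- c("pleioscan run report", strrep("=", 40), "")
  if (file.exists(path("peaks.csv"))) {
    pk <- read.csv(path("peaks.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, sprintf("QTL peaks: %d", nrow(pk)))
    if (nrow(pk))
      lines <- c(lines, sprintf(
        "  %s (%s) chr %s @ %.2f Mbp, LOD %.2f, CI [%.2f, %.2f]",
        pk$trait, pk$trait_class, pk$chr, pk$pos_Mbp, pk$lod, pk$ci_lo,
        pk$ci_hi))
  } else lines <- c(lines, "QTL peaks: not run")
  lines <- c(lines, "")
  if (file.exists(path("comap_pairs.csv"))) {
    cm <- read.csv(path("comap_pairs.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, sprintf("Co-mapped microbe-metabolite pairs: %d",
                              nrow(cm)))
    pl <- if (file.exists(path("pleio_results.json")))
      jsonlite::read_json(path("pleio_results.json"))
    if (nrow(cm)) for (i in seq_len(nrow(cm))) {
      ln <- sprintf("  %s x %s chr %s overlap [%.2f, %.2f] Mbp, r_eff %.2f",
                    cm$trait_a[i], cm$trait_b[i], cm$chr[i],
                    cm$overlap_lo[i], cm$overlap_hi[i], cm$r_effects[i])
      if (!is.null(pl) && length(pl) >= i)
        ln <- paste0(ln, sprintf("; pleiotropy LRT %.3f, bootstrap p %.3f",
                                 pl[[i]]$lrt, pl[[i]]$p))
      lines <- c(lines, ln)
    }
  } else lines <- c(lines, "Co-mapping: not run")
  lines <- c(lines, "")
  if (file.exists(path("verdicts.csv"))) {
    vd <- read.csv(path("verdicts.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, "Mediation verdicts:")
    if (nrow(vd))
      lines <- c(lines, sprintf("  %s: %s (BIC margin %.2f)", vd$pair,
                                vd$label, vd$margin))
    else lines <- c(lines, "  (no pairs)")
    if (file.exists(path("mediation.csv"))) {
      md <- read.csv(path("mediation.csv"), stringsAsFactors = FALSE)
      lines <- c(lines, sprintf(
        "  %s | mediator %s: LOD %.2f -> %.2f (drop %.2f%s)",
        md$target, md$mediator, md$lod_orig, md$lod_cond, md$drop,
        ifelse(md$pass, ", passes >2 criterion", "")))
    }
  } else lines <- c(lines, "Mediation: not run")
  writeLines(lines, path("report.txt"))
  invisible(path("report.txt"))
}

manifest <- function(out, cfg) {
  cfg$out_dir <- NULL          # hashes must not depend on where a run lives
  files <- setdiff(list.files(out), "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("pleioscan")),
         seed = cfg$seed,
         thresholds_applied = list(
           peak_lod = cfg$peaks$threshold,
           comap_lod = cfg$comap$lod_min,
           permutation_alphas = cfg$permute$alphas,
           mediation_drop = cfg$mediation$drop_threshold,
           screen_q = cfg$comap$q_cutoff,
           screen_abs_rho = cfg$comap$abs_rho_cutoff,
           cmm_prevalence = cfg$preprocess$min_prevalence),
         config = cfg, files = hashes),
    file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(file.path(out, "manifest.json"))
}
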