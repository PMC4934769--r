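#' Build a run configuration for the full analysis
#'
#' Collects input locations (TPS landmark file and/or isotope CSV, or the
#' built-in synthetic presets), grouping choices, iteration counts and every
#' threshold of the diet endmember model into one validated object. All
#' thresholds default to the study constants; the seed is mandatory.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory for the report bundle.
#' @param tps optional path to a TPS landmark file.
#' @param isotope_csv optional path to an isotope CSV.
#' @param synthetic_shapes optional list of group specs for
#'   [simulate_shape_dataset()] (or `TRUE` for [xwg_shape_preset()]).
#' @param synthetic_isotopes optional list of phase specs for
#'   [simulate_isotope_dataset()] (or `TRUE` for [xwg_isotope_preset()]).
#' @param n_perm permutations for the allometry test.
#' @param G_range candidate mixture component counts.
#' @param m3_cutoff wild/domestic M3 length cutoff (mm).
#' @param wild_size_range centroid-size range of the wild reference
#'   phenotype for the admixture screen.
#' @param endmember a [diet_endmember_model].
#' @param baselines optional list with `herbivore_mean_d15N` and
#'   `carnivore_mean_d15N` for trophic categorisation.
#' @param strict_weaning drop records lacking a dental stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, out_dir,
                       tps = NULL, isotope_csv = NULL,
                       synthetic_shapes = NULL, synthetic_isotopes = NULL,
                       n_perm = 1000L, G_range = 1:3, m3_cutoff = 37.9,
                       wild_size_range = c(11, 16),
                       endmember = diet_endmember_model(),
                       baselines = NULL, strict_weaning = FALSE) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory", call. = FALSE)
  if (missing(out_dir)) stop("out_dir is mandatory", call. = FALSE)
  if (isTRUE(synthetic_shapes)) synthetic_shapes <- xwg_shape_preset()
  if (isTRUE(synthetic_isotopes)) synthetic_isotopes <- xwg_isotope_preset()
  stopifnot(is.finite(m3_cutoff), all(is.finite(wild_size_range)))
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, tps = tps,
         isotope_csv = isotope_csv, synthetic_shapes = synthetic_shapes,
         synthetic_isotopes = synthetic_isotopes, n_perm = as.integer(n_perm),
         G_range = as.integer(G_range), m3_cutoff = m3_cutoff,
         wild_size_range = wild_size_range, endmember = endmember,
         baselines = baselines, strict_weaning = strict_weaning),
    class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path path to a YAML or JSON file whose keys match the arguments of
#'   [run_config()] (`synthetic_shapes`/`synthetic_isotopes` may be `true`
#'   to request the built-in presets).
#' @param ... overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- utils::modifyList(raw, list(...))
  do.call(run_config, args)
}

.write_csv <- function(x, dir, name) {
  p <- file.path(dir, name)
  write.csv(x, p, row.names = FALSE)
  p
}

.write_json <- function(x, dir, name) {
  p <- file.path(dir, name)
  jsonlite::write_json(x, p, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  p
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full combined shape + isotope analysis
#'
#' Orchestrates the study-shaped pipeline: Procrustes superimposition with
#' semi-landmark sliding, per-phase size summary and ANOVA, the wild/domestic
#' admixture screen, the allometry permutation test and pooled within-group
#' correction, MANOVA, CVA with cross-validated dimensionality selection,
#' Mahalanobis distances and the NJ phenogram on the shape side; weaning
#' filter, diet endmember classification, per-phase ANOVAs, delta-13C
#' mixture clustering and the isotope-by-M3-size cross-table on the isotope
#' side. Stages lacking their input are skipped. Everything is written to
#' `config$out_dir` as CSV / JSON / Newick plus a manifest of every constant
#' and seed used; a second run with the same config reproduces the files
#' byte for byte.
#'
#' @param config a [run_config].
#' @return Invisibly, the report bundle: a list with elements `shape`
#'   (size summary, admixture screen, allometry, MANOVA, CVA, Mahalanobis,
#'   phenogram), `isotope` (classification, phase ANOVAs, mixture fits,
#'   cross-table), `files` (paths written) and `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  bundle <- list(shape = NULL, isotope = NULL)

  ## ---- landmark input ----
  configs <- NULL
  if (!is.null(config$tps)) {
    configs <- .stage("read_tps", read_tps(config$tps))
  } else if (!is.null(config$synthetic_shapes)) {
    sim <- .stage("simulate_shapes", simulate_shape_dataset(
      config$synthetic_shapes, seed = config$seed))
    configs <- sim$configs
  }

  if (!is.null(configs)) {
    shapes <- .stage("gpa", gpa_align(configs))
    if (length(shapes$semi) > 0L) {
      spec <- default_sliding_spec(configs[[1]])
      shapes <- .stage("sliding", slide_semilandmarks(shapes, spec))
    }
    phase <- vapply(configs, function(cf)
      as.character(cf$meta$phase %||% "all"), character(1))

    sz <- .stage("size_summary",
                 size_summary(log(shapes$centroid_sizes), phase))
    files <- c(files, .write_csv(sz$table, config$out_dir, "size_summary.csv"))

    g_screen <- config$G_range[config$G_range <= 2L]
    if (length(g_screen) == 0L) g_screen <- 1:2
    screen <- .stage("admixture_screen", admixture_screen(
      shapes, phase, wild_size_range = config$wild_size_range,
      G_range = g_screen, seed = config$seed))
    files <- c(files, .write_csv(as.data.frame(screen), config$out_dir,
                                 "admixture_screen.csv"))

    allo <- .stage("allometry", test_allometry(
      shapes, n_perm = config$n_perm, seed = config$seed))
    corrected <- .stage("allometry_correction",
                        remove_allometry(shapes, phase))
    files <- c(files, .write_csv(
      data.frame(specimen_id = shapes$ids, corrected$residuals),
      config$out_dir, "allometry_free_shapes.csv"))

    pca <- .stage("pca", shape_pca(corrected$residuals))
    n_pc <- .stage("pc_selection", select_pc_count(
      pca$scores, phase, seed = config$seed))
    man <- .stage("manova", manova_test(
      pca$scores[, seq_len(n_pc), drop = FALSE], phase))

    cv <- .stage("cva", cva(pca$scores, phase, n_pc = n_pc))
    files <- c(files, .write_csv(
      data.frame(specimen_id = shapes$ids, phase = phase, cv$scores),
      config$out_dir, "cva_scores.csv"))
    ell <- lapply(split(seq_along(phase), phase), function(ix) {
      if (length(ix) < 3L) return(NULL)
      e <- confidence_ellipse(cv$scores[ix, 1:2, drop = FALSE], 0.9)
      data.frame(cx = e$center[1], cy = e$center[2], a = e$axes[1],
                 b = e$axes[2], angle = e$angle, level = e$level)
    })
    ell_df <- do.call(rbind, Filter(Negate(is.null), ell))
    ell_df <- cbind(phase = rownames(ell_df), ell_df)
    files <- c(files, .write_csv(ell_df, config$out_dir, "cva_ellipses.csv"))
    files <- c(files, .write_csv(
      data.frame(variable = colnames(pca$scores), cv$axis_shape_changes),
      config$out_dir, "cva_axis_changes.csv"))
    files <- c(files, .write_csv(
      cbind(group = rownames(cv$mahalanobis), as.data.frame(cv$mahalanobis)),
      config$out_dir, "mahalanobis.csv"))

    phen <- NULL
    if (nrow(cv$mahalanobis) >= 3L) {
      phen <- .stage("phenogram", nj_phenogram(cv$mahalanobis))
      writeLines(phen$newick, file.path(config$out_dir, "phenogram.nwk"))
      files <- c(files, file.path(config$out_dir, "phenogram.nwk"))
    }

    files <- c(files, .write_json(list(
      size_anova = list(F = sz$anova_F, p = sz$anova_p),
      allometry = list(pct_variance_predicted = allo$pct_variance_predicted,
                       p_value = allo$p_value, n_perm = allo$n_perm),
      manova = list(pillai = man$pillai, wilks = man$wilks),
      n_pc_used = n_pc, cv_accuracy = cv$cv_accuracy),
      config$out_dir, "shape_stats.json"))

    bundle$shape <- list(shapes = shapes, size_summary = sz,
                         admixture_screen = screen, allometry = allo,
                         corrected = corrected, pca = pca, n_pc = n_pc,
                         manova = man, cva = cv, phenogram = phen)
  }

  ## ---- isotope input ----
  records <- NULL
  if (!is.null(config$isotope_csv)) {
    records <- .stage("read_isotopes", read_isotope_csv(config$isotope_csv))
  } else if (!is.null(config$synthetic_isotopes)) {
    isim <- .stage("simulate_isotopes", simulate_isotope_dataset(
      config$synthetic_isotopes, seed = config$seed + 1L))
    records <- isim$records
  }

  if (!is.null(records)) {
    records <- .stage("weaning_filter", filter_weaned(
      records, strict = config$strict_weaning))
    cls <- .stage("diet_classification",
                  classify_d13C(records, model = config$endmember))
    if (!is.null(config$baselines))
      cls$trophic_category <- trophic_category(records$d15N, config$baselines)
    if ("M3_length" %in% names(records)) {
      has_m3 <- is.finite(records$M3_length)
      cls$M3_class <- NA_character_
      cls$M3_class[has_m3] <- classify_M3(records$M3_length[has_m3],
                                          config$m3_cutoff)
    }
    cls$phase <- records$phase
    files <- c(files, .write_csv(cls, config$out_dir,
                                 "isotope_classification.csv"))

    an13 <- .stage("phase_anova_d13C", phase_comparison(records, "d13C"))
    an15 <- .stage("phase_anova_d15N", phase_comparison(records, "d15N"))

    mix <- list()
    for (ph in unique(records$phase)) {
      sub <- records[records$phase == ph, , drop = FALSE]
      if (nrow(sub) >= 5L)
        mix[[ph]] <- .stage(paste0("cluster_d13C_", ph), cluster_d13C(
          sub, G_range = config$G_range, seed = config$seed))
    }
    mix_report <- lapply(mix, function(f)
      list(G = f$G, family = f$family, loglik = f$loglik, n = f$n,
           df = f$df, bic = f$bic,
           means = as.vector(f$means),
           bic_table = f$bic_table))
    files <- c(files, .write_json(list(
      phase_anova = list(d13C = list(F = an13$anova_F, p = an13$anova_p,
                                     ranges = an13$ranges),
                         d15N = list(F = an15$anova_F, p = an15$anova_p,
                                     ranges = an15$ranges)),
      d13C_mixture_by_phase = mix_report),
      config$out_dir, "isotope_stats.json"))

    crosstab <- NULL
    if ("M3_class" %in% names(cls)) {
      sub <- cls[!is.na(cls$M3_class), , drop = FALSE]
      if (nrow(sub) > 0L) {
        crosstab <- as.data.frame.matrix(table(sub$M3_class,
                                               sub$d13C_category))
        crosstab <- cbind(M3_class = rownames(crosstab), crosstab)
      }
    }
    if (is.null(crosstab))
      crosstab <- data.frame(M3_class = character(0))
    files <- c(files, .write_csv(crosstab, config$out_dir,
                                 "isotope_m3_crosstab.csv"))

    bundle$isotope <- list(records = records, classification = cls,
                           anova_d13C = an13, anova_d15N = an15,
                           mixtures = mix, crosstab = crosstab)
  }

  manifest <- list(
    seed = config$seed,
    n_perm = config$n_perm,
    G_range = config$G_range,
    m3_cutoff = config$m3_cutoff,
    wild_size_range = config$wild_size_range,
    strict_weaning = config$strict_weaning,
    endmember_model = unclass(config$endmember),
    baselines = config$baselines,
    inputs = list(tps = config$tps, isotope_csv = config$isotope_csv,
                  synthetic_shapes = !is.null(config$synthetic_shapes),
                  synthetic_isotopes = !is.null(config$synthetic_isotopes)),
    package_version = as.character(utils::packageVersion("pigtrace")))
  files <- c(files, .write_json(manifest, config$out_dir, "manifest.json"))

  bundle$files <- files
  bundle$manifest <- manifest
  invisible(bundle)
}
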