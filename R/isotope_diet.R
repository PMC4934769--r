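#' Diet endmember model for bone-collagen delta-13C interpretation
#'
#' Bundles the plant endmember delta-13C ranges and the correction constants
#' used to project plant values into consumer bone collagen: modern C3
#' plants from open areas (-29 to -25 permil, mean -26.5), archaeological
#' millet seeds (-11.9 to -9.6 permil), modern millet leaves (-14.6 to
#' -12.3 permil); a +1.5 permil fossil-fuel (Suess) correction applied to
#' modern plant values only; a +5 permil diet-protein-to-collagen
#' enrichment; a -31.5 permil modern-plant canopy cutoff mapping to a -25
#' permil collagen threshold for forest C3 input; the -18.5 permil collagen
#' bound below which no millet contribution is inferred; and the 3-4 permil
#' delta-15N trophic step.
#'
#' @param c3_plant_range_modern,millet_seed_range_archaeological,millet_leaf_range_modern
#'   length-2 plant delta-13C ranges (permil VPDB), low then high.
#' @param c3_plant_mean_modern mean modern C3 plant value.
#' @param suess_correction fossil-fuel correction added to modern values.
#' @param collagen_enrichment diet-to-collagen 13C enrichment.
#' @param canopy_cutoff_modern_plants,canopy_collagen_threshold canopy-effect
#'   cutoffs on the plant and collagen scales.
#' @param no_millet_collagen_bound collagen value below which millet intake
#'   is excluded.
#' @param trophic_step_d15N length-2 range of the per-trophic-level delta-15N
#'   enrichment.
#' @return Object of class `diet_endmember_model`.
#' @export
diet_endmember_model <- function(c3_plant_range_modern = c(-29, -25),
                                 c3_plant_mean_modern = -26.5,
                                 millet_seed_range_archaeological = c(-11.9, -9.6),
                                 millet_leaf_range_modern = c(-14.6, -12.3),
                                 suess_correction = 1.5,
                                 collagen_enrichment = 5,
                                 canopy_cutoff_modern_plants = -31.5,
                                 canopy_collagen_threshold = -25,
                                 no_millet_collagen_bound = -18.5,
                                 trophic_step_d15N = c(3, 4)) {
  chk <- function(r, nm) if (length(r) != 2L || r[1] >= r[2] || !all(is.finite(r)))
    stop(nm, " must be an ordered finite (low, high) pair", call. = FALSE)
  chk(c3_plant_range_modern, "c3_plant_range_modern")
  chk(millet_seed_range_archaeological, "millet_seed_range_archaeological")
  chk(millet_leaf_range_modern, "millet_leaf_range_modern")
  chk(trophic_step_d15N, "trophic_step_d15N")
  structure(as.list(environment())[setdiff(ls(), "chk")],
            class = "diet_endmember_model")
}

#' Fossil-fuel (Suess) correction of a modern plant delta-13C value
#'
#' Modern plants are 13C-depleted relative to pre-industrial ones; adding
#' the correction makes modern reference values comparable with
#' archaeological tissue.
#'
#' @param modern_d13C delta-13C value(s), permil.
#' @param correction correction magnitude (default +1.5 permil).
#' @return Corrected value(s).
#' @export
suess_correct <- function(modern_d13C, correction = 1.5) {
  stopifnot(all(is.finite(modern_d13C)))
  modern_d13C + correction
}

#' Diet-protein to bone-collagen delta-13C enrichment
#'
#' @param plant_d13C delta-13C value(s) of the diet, permil.
#' @param enrichment enrichment magnitude (default +5 permil).
#' @return Expected collagen value(s).
#' @export
diet_to_collagen <- function(plant_d13C, enrichment = 5) {
  stopifnot(all(is.finite(plant_d13C)))
  plant_d13C + enrichment
}

#' Expected bone-collagen delta-13C range for a pure endmember diet
#'
#' Composes the corrections on the appropriate plant range: the Suess
#' correction applies to modern reference material (C3 plants, millet
#' leaves) but not to archaeological millet seeds; the diet-to-collagen
#' enrichment applies to all. With the default model this gives
#' (-22.5, -18.5) for a pure C3 diet, (-6.9, -4.6) for a millet-seed diet
#' and (-8.1, -5.8) for a millet-leaf diet.
#'
#' @param model a [diet_endmember_model].
#' @param endmember one of `"c3"`, `"millet_seed"`, `"millet_leaf"`.
#' @return Length-2 numeric (low, high) collagen range, permil.
#' @export
endmember_collagen_range <- function(model = diet_endmember_model(),
                                     endmember = c("c3", "millet_seed",
                                                   "millet_leaf")) {
  endmember <- match.arg(endmember)
  switch(endmember,
    c3 = diet_to_collagen(
      suess_correct(model$c3_plant_range_modern, model$suess_correction),
      model$collagen_enrichment),
    millet_seed = diet_to_collagen(
      model$millet_seed_range_archaeological, model$collagen_enrichment),
    millet_leaf = diet_to_collagen(
      suess_correct(model$millet_leaf_range_modern, model$suess_correction),
      model$collagen_enrichment))
}

#' Categorical diet classification from collagen delta-13C
#'
#' Partitions the collagen delta-13C axis into forest-influenced C3
#' (at or below the canopy collagen threshold, -25 permil), pure C3 (up to
#' the no-millet bound, -18.5 permil), mixed C3/C4, and C4-dominant (at or
#' above the C4 threshold, by default the millet-leaf collagen lower bound,
#' -8.1 permil). Also reports an indicative millet fraction by linear
#' two-endmember interpolation between the C3 collagen mean (-20 permil)
#' and the midpoint of the seed and leaf collagen means, clamped to
#' [0, 100]; the thresholds describe trends, not precise diet proportions,
#' so the fraction is descriptive only.
#'
#' @param records an `isotope_data` data frame (or any data frame with
#'   `specimen_id` and `d13C`), or a bare numeric vector of d13C values.
#' @param model a [diet_endmember_model].
#' @param c4_threshold collagen value at or above which the diet is called
#'   C4-dominant; defaults to the millet-leaf collagen lower bound.
#' @return Data frame: `specimen_id`, `d13C`, `d13C_category` (factor),
#'   `millet_fraction_indicative` (percent).
#' @export
classify_d13C <- function(records, model = diet_endmember_model(),
                          c4_threshold = endmember_collagen_range(model,
                                                                  "millet_leaf")[1]) {
  if (is.numeric(records))
    records <- data.frame(specimen_id = as.character(seq_along(records)),
                          d13C = records)
  x <- records$d13C
  if (is.null(x)) stop("records must contain a d13C column", call. = FALSE)
  keep <- is.finite(x)
  cat_of <- function(v) {
    if (v <= model$canopy_collagen_threshold) "forest_C3_contribution"
    else if (v < model$no_millet_collagen_bound) "pure_C3"
    else if (v >= c4_threshold) "C4_dominant"
    else "mixed_C3_C4"
  }
  cats <- rep(NA_character_, length(x))
  cats[keep] <- vapply(x[keep], cat_of, character(1))
  # the C3 collagen anchor comes from the mean plant value, not the range
  # midpoint: -26.5 + 1.5 + 5 = -20
  c3_mean <- diet_to_collagen(
    suess_correct(model$c3_plant_mean_modern, model$suess_correction),
    model$collagen_enrichment)
  millet_mean <- mean(c(mean(endmember_collagen_range(model, "millet_seed")),
                        mean(endmember_collagen_range(model, "millet_leaf"))))
  frac <- pmin(pmax(100 * (x - c3_mean) / (millet_mean - c3_mean), 0), 100)
  frac[!keep] <- NA_real_
  data.frame(specimen_id = records$specimen_id, d13C = x,
             d13C_category = factor(cats,
               levels = c("forest_C3_contribution", "pure_C3", "mixed_C3_C4",
                          "C4_dominant")),
             millet_fraction_indicative = frac)
}

#' Trophic category from delta-15N against ecosystem baselines
#'
#' Assigns herbivore-like / omnivore-like / carnivore-like relative to
#' herbivore (e.g. deer) and carnivore (e.g. tiger) delta-15N baselines
#' from the same ecosystem. The omnivore band is centred on the midpoint of
#' the two baselines with a half-width of half the trophic step (3.5/2 =
#' 1.75 permil): values below it are herbivore-like, above it
#' carnivore-like.
#'
#' @param d15N delta-15N value(s), permil AIR.
#' @param baselines named list or vector with `herbivore_mean_d15N` and
#'   `carnivore_mean_d15N`.
#' @param half_step half of the trophic delta-15N step (permil).
#' @return Character vector of categories.
#' @export
trophic_category <- function(d15N, baselines, half_step = 1.75) {
  hb <- baselines[["herbivore_mean_d15N"]]
  cb <- baselines[["carnivore_mean_d15N"]]
  if (is.null(hb) || is.null(cb) || !is.finite(hb) || !is.finite(cb))
    stop("both herbivore and carnivore baselines are required", call. = FALSE)
  mid <- (hb + cb) / 2
  ifelse(d15N < mid - half_step, "herbivore_like",
         ifelse(d15N > mid + half_step, "carnivore_like", "omnivore_like"))
}

#' Wild/domestic classification from third-molar length
#'
#' Lengths strictly above the cutoff (37.9 mm by default) are classed wild;
#' the cutoff itself falls on the domestic side.
#'
#' @param length M3 length(s), mm, positive.
#' @param cutoff wild/domestic length cutoff, mm.
#' @return Character vector `"wild"`/`"domestic"`.
#' @export
classify_M3 <- function(length, cutoff = 37.9) {
  if (any(!is.finite(length) | length <= 0))
    stop("M3 lengths must be positive", call. = FALSE)
  ifelse(length > cutoff, "wild", "domestic")
}

#' Filter out unweaned specimens by dental age stage
#'
#' Suckling animals carry a nursing delta-15N offset; the analysis keeps
#' specimens at or beyond dental stage 10 (about 8-10 months). Records
#' without a recorded stage are kept with a `stage_unknown` flag unless
#' `strict = TRUE`, in which case they are dropped.
#'
#' @param records an `isotope_data` data frame.
#' @param min_stage minimum retained dental stage.
#' @param strict drop records lacking a dental stage.
#' @return The retained subset, with a logical `stage_unknown` column.
#' @export
filter_weaned <- function(records, min_stage = 10L, strict = FALSE) {
  if (nrow(records) == 0L) {
    records$stage_unknown <- logical(0)
    return(records)
  }
  stage <- if ("dental_stage" %in% names(records)) records$dental_stage
           else rep(NA_real_, nrow(records))
  unknown <- is.na(stage)
  keep <- (!unknown & stage >= min_stage) | (unknown & !strict)
  out <- records[keep, , drop = FALSE]
  out$stage_unknown <- unknown[keep]
  out
}

#' Per-phase comparison of an isotope variable
#'
#' One-way ANOVA of delta-13C or delta-15N across chronological phases,
#' plus the per-phase inter-individual ranges (max - min spans). With a
#' single phase, only the ranges are returned.
#'
#' @param records an `isotope_data` data frame.
#' @param value `"d13C"` or `"d15N"`.
#' @return List: `anova_F`, `anova_p`, `df`, `ranges` (data frame with
#'   phase, n, min, max, span, mean, sd).
#' @export
phase_comparison <- function(records, value = c("d13C", "d15N")) {
  value <- match.arg(value)
  v <- records[[value]]
  ph <- factor(records$phase)
  ranges <- do.call(rbind, lapply(split(v, ph), function(x)
    data.frame(n = length(x), min = min(x), max = max(x),
               span = max(x) - min(x), mean = mean(x), sd = sd(x))))
  ranges <- cbind(phase = levels(ph), ranges)
  rownames(ranges) <- NULL
  out <- list(anova_F = NA_real_, anova_p = NA_real_, df = NULL,
              ranges = ranges)
  if (nlevels(ph) >= 2L && all(tabulate(ph) >= 2L)) {
    ss <- size_summary(v, ph)
    out$anova_F <- ss$anova_F; out$anova_p <- ss$anova_p; out$df <- ss$df
  }
  out
}

#' Mixture clustering of delta-13C values
#'
#' BIC model selection over 1-3 univariate Gaussian components on the
#' delta-13C vector, the screen that separates C3-fed from millet-fed herds
#' within a phase.
#'
#' @param records an `isotope_data` data frame or numeric d13C vector.
#' @param G_range candidate component counts.
#' @param seed integer seed.
#' @param ... passed to [select_model()].
#' @return A `mixture_fit` with its `bic_table`.
#' @export
cluster_d13C <- function(records, G_range = 1:3, seed = 1L, ...) {
  x <- if (is.numeric(records)) records else records$d13C
  if (length(x) < 5L) stop("need at least 5 records to cluster", call. = FALSE)
  select_model(x, G_range = G_range, seed = seed, ...)
}
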