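#' Simulation configuration for the multiplexed serum study
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the study design the downstream analyses assume: matched tumor/control
#' pairs measured in TMT sixplexes (channels 126/128/129/130 = two tumor and
#' two control sera, 131 = pooled reference made from aliquots of the first
#' `reference_pool_size` subjects, 127 = pure-standard spike), per-metabolite
#' technical CVs, plex- and channel-level batch effects, a tumor-vs-control
#' effect whose magnitude decreases with enzymatic distance from Trp, tumor
#' volumes negatively related to the proximal metabolites, and survival times
#' linked to the subject's kynurenine level.
#'
#' All log-scale quantities are log2. The tumor-vs-control effects default to
#' log2 fold changes -0.6, -0.45, -0.45, -0.3, -0.2, -0.1, -0.05 for pathway
#' distances 0, 1, 1, 2, 3, 3, 4 — a monotone-in-distance gradient.
#'
#' @param n_pairs Number of age/sex-matched tumor-control pairs (default 43).
#' @param n_excluded_pairs Pairs flagged for exclusion before statistical
#'   analysis (technical problems or IDH-mutant status; default 5).
#' @param baseline_log2 Named vector, per-analyte baseline log2 abundance.
#' @param class_effect_log2 Named vector, tumor-vs-control log2 fold change
#'   per analyte (negative = lower in tumor).
#' @param technical_cv Named vector of per-analyte multiplicative measurement
#'   CVs; defaults to `kp_analytes()$technical_cv`.
#' @param biological_sd Between-subject SD of log2 abundance (per analyte).
#' @param plex_effect_sd SD of the random per-plex log2 offset.
#' @param channel_effects Named fixed log2 offsets per TMT channel
#'   (systematic channel bias; reference and spike channels default to 0).
#' @param reference_pool_size Number of subjects pooled into the reference
#'   (default 34).
#' @param corrupt_reference_rate Probability that a reference cell
#'   (analyte x plex) is corrupted by `corruption_factor` (default 0).
#' @param corruption_factor Multiplicative corruption applied to corrupted
#'   reference cells (default 10).
#' @param volume_effect_slope Named vector: change in a tumor subject's log2
#'   abundance per SD of log tumor volume (negative for Trp, OH-Trp, FK, Kyn
#'   by default).
#' @param survival_link Log-hazard change per SD of a tumor subject's latent
#'   Kyn level (negative default: high Kyn protective).
#' @param baseline_hazard Baseline exponential event hazard per day.
#' @param censoring_ratio Ratio of censoring hazard to baseline event hazard
#'   (default 0.45, giving roughly 30% censoring).
#' @param seed Integer seed; together with the other fields it fully
#'   determines every generated table.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_pairs = 4, seed = 1)
#' cfg$class_effect_log2
#' @export
sim_config <- function(n_pairs = 43,
                       n_excluded_pairs = 5,
                       baseline_log2 = NULL,
                       class_effect_log2 = NULL,
                       technical_cv = NULL,
                       biological_sd = 0.35,
                       plex_effect_sd = 0.25,
                       channel_effects = c(
                         "126" = 0.05, "127" = 0, "128" = 0,
                         "129" = -0.05, "130" = 0.02, "131" = 0
                       ),
                       reference_pool_size = 34,
                       corrupt_reference_rate = 0,
                       corruption_factor = 10,
                       volume_effect_slope = NULL,
                       survival_link = -0.8,
                       baseline_hazard = log(2) / 400,
                       censoring_ratio = 0.45,
                       seed = 1L) {
  an <- kp_analytes()
  nm <- an$analyte

  default_named <- function(x, default, what) {
    if (is.null(x)) x <- default
    if (is.null(names(x))) {
      if (length(x) == 1L) x <- stats::setNames(rep(x, length(nm)), nm)
      else if (length(x) == length(nm)) names(x) <- nm
    }
    if (!all(nm %in% names(x))) {
      rlang::abort(
        paste0("`", what, "` must be named for all analytes: ",
               paste(setdiff(nm, names(x)), collapse = ", "), " missing"),
        class = "trpflux_config_error"
      )
    }
    x[nm]
  }

  baseline_log2 <- default_named(
    baseline_log2,
    c(Trp = 16.5, `OH-Trp` = 12, FK = 13, Kyn = 15,
      `OH-Kyn` = 11.5, AA = 12.5, `OH-AA` = 11),
    "baseline_log2"
  )
  class_effect_log2 <- default_named(
    class_effect_log2,
    c(Trp = -0.6, `OH-Trp` = -0.45, FK = -0.45, Kyn = -0.3,
      `OH-Kyn` = -0.2, AA = -0.1, `OH-AA` = -0.05),
    "class_effect_log2"
  )
  technical_cv <- default_named(
    technical_cv, stats::setNames(an$technical_cv, nm), "technical_cv"
  )
  volume_effect_slope <- default_named(
    volume_effect_slope,
    c(Trp = -0.25, `OH-Trp` = -0.2, FK = -0.2, Kyn = -0.15,
      `OH-Kyn` = 0, AA = 0, `OH-AA` = 0),
    "volume_effect_slope"
  )

  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 2) {
    rlang::abort("`n_pairs` must be a single number >= 2",
                 class = "trpflux_config_error")
  }
  n_pairs <- as.integer(n_pairs)
  if (n_excluded_pairs < 0 || n_excluded_pairs >= n_pairs) {
    rlang::abort("`n_excluded_pairs` must be in [0, n_pairs)",
                 class = "trpflux_config_error")
  }
  if (any(technical_cv < 0) || biological_sd < 0 || plex_effect_sd < 0) {
    rlang::abort("CVs and SDs must be non-negative",
                 class = "trpflux_config_error")
  }
  if (corrupt_reference_rate < 0 || corrupt_reference_rate > 1) {
    rlang::abort("`corrupt_reference_rate` must be in [0, 1]",
                 class = "trpflux_config_error")
  }
  if (reference_pool_size < 1) {
    rlang::abort("`reference_pool_size` must be >= 1",
                 class = "trpflux_config_error")
  }
  needed_ch <- c("126", "127", "128", "129", "130", "131")
  miss <- setdiff(needed_ch, names(channel_effects))
  channel_effects[miss] <- 0
  channel_effects <- channel_effects[needed_ch]

  structure(
    list(
      n_pairs = n_pairs,
      n_excluded_pairs = as.integer(n_excluded_pairs),
      analytes = an,
      baseline_log2 = baseline_log2,
      class_effect_log2 = class_effect_log2,
      technical_cv = technical_cv,
      biological_sd = biological_sd,
      plex_effect_sd = plex_effect_sd,
      channel_effects = channel_effects,
      reference_pool_size = as.integer(reference_pool_size),
      corrupt_reference_rate = corrupt_reference_rate,
      corruption_factor = corruption_factor,
      volume_effect_slope = volume_effect_slope,
      survival_link = survival_link,
      baseline_hazard = baseline_hazard,
      censoring_ratio = censoring_ratio,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_pairs, " matched pairs (",
      x$n_excluded_pairs, " flagged for exclusion), seed ", x$seed, "\n",
      sep = "")
  cat("  class effects (log2 tumor-control): ",
      paste(sprintf("%s=%.2f", names(x$class_effect_log2),
                    x$class_effect_log2), collapse = ", "), "\n", sep = "")
  cat("  biological SD ", x$biological_sd, ", plex SD ", x$plex_effect_sd,
      ", reference pool ", x$reference_pool_size, "\n", sep = "")
  invisible(x)
}
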