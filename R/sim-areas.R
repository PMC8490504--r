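#' Simulate reporter-ion peak areas for a plex layout
#'
#' Generates the long analyte x plex x channel table of reporter peak areas
#' that the quantitation pipeline consumes. A subject channel's area is
#' `2^(baseline + class_effect + subject_effect + plex_offset + channel_offset)
#' * (1 + eps)` with `eps ~ Normal(0, technical_cv)` per analyte; reference
#' (and filler-reference) channels carry the pooled mean abundance of the
#' first `reference_pool_size` subjects with their own technical noise; the
#' spike channel carries a constant pure-standard abundance. With probability
#' `corrupt_reference_rate`, a reference cell is multiplied by
#' `corruption_factor`; corrupted cells are recorded in the
#' `"corrupted_cells"` attribute (hidden ground truth for QC tests).
#' Corruption uses its own random stream, so a zero-rate "twin" dataset under
#' the same seed is identical except for the corrupted cells.
#'
#' @param subjects Cohort from [simulate_cohort()] (must carry the
#'   `"latent_effects"` attribute).
#' @param layout Plex layout from [assign_plexes()].
#' @param config The [sim_config()] used to build the cohort.
#' @param seed Seed for measurement noise; defaults to `config$seed + 1`.
#' @return A tibble with columns `analyte`, `plex_id`, `channel`, `role`,
#'   `subject_id`, `area`, `qc_flag` ("ok"), with attributes
#'   `"corrupted_cells"` and `"config"`.
#' @export
simulate_reporter_areas <- function(subjects, layout, config,
                                    seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  latent <- attr(subjects, "latent_effects")
  if (is.null(latent)) {
    rlang::abort("`subjects` lacks the latent_effects attribute; use simulate_cohort()",
                 class = "trpflux_config_error")
  }
  set.seed(seed)
  an <- config$analytes$analyte

  # per-subject true log2 abundance
  cls <- stats::setNames(subjects$class, subjects$subject_id)
  latent$log2_abund <- config$baseline_log2[latent$analyte] +
    ifelse(cls[latent$subject_id] == "tumor",
           config$class_effect_log2[latent$analyte], 0) +
    latent$subject_effect_log2

  # pooled reference abundance: mean natural-scale abundance of the pool
  pool <- utils::head(subjects$subject_id,
                      min(config$reference_pool_size, nrow(subjects)))
  ref_abund <- latent |>
    dplyr::filter(.data$subject_id %in% pool) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(ref_abund = mean(2^.data$log2_abund), .groups = "drop")
  ref_log2 <- stats::setNames(log2(ref_abund$ref_abund), ref_abund$analyte)

  plex_ids <- unique(layout$plex_id)
  plex_off <- stats::setNames(
    stats::rnorm(length(plex_ids), 0, config$plex_effect_sd), plex_ids)

  grid <- tidyr::expand_grid(
    analyte = an,
    layout
  )
  sub_log2 <- stats::setNames(latent$log2_abund,
                              paste(latent$subject_id, latent$analyte))
  base <- dplyr::case_when(
    grid$role == "subject" ~ sub_log2[paste(grid$subject_id, grid$analyte)],
    grid$role %in% c("reference", "filler_reference") ~ ref_log2[grid$analyte],
    grid$role == "spike" ~ config$baseline_log2[grid$analyte] + 1
  )
  log2_mean <- base + plex_off[grid$plex_id] +
    config$channel_effects[as.character(grid$channel)]
  cv <- config$technical_cv[grid$analyte]
  noise <- pmax(1 + stats::rnorm(nrow(grid), 0, cv), 0.05)
  areas <- dplyr::mutate(grid,
    area = unname(2^log2_mean * noise),
    qc_flag = "ok"
  )

  # corruption drawn from a dedicated stream so the base table is unchanged
  corrupted <- tibble::tibble(analyte = character(), plex_id = character(),
                              channel = integer())
  if (config$corrupt_reference_rate > 0) {
    set.seed(seed + 90001L)
    is_ref <- areas$channel == 131L
    hit <- is_ref &
      stats::runif(nrow(areas)) < config$corrupt_reference_rate
    areas$area[hit] <- areas$area[hit] * config$corruption_factor
    corrupted <- areas[hit, c("analyte", "plex_id", "channel")]
  }
  areas <- dplyr::arrange(areas, .data$analyte, .data$plex_id, .data$channel)
  attr(areas, "corrupted_cells") <- corrupted
  attr(areas, "config") <- config
  areas
}

#' Simulate enzyme transcript abundances for two cohorts
#'
#' Log-normal per-gene abundances (TPM-like) for the kynurenine-pathway
#' enzyme genes and the Trp transporter, with the second group shifted by
#' per-gene fold changes. Defaults emulate elevated tryptophan-catabolizing
#' enzyme expression in glioblastoma versus normal brain tissue.
#'
#' @param n_per_group Samples per group.
#' @param fold_change Named per-gene fold change (group 2 / group 1); must
#'   cover every gene in [kp_genes()].
#' @param base_log2 Named per-gene baseline mean log2 TPM.
#' @param sd_log2 Between-sample SD of log2 expression.
#' @param groups Length-2 character vector of group labels.
#' @param seed Seed.
#' @return Long tibble: `sample_id`, `group`, `gene`, `tpm`.
#' @examples
#' expr <- simulate_expression(n_per_group = 5, seed = 1)
#' head(expr)
#' @export
simulate_expression <- function(n_per_group = 50,
                                fold_change = NULL,
                                base_log2 = NULL,
                                sd_log2 = 0.5,
                                groups = c("normal", "gbm"),
                                seed = 1L) {
  genes <- kp_genes()
  if (is.null(fold_change)) {
    fold_change <- c(TPH1 = 1.5, TPH2 = 1.2, IDO1 = 4, TDO2 = 3, AFMID = 1.5,
                     KMO = 2, KYNU = 2, HAAO = 1.5, SLC7A5 = 3)
  }
  miss <- setdiff(genes, names(fold_change))
  if (length(miss) > 0) {
    rlang::abort(paste0("fold_change missing enzyme genes: ",
                        paste(miss, collapse = ", ")),
                 class = "trpflux_config_error")
  }
  if (is.null(base_log2)) {
    base_log2 <- stats::setNames(rep(5, length(genes)), genes)
  }
  stopifnot(length(groups) == 2, n_per_group >= 1)
  set.seed(seed)
  grid <- tidyr::expand_grid(
    group = groups,
    rep = seq_len(n_per_group),
    gene = genes
  )
  mu <- base_log2[grid$gene] +
    ifelse(grid$group == groups[2], log2(fold_change[grid$gene]), 0)
  tibble::tibble(
    sample_id = sprintf("%s_%02d", grid$group, grid$rep),
    group = grid$group,
    gene = grid$gene,
    tpm = 2^(mu + stats::rnorm(nrow(grid), 0, sd_log2))
  )
}

#' Simulate a complete multiplexed study
#'
#' Convenience wrapper chaining [simulate_cohort()], [assign_plexes()] and
#' [simulate_reporter_areas()] under sub-seeds derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `kp_study` with elements `subjects`, `layout`,
#'   `areas`, `truth` (corrupted reference cells) and `config`.
#' @examples
#' study <- simulate_study(sim_config(n_pairs = 4, seed = 3))
#' names(study)
#' @export
simulate_study <- function(config) {
  subjects <- simulate_cohort(config, seed = config$seed)
  layout <- assign_plexes(subjects, seed = config$seed + 10000L)
  areas <- simulate_reporter_areas(subjects, layout, config,
                                   seed = config$seed + 20000L)
  structure(
    list(subjects = subjects, layout = layout, areas = areas,
         truth = attr(areas, "corrupted_cells"), config = config),
    class = "kp_study"
  )
}
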