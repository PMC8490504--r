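#' Linearity-based quality control of reporter areas
#'
#' For each analyte, the areas of every channel are regressed (through the
#' origin) against the median areas of the sixplexes: in the ideal case the
#' relationship is linear with coefficient ~1. A cell (analyte, plex,
#' channel) is flagged `low_quality` when its standardized residual
#' (residual divided by 1.4826 x MAD of that channel's residuals) exceeds
#' `resid_k` in magnitude, or when the channel's uncentered R-squared falls
#' below `r2_min`. The plex medians are taken over the subject-position
#' channels 126/128/129/130 (the same channels the replacement rule uses),
#' leaving the channel under assessment out of its own median, so each
#' channel — including the reference — is compared against an independent
#' plex summary; the spike channel (pure standards, 127) is QC'd against
#' the same medians but never drives them. The channel fit is
#' robust: cells beyond the residual cutoff are masked and the slope,
#' R-squared and residual scale are recomputed on the clean cells, so a
#' single gross outlier flags itself without condemning its whole channel.
#'
#' @param areas Reporter-area tibble (columns `analyte`, `plex_id`,
#'   `channel`, `area`; `role` optional — channel 127 is treated as spike
#'   when absent).
#' @param r2_min Minimum uncentered R-squared per channel (default 0.5:
#'   clean channels carrying realistic between-subject biological spread sit
#'   around 0.85-0.95, grossly broken channels below ~0.4).
#' @param resid_k Standardized-residual cutoff (default 3).
#' @return An object of class `qc_report`: list with `channels` (per
#'   analyte x channel slope, R-squared, plex count) and `cells` (per-cell
#'   fitted values, standardized residuals and `flagged`).
#' @examples
#' study <- simulate_study(sim_config(n_pairs = 4, seed = 1))
#' qc <- qc_linearity(study$areas)
#' qc$channels
#' @export
qc_linearity <- function(areas, r2_min = 0.5, resid_k = 3) {
  areas <- as_area_table(areas)
  if (any(!is.finite(areas$area) | areas$area <= 0)) {
    rlang::abort("all reporter areas must be positive and finite",
                 class = "trpflux_validation_error")
  }
  work <- dplyr::filter(areas, .data$role != "spike")
  n_plex <- work |>
    dplyr::distinct(.data$analyte, .data$plex_id) |>
    dplyr::count(.data$analyte)
  if (any(n_plex$n < 3)) {
    rlang::abort("qc_linearity needs at least 3 plexes per analyte",
                 class = "trpflux_insufficient_data")
  }

  # plex summary from the subject-position channels (the channels the
  # replacement rule uses). A subject channel is compared against the median
  # of the OTHER three subject channels (leave-self-out); reference and
  # spike channels use the median of all four. No channel predicts itself,
  # which would compress the residual core and break the MAD scale.
  subj_ch <- c(126L, 128L, 129L, 130L)
  subj_wide <- work |>
    dplyr::filter(.data$channel %in% subj_ch) |>
    dplyr::select("analyte", "plex_id", "channel", "area") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "area")
  med_of <- function(drop_col) {
    cols <- setdiff(intersect(as.character(subj_ch), names(subj_wide)),
                    drop_col)
    apply(as.matrix(subj_wide[, cols, drop = FALSE]), 1, stats::median,
          na.rm = TRUE)
  }
  meds <- dplyr::bind_rows(lapply(
    c(as.character(subj_ch), "all"),
    function(ch) tibble::tibble(
      analyte = subj_wide$analyte, plex_id = subj_wide$plex_id, med_for = ch,
      plex_median = med_of(if (ch == "all") NULL else ch)
    )
  ))
  work$med_for <- ifelse(work$channel %in% subj_ch,
                         as.character(work$channel), "all")
  work <- dplyr::left_join(work, meds, by = c("analyte", "plex_id", "med_for"))

  cells <- work |>
    dplyr::group_by(.data$analyte, .data$channel) |>
    dplyr::group_modify(function(d, key) {
      x <- d$plex_median
      y <- d$area
      # reporter noise is multiplicative, so residuals are standardized on
      # the log scale, where that noise is symmetric; a robust (median/MAD)
      # z keeps the flag rate comparable across plexes and analytes
      std_of <- function(slope, keep, use_sd = FALSE) {
        lr <- log(y / (slope * x))
        ctr <- stats::median(lr[keep])
        scale <- stats::mad(lr[keep])
        if (scale == 0) scale <- stats::IQR(lr[keep]) / 1.349
        # once outliers are masked, the plain SD is a less noisy scale
        # estimate than the MAD (n is small), tightening the null tails
        if (use_sd && sum(keep) > 2) {
          sd_keep <- stats::sd(lr[keep])
          if (sd_keep > 0) scale <- sd_keep
        }
        if (scale > 0) (lr - ctr) / scale else rep(0, length(lr))
      }
      slope <- sum(x * y) / sum(x * x)
      keep <- abs(std_of(slope, rep(TRUE, length(x)))) <= resid_k
      if (!any(keep)) keep <- rep(TRUE, length(x))
      # refit on the unflagged cells so one gross outlier cannot drag the
      # slope or destroy the channel's R-squared
      slope <- sum(x[keep] * y[keep]) / sum(x[keep]^2)
      resid <- y - slope * x
      ss_res <- sum(resid[keep]^2)
      ss_tot <- sum(y[keep]^2)
      r2 <- if (ss_tot == 0 || ss_res <= 1e-24 * ss_tot) 1 else 1 - ss_res / ss_tot
      std <- std_of(slope, keep, use_sd = TRUE)
      dplyr::mutate(d, slope = slope, r_squared = r2,
                    fitted = slope * x, residual = resid, std_residual = std)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = abs(.data$std_residual) > resid_k |
                    .data$r_squared < r2_min)

  channels <- cells |>
    dplyr::group_by(.data$analyte, .data$channel) |>
    dplyr::summarise(slope = .data$slope[1], r_squared = .data$r_squared[1],
                     n_plexes = dplyr::n(), .groups = "drop")

  structure(
    list(
      channels = channels,
      cells = dplyr::select(cells, "analyte", "plex_id", "channel", "role",
                            "area", "plex_median", "fitted", "residual",
                            "std_residual", "r_squared", "flagged"),
      r2_min = r2_min, resid_k = resid_k
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  n_flag <- sum(x$cells$flagged)
  cat("<qc_report> ", nrow(x$channels), " analyte x channel fits, ",
      n_flag, " flagged cell(s) (R2 >= ", x$r2_min,
      ", |std resid| <= ", x$resid_k, ")\n", sep = "")
  invisible(x)
}

#' Flagged QC cells
#' @param report A [qc_linearity()] report.
#' @return Tibble of flagged (analyte, plex, channel) cells.
#' @export
qc_flagged_cells <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  dplyr::filter(report$cells, .data$flagged) |>
    dplyr::select("analyte", "plex_id", "channel")
}

#' Replace low-quality reference values
#'
#' Flagged reference (channel 131) cells are replaced by the median of the
#' same analyte's areas in the subject channels 126, 128, 129 and 130 of the
#' same plex, and marked `replaced`. Flagged non-reference cells are marked
#' `low_quality` but never modified (replacing subject measurements would
#' fabricate data). The operation is idempotent.
#'
#' @param areas Reporter-area tibble.
#' @param report Matching [qc_linearity()] report.
#' @return The area tibble with updated `area` and `qc_flag` columns.
#' @export
replace_low_quality_reference <- function(areas, report) {
  areas <- as_area_table(areas)
  stopifnot(inherits(report, "qc_report"))
  flagged <- qc_flagged_cells(report)
  if (nrow(flagged) == 0) return(areas)

  key <- function(d) paste(d$analyte, d$plex_id, d$channel)
  flag_ref <- dplyr::filter(flagged, .data$channel == 131L)
  flag_other <- dplyr::filter(flagged, .data$channel != 131L)

  if (nrow(flag_ref) > 0) {
    subj <- dplyr::filter(areas, .data$channel %in% c(126L, 128L, 129L, 130L))
    med <- subj |>
      dplyr::group_by(.data$analyte, .data$plex_id) |>
      dplyr::summarise(replacement = stats::median(.data$area), .groups = "drop")
    flag_ref <- dplyr::left_join(flag_ref, med, by = c("analyte", "plex_id"))
    if (anyNA(flag_ref$replacement)) {
      bad <- flag_ref[is.na(flag_ref$replacement), ]
      rlang::abort(
        paste0("cannot replace reference for ",
               paste(paste0(bad$analyte, "/", bad$plex_id), collapse = ", "),
               ": no subject channels present in plex"),
        class = "trpflux_unreplaceable"
      )
    }
    idx <- match(key(flag_ref), key(areas))
    areas$area[idx] <- flag_ref$replacement
    areas$qc_flag[idx] <- "replaced"
  }
  if (nrow(flag_other) > 0) {
    idx <- match(key(flag_other), key(areas))
    areas$qc_flag[idx] <- "low_quality"
  }
  areas
}

#' Exclude flagged subject pairs
#'
#' Any subject whose `excluded_flag` is not `"none"` is removed together with
#' its matched pair partner (technical problems or IDH-mutant status exclude
#' the whole pair). Their channels are dropped from the area table; the plex
#' itself is retained.
#'
#' @param areas Reporter-area tibble carrying `subject_id`.
#' @param subjects Subject metadata with `pair_id` and `excluded_flag`.
#' @return List with elements `areas` and `subjects`, both filtered.
#' @export
exclude_pairs <- function(areas, subjects) {
  counts <- subjects |>
    dplyr::count(.data$pair_id, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  if (!all(c("tumor", "control") %in% names(counts)) ||
      any(counts$tumor != 1L) || any(counts$control != 1L)) {
    rlang::abort("each pair_id must contain exactly one tumor and one control subject",
                 class = "trpflux_metadata_error")
  }
  bad_pairs <- unique(subjects$pair_id[subjects$excluded_flag != "none"])
  drop_ids <- subjects$subject_id[subjects$pair_id %in% bad_pairs]
  keep_subjects <- dplyr::filter(subjects, !.data$pair_id %in% bad_pairs)
  keep_areas <- dplyr::filter(
    areas, is.na(.data$subject_id) | !.data$subject_id %in% drop_ids)
  for (a in c("corrupted_cells", "config")) {
    attr(keep_areas, a) <- attr(areas, a)
  }
  attr(keep_subjects, "latent_effects") <- attr(subjects, "latent_effects")
  list(areas = keep_areas, subjects = keep_subjects)
}

#' Build the log2 sample/reference ratio matrix
#'
#' Applies the reference design: within each plex, every subject channel's
#' area is divided by the plex's channel-131 reference area for the same
#' analyte, and the ratio is taken log2. Subject metadata is joined when
#' supplied. Missing responses propagate as `NA`; nothing is imputed.
#'
#' @param areas Reporter-area tibble (after QC/replacement as desired).
#' @param layout Optional layout tibble supplying `role`/`subject_id` when
#'   the area table lacks them.
#' @param subjects Optional subject metadata to join.
#' @param warn_missing_frac Warn when an analyte is missing in more than this
#'   fraction of subjects (default 0.5).
#' @return Long tibble with one row per subject x analyte: `subject_id`,
#'   `analyte`, `log_ratio`, `ratio`, `plex_id`, `channel` and any metadata
#'   columns.
#' @examples
#' study <- simulate_study(sim_config(n_pairs = 4, seed = 1))
#' ratios <- build_ratio_matrix(study$areas, subjects = study$subjects)
#' head(ratios)
#' @export
build_ratio_matrix <- function(areas, layout = NULL, subjects = NULL,
                               warn_missing_frac = 0.5) {
  areas <- as_area_table(areas, layout = layout)
  refs <- areas |>
    dplyr::filter(.data$channel == 131L) |>
    dplyr::select("analyte", "plex_id", ref_area = "area")
  subj <- dplyr::filter(areas, .data$role == "subject")
  need <- dplyr::distinct(subj, .data$analyte, .data$plex_id)
  missing_ref <- dplyr::anti_join(need, refs, by = c("analyte", "plex_id"))
  if (nrow(missing_ref) > 0) {
    rlang::abort(
      paste0("missing reference (channel 131) area for ",
             paste(paste0(missing_ref$analyte, "/", missing_ref$plex_id),
                   collapse = ", ")),
      class = "trpflux_missing_reference"
    )
  }
  out <- subj |>
    dplyr::left_join(refs, by = c("analyte", "plex_id")) |>
    dplyr::mutate(ratio = .data$area / .data$ref_area,
                  log_ratio = log2(.data$ratio)) |>
    dplyr::select("subject_id", "analyte", "log_ratio", "ratio",
                  "plex_id", "channel")
  if (!is.null(subjects)) {
    out <- dplyr::left_join(out, subjects, by = "subject_id")
  }
  frac_missing <- out |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(f = mean(is.na(.data$log_ratio)), .groups = "drop")
  bad <- frac_missing$analyte[frac_missing$f > warn_missing_frac]
  if (length(bad) > 0) {
    rlang::warn(paste0("analyte(s) missing in more than ",
                       round(100 * warn_missing_frac), "% of subjects: ",
                       paste(bad, collapse = ", ")))
  }
  out
}

#' Pivot a long ratio table to the subjects x analytes matrix
#' @param ratios Output of [build_ratio_matrix()].
#' @return Wide tibble, one row per subject, one column per analyte.
#' @export
ratio_matrix_wide <- function(ratios) {
  ratios |>
    dplyr::select(dplyr::any_of(c("subject_id", "plex_id", "channel", "class")),
                  "analyte", "log_ratio") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "log_ratio")
}

# normalize an external/long area table: ensure role and subject_id columns
as_area_table <- function(areas, layout = NULL) {
  req <- c("analyte", "plex_id", "channel", "area")
  miss <- setdiff(req, names(areas))
  if (length(miss) > 0) {
    rlang::abort(paste0("area table lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "trpflux_validation_error")
  }
  areas <- tibble::as_tibble(areas)
  areas$channel <- as.integer(areas$channel)
  if (!is.null(layout) && !all(c("role", "subject_id") %in% names(areas))) {
    areas <- dplyr::left_join(
      areas,
      dplyr::select(layout, "plex_id", "channel", "role", "subject_id"),
      by = c("plex_id", "channel"))
  }
  if (!"role" %in% names(areas)) {
    areas$role <- dplyr::case_when(
      areas$channel == 131L ~ "reference",
      areas$channel == 127L ~ "spike",
      TRUE ~ "subject"
    )
  }
  if (!"subject_id" %in% names(areas)) areas$subject_id <- NA_character_
  if (!"qc_flag" %in% names(areas)) areas$qc_flag <- "ok"
  dup <- duplicated(areas[, c("analyte", "plex_id", "channel")])
  if (any(dup)) {
    rlang::abort("duplicate (analyte, plex, channel) records in area table",
                 class = "trpflux_validation_error")
  }
  areas
}
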