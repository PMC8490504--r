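#' Generate a matched tumor/control cohort
#'
#' Draws `n_pairs` age- and sex-matched pairs of one recurrent-glioblastoma
#' patient and one healthy control. Tumor subjects additionally carry an
#' MRI-derived tumor volume (log-normal), a cumulative bevacizumab dose,
#' binary molecular features (MGMT promoter methylation, EGFR amplification,
#' PTEN loss) and overall-survival fields. `n_excluded_pairs` pairs are
#' flagged (`technical` or `idh_mutant`) for later exclusion.
#'
#' Latent per-subject, per-analyte log2 abundance deviations are attached as
#' attribute `"latent_effects"`; they encode the negative tumor-volume
#' relationship for the proximal metabolites and drive both the reporter-area
#' generator and the Kyn-linked survival times (high Kyn, longer survival).
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A tibble with one row per subject (columns `subject_id`,
#'   `pair_id`, `class`, `age`, `sex`, `bevacizumab_dose`,
#'   `tumor_volume_cm3`, `survival_days`, `event`, `mgmt_methylated`,
#'   `egfr_amplified`, `pten_loss`, `excluded_flag`), plus the
#'   `"latent_effects"` attribute.
#' @examples
#' subjects <- simulate_cohort(sim_config(n_pairs = 4, seed = 7))
#' table(subjects$class)
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_pairs
  an <- config$analytes$analyte

  pair_id <- sprintf("P%03d", seq_len(n))
  base_age <- sample(35:75, n, replace = TRUE)
  ctrl_age <- base_age + sample(-2:2, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)

  tumor_volume <- exp(stats::rnorm(n, log(30), 0.6))
  bev_dose <- round(stats::rexp(n, 1 / 1500))

  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(2 * n)),
    pair_id = rep(pair_id, each = 2),
    class = rep(c("tumor", "control"), n),
    age = as.integer(as.vector(rbind(base_age, ctrl_age))),
    sex = rep(sex, each = 2),
    bevacizumab_dose = as.vector(rbind(bev_dose, rep(NA_real_, n))),
    tumor_volume_cm3 = as.vector(rbind(tumor_volume, rep(NA_real_, n))),
    mgmt_methylated = as.vector(rbind(stats::rbinom(n, 1, 0.45), rep(NA_integer_, n))),
    egfr_amplified = as.vector(rbind(stats::rbinom(n, 1, 0.40), rep(NA_integer_, n))),
    pten_loss = as.vector(rbind(stats::rbinom(n, 1, 0.30), rep(NA_integer_, n)))
  )

  # latent subject x analyte log2 deviations: biological noise plus the
  # tumor-volume slope for tumor subjects
  eff <- matrix(stats::rnorm(2 * n * length(an), 0, config$biological_sd),
                nrow = 2 * n, dimnames = list(subjects$subject_id, an))
  is_tumor <- subjects$class == "tumor"
  # standardize by the generating distribution (meanlog log 30, sdlog 0.6),
  # not the sample: within-sample scaling would pin the volume term's sum to
  # exactly zero in every cohort, an artificial constraint that removes its
  # contribution to the class coefficient's sampling variance
  z_vol <- (log(subjects$tumor_volume_cm3[is_tumor]) - log(30)) / 0.6
  eff[is_tumor, ] <- eff[is_tumor, , drop = FALSE] +
    outer(z_vol, config$volume_effect_slope[an])

  # survival linked to the tumor subject's total latent Kyn level
  kyn <- eff[is_tumor, "Kyn"] + config$class_effect_log2[["Kyn"]]
  z_kyn <- if (stats::sd(kyn) > 0) (kyn - mean(kyn)) / stats::sd(kyn) else kyn * 0
  hz <- config$baseline_hazard * exp(config$survival_link * z_kyn)
  t_event <- stats::rexp(sum(is_tumor), hz)
  t_cens <- stats::rexp(sum(is_tumor),
                        config$baseline_hazard * config$censoring_ratio)
  subjects$survival_days <- NA_real_
  subjects$event <- NA_integer_
  subjects$survival_days[is_tumor] <- pmax(1, round(pmin(t_event, t_cens)))
  subjects$event[is_tumor] <- as.integer(t_event <= t_cens)

  subjects$excluded_flag <- "none"
  if (config$n_excluded_pairs > 0) {
    excl <- sample(pair_id, config$n_excluded_pairs)
    reason <- sample(c("technical", "idh_mutant"), length(excl), replace = TRUE)
    idx <- match(subjects$pair_id, excl)
    subjects$excluded_flag <- ifelse(is.na(idx), "none", reason[idx])
  }

  latent <- tibble::as_tibble(as.data.frame.table(eff, stringsAsFactors = FALSE))
  names(latent) <- c("subject_id", "analyte", "subject_effect_log2")
  attr(subjects, "latent_effects") <- latent
  subjects
}

#' Assign subjects to TMT sixplex layouts
#'
#' Randomizes subjects over the four subject channels 126/128/129/130 with
#' exactly two tumor and two control sera per plex; channel 131 carries the
#' pooled reference and channel 127 the pure-standard spike. When the subject
#' count is not a multiple of four, the final plex places the leftover
#' (balanced) pair and fills its unused subject channels with extra reference
#' aliquots, marked `filler_reference`.
#'
#' @param subjects Cohort tibble from [simulate_cohort()] (or any tibble with
#'   `subject_id` and `class`).
#' @param seed Randomization seed.
#' @return A tibble with columns `plex_id`, `channel`, `role`
#'   (`subject`/`reference`/`spike`/`filler_reference`) and `subject_id`.
#' @examples
#' subjects <- simulate_cohort(sim_config(n_pairs = 4, seed = 1))
#' assign_plexes(subjects, seed = 1)
#' @export
assign_plexes <- function(subjects, seed = 1L) {
  tumors <- subjects$subject_id[subjects$class == "tumor"]
  controls <- subjects$subject_id[subjects$class == "control"]
  if (length(tumors) < 2 || length(controls) < 2) {
    rlang::abort("need at least 2 subjects per class to fill a sixplex",
                 class = "trpflux_layout_error")
  }
  if (length(tumors) != length(controls)) {
    rlang::abort(
      paste0("cannot balance plexes: ", length(tumors), " tumor vs ",
             length(controls), " control subjects"),
      class = "trpflux_layout_error"
    )
  }
  set.seed(seed)
  tumors <- sample(tumors)
  controls <- sample(controls)
  n_plex <- ceiling((length(tumors) + length(controls)) / 4)
  subject_channels <- c(126L, 128L, 129L, 130L)

  rows <- vector("list", n_plex)
  for (k in seq_len(n_plex)) {
    idx <- (2 * k - 1):min(2 * k, length(tumors))
    ids <- c(tumors[idx], controls[idx])
    ch <- sample(subject_channels)
    role <- rep("subject", length(ids))
    if (length(ids) < 4) {
      ids <- c(ids, rep(NA_character_, 4 - length(ids)))
      role <- c(role, rep("filler_reference", 4 - length(role)))
    }
    rows[[k]] <- tibble::tibble(
      plex_id = sprintf("plex%02d", k),
      channel = c(ch, 131L, 127L),
      role = c(role, "reference", "spike"),
      subject_id = c(ids, NA_character_, NA_character_)
    )
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$plex_id, .data$channel)
}
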