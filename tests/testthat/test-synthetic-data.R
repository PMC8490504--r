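test_that("analyte panel encodes the pathway distance map", {
  an <- kp_analytes()
  expect_equal(
    setNames(an$pathway_distance, an$analyte),
    c(Trp = 0L, `OH-Trp` = 1L, FK = 1L, Kyn = 2L,
      `OH-Kyn` = 3L, AA = 3L, `OH-AA` = 4L)
  )
  expect_true(all(an$technical_cv > 0))
})

test_that("cohort generation matches the study design and is deterministic", {
  cfg <- sim_config(n_pairs = 43, seed = 1)
  subjects <- simulate_cohort(cfg)
  expect_equal(nrow(subjects), 86)
  expect_equal(as.integer(table(subjects$class)[c("tumor", "control")]),
               c(43L, 43L))
  # each pair: one tumor + one control, matched on age (+/- 2y) and sex
  pairs <- split(subjects, subjects$pair_id)
  expect_true(all(vapply(pairs, function(p) {
    nrow(p) == 2 && setequal(p$class, c("tumor", "control")) &&
      abs(diff(p$age)) <= 2 && length(unique(p$sex)) == 1
  }, logical(1))))
  # survival / volume fields only for tumor subjects
  expect_true(all(is.na(subjects$tumor_volume_cm3[subjects$class == "control"])))
  expect_true(all(!is.na(subjects$survival_days[subjects$class == "tumor"])))
  # flagged pairs
  expect_equal(sum(subjects$excluded_flag != "none"), 10)
  # determinism: identical config + seed => identical tables
  again <- simulate_cohort(sim_config(n_pairs = 43, seed = 1))
  expect_identical(subjects, again)
  expect_false(identical(subjects,
                         simulate_cohort(sim_config(n_pairs = 43, seed = 2))))
})

test_that("tiny cohorts and invalid configs behave as specified", {
  sub4 <- simulate_cohort(sim_config(n_pairs = 2, n_excluded_pairs = 0, seed = 7))
  expect_equal(nrow(sub4), 4)
  expect_true(all(table(sub4$pair_id, sub4$class) == 1))
  expect_error(sim_config(n_pairs = 1), class = "trpflux_config_error")
})

test_that("plex assignment fills sixplexes with 2 tumor + 2 control", {
  cfg <- sim_config(n_pairs = 4, n_excluded_pairs = 0, seed = 3)
  layout <- assign_plexes(simulate_cohort(cfg), seed = 1)
  expect_equal(length(unique(layout$plex_id)), 2)
  # per plex: 4 subjects, 1 reference, 1 spike
  per <- dplyr::count(layout, plex_id, role)
  expect_true(all(per$n[per$role == "subject"] == 4))
  expect_true(all(c(131L, 127L) %in% layout$channel))

  # 86 subjects -> 22 plexes, final plex with 2 filler reference channels
  big <- assign_plexes(simulate_cohort(sim_config(n_pairs = 43, seed = 1)),
                       seed = 2)
  expect_equal(length(unique(big$plex_id)), 22)
  expect_equal(sum(big$role == "filler_reference"), 2)
  # every subject appears exactly once
  ids <- big$subject_id[big$role == "subject"]
  expect_equal(sort(ids), sort(sprintf("S%03d", 1:86)))
})

test_that("unbalanced or too-small classes give a layout error", {
  cfg <- sim_config(n_pairs = 3, n_excluded_pairs = 0, seed = 1)
  subjects <- simulate_cohort(cfg)
  unbal <- dplyr::bind_rows(
    subjects[subjects$class == "tumor", ][1:4, ] |>
      dplyr::mutate(class = c("tumor", "tumor", "tumor", "tumor")),
    subjects[subjects$class == "control", ][1:2, ]
  )
  expect_error(assign_plexes(unbal, seed = 1), class = "trpflux_layout_error")
  expect_error(assign_plexes(subjects[1:2, ], seed = 1),
               class = "trpflux_layout_error")
})

test_that("noise-free null generator yields ratios of exactly one", {
  cfg <- sim_config(
    n_pairs = 4, n_excluded_pairs = 0, seed = 11,
    class_effect_log2 = 0, technical_cv = 1e-12, biological_sd = 0,
    plex_effect_sd = 0, channel_effects = c("126" = 0, "127" = 0, "128" = 0,
                                            "129" = 0, "130" = 0, "131" = 0),
    volume_effect_slope = 0
  )
  st <- simulate_study(cfg)
  ratios <- build_ratio_matrix(st$areas)
  expect_true(all(abs(ratios$log_ratio) < 1e-9))
})

test_that("class effect is encoded on the log2 ratio scale", {
  # with biological and technical noise off, the realized tumor-vs-control
  # log2 difference equals the configured effect exactly
  cfg <- sim_config(
    n_pairs = 10, n_excluded_pairs = 0, seed = 5,
    technical_cv = 1e-6, biological_sd = 0, plex_effect_sd = 0.2,
    channel_effects = c("126" = 0, "127" = 0, "128" = 0, "129" = 0,
                        "130" = 0, "131" = 0),
    volume_effect_slope = 0
  )
  st <- simulate_study(cfg)
  ratios <- build_ratio_matrix(st$areas, subjects = st$subjects)
  diffs <- ratios |>
    dplyr::group_by(analyte, class) |>
    dplyr::summarise(m = mean(log_ratio), .groups = "drop") |>
    tidyr::pivot_wider(names_from = class, values_from = m) |>
    dplyr::mutate(d = tumor - control)
  expect_equal(setNames(diffs$d, diffs$analyte)[names(cfg$class_effect_log2)],
               cfg$class_effect_log2, tolerance = 1e-4)
})

test_that("mean tumor/control area ratio matches 2^effect over many plexes", {
  cfg <- sim_config(n_pairs = 200, n_excluded_pairs = 0, seed = 9,
                    volume_effect_slope = 0)
  st <- simulate_study(cfg)
  trp <- st$areas |>
    dplyr::filter(analyte == "Trp", role == "subject") |>
    dplyr::left_join(dplyr::select(st$subjects, subject_id, class),
                     by = "subject_id")
  ratios <- trp |>
    dplyr::group_by(plex_id, class) |>
    dplyr::summarise(g = exp(mean(log(area))), .groups = "drop") |>
    tidyr::pivot_wider(names_from = class, values_from = g)
  # geometric-mean contrast removes plex effects; MC error ~ sd/sqrt(n)
  est <- mean(log2(ratios$tumor / ratios$control))
  expect_equal(est, -0.6, tolerance = 0.15)
})

test_that("corruption bookkeeping matches a zero-rate twin exactly", {
  cfg_c <- sim_config(n_pairs = 8, n_excluded_pairs = 0, seed = 21,
                      corrupt_reference_rate = 0.2)
  cfg_0 <- sim_config(n_pairs = 8, n_excluded_pairs = 0, seed = 21,
                      corrupt_reference_rate = 0)
  st_c <- simulate_study(cfg_c)
  st_0 <- simulate_study(cfg_0)
  differing <- st_c$areas |>
    dplyr::mutate(area0 = st_0$areas$area) |>
    dplyr::filter(area != area0)
  expect_gt(nrow(st_c$truth), 0)
  expect_setequal(cell_key(differing), cell_key(st_c$truth))
  # corrupted cells are exactly 10x their twin
  expect_equal(differing$area, differing$area0 * 10, tolerance = 1e-12)
  expect_true(all(st_c$truth$channel == 131L))
})

test_that("removing a flagged pair removes one subject of each class", {
  cfg <- sim_config(n_pairs = 10, n_excluded_pairs = 3, seed = 13)
  subjects <- simulate_cohort(cfg)
  flagged_pairs <- unique(subjects$pair_id[subjects$excluded_flag != "none"])
  for (p in flagged_pairs) {
    dropped <- subjects[subjects$pair_id == p, ]
    expect_equal(nrow(dropped), 2)
    expect_setequal(dropped$class, c("tumor", "control"))
  }
})

test_that("expression simulator encodes per-gene fold changes", {
  # same seed twice: identical
  e1 <- simulate_expression(n_per_group = 5, seed = 4)
  e2 <- simulate_expression(n_per_group = 5, seed = 4)
  expect_identical(e1, e2)
  # all fold changes 1: group means differ only by noise
  fc1 <- setNames(rep(1, length(kp_genes())), kp_genes())
  e <- simulate_expression(n_per_group = 200, fold_change = fc1, seed = 6)
  mr <- e |>
    dplyr::group_by(gene, group) |>
    dplyr::summarise(m = mean(log2(tpm)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = m)
  expect_true(all(abs(mr$gbm - mr$normal) < 0.2))
  # IDO1 fold change 4, n = 50/group: empirical ratio within 10%
  e4 <- simulate_expression(n_per_group = 50, seed = 8)
  ido <- e4 |>
    dplyr::filter(gene == "IDO1") |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = exp(mean(log(tpm))), .groups = "drop")
  ratio <- ido$m[ido$group == "gbm"] / ido$m[ido$group == "normal"]
  expect_lt(abs(ratio / 4 - 1), 0.1)
  # missing enzyme gene in the fold-change map
  expect_error(simulate_expression(fold_change = c(IDO1 = 2), seed = 1),
               class = "trpflux_config_error")
})
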