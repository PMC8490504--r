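# small synthetic ratio table with explicit factors
make_ratios <- function(n_subj = 16, n_plex = 4, seed = 1,
                        analytes = c("Trp", "Kyn", "AA")) {
  set.seed(seed)
  per_plex <- n_subj / n_plex
  ch <- c(126L, 128L, 129L, 130L)
  meta <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_subj)),
    class = rep(c("tumor", "control"), n_subj / 2),
    plex_id = rep(sprintf("plex%02d", seq_len(n_plex)), each = per_plex),
    # rotate the channel order across plexes so class and channel decouple
    channel = as.integer(unlist(lapply(seq_len(n_plex), function(i)
      rep(ch[((seq_len(4) + i - 2) %% 4) + 1], length.out = per_plex))))
  )
  tidyr::expand_grid(meta, analyte = analytes) |>
    dplyr::mutate(log_ratio = rnorm(dplyr::n(), 0, 0.3))
}

test_that("constant response gives a zero class coefficient and zero variance", {
  r <- make_ratios()
  r$log_ratio <- 0.5
  fits <- fit_metabolite_lm(r)
  expect_true(all(abs(fits$log2_fc) < 1e-12))
  expect_true(all(fits$s2 < 1e-24))
})

test_that("per-analyte OLS matches the normal-equation oracle", {
  r <- make_ratios(n_subj = 16, seed = 3)
  fits <- fit_metabolite_lm(r)
  for (a in unique(r$analyte)) {
    d <- r[r$analyte == a, ]
    X <- stats::model.matrix(~ factor(class, c("control", "tumor")) +
                               factor(plex_id) + factor(channel), data = d)
    o <- oracle_ols(X, d$log_ratio)
    row <- fits[fits$analyte == a, ]
    expect_equal(row$log2_fc, unname(o$beta[2]), tolerance = 1e-10)
    expect_equal(row$s2, o$s2, tolerance = 1e-10)
    expect_equal(row$v_unscaled, o$xtx_inv[2, 2], tolerance = 1e-10)
    expect_equal(row$df_residual, o$d)
  }
})

test_that("single-plex data silently drop the plex factor", {
  set.seed(5)
  meta <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:8),
    class = rep(c("tumor", "control"), 4),
    plex_id = "plex01",
    # each channel carries one tumor and one control subject
    channel = c(126L, 128L, 129L, 130L, 130L, 129L, 128L, 126L)
  )
  r <- tidyr::expand_grid(meta, analyte = c("Trp", "Kyn")) |>
    dplyr::mutate(log_ratio = rnorm(dplyr::n(), 0, 0.3))
  fits <- fit_metabolite_lm(r)
  # design: intercept + class + 3 channel contrasts -> 8 - 5 residual df
  expect_true(all(fits$df_residual == 3))
})

test_that("a plex-constant offset leaves the class coefficient unchanged", {
  st <- simulate_study(sim_config(n_pairs = 10, n_excluded_pairs = 0, seed = 17))
  ratios <- build_ratio_matrix(st$areas, subjects = st$subjects)
  f1 <- fit_metabolite_lm(ratios)
  shifted <- ratios |>
    dplyr::mutate(log_ratio = log_ratio +
                    as.numeric(factor(plex_id)) * 0.83)
  f2 <- fit_metabolite_lm(shifted)
  expect_equal(f2$log2_fc, f1$log2_fc, tolerance = 1e-10)
})

test_that("aliased designs raise a singular-design error", {
  r <- make_ratios(n_subj = 8, n_plex = 2, seed = 7)
  # every tumor in plex01 and every control in plex02: class aliased with plex
  r$class <- ifelse(r$plex_id == "plex01", "tumor", "control")
  expect_error(fit_metabolite_lm(r), class = "trpflux_singular_design")
})

test_that("empirical-Bayes moderation matches an independent moment solver", {
  set.seed(42)
  for (i in 1:50) {
    n_a <- sample(5:30, 1)
    d <- sample(c(10L, 30L, 50L), 1)
    s2 <- exp(rnorm(n_a, -2, sample(c(0.3, 0.6, 1), 1)))
    fits <- tibble::tibble(
      analyte = sprintf("m%02d", seq_len(n_a)),
      log2_fc = rnorm(n_a), s2 = s2, df_residual = rep(d, n_a),
      v_unscaled = runif(n_a, 0.01, 0.2), n = d + 4
    )
    fits$se_raw <- sqrt(fits$s2 * fits$v_unscaled)
    mod <- ebayes_moderate(fits)
    o <- oracle_ebayes(s2, rep(d, n_a))
    if (is.finite(o$d0)) {
      expect_equal(mod$d0, o$d0, tolerance = 1e-8)
      expect_equal(mod$s0_sq, o$s0_sq, tolerance = 1e-8)
    } else {
      expect_identical(mod$d0, Inf)
    }
    expect_equal(mod$table$s2_post, o$s2_post, tolerance = 1e-8)
    t_expected <- fits$log2_fc / sqrt(o$s2_post * fits$v_unscaled)
    expect_equal(mod$table$t_mod, t_expected, tolerance = 1e-8)
    # shrinkage bound: s2_post between each s2 and the prior value
    expect_true(all(
      mod$table$s2_post >= pmin(fits$s2, mod$s0_sq) - 1e-12 &
        mod$table$s2_post <= pmax(fits$s2, mod$s0_sq) + 1e-12
    ))
  }
})

test_that("equal observed variances make the moderated t the ordinary t", {
  fits <- tibble::tibble(
    analyte = letters[1:7],
    log2_fc = c(-0.6, -0.45, -0.45, -0.3, -0.2, -0.1, -0.05),
    s2 = rep(0.04, 7), df_residual = rep(50L, 7),
    v_unscaled = rep(0.05, 7), n = 76
  )
  fits$se_raw <- sqrt(fits$s2 * fits$v_unscaled)
  mod <- ebayes_moderate(fits)
  expect_identical(mod$d0, Inf)
  expect_equal(mod$table$s2_post, fits$s2)
  expect_equal(mod$table$t_mod, fits$log2_fc / fits$se_raw)
  expect_equal(mod$table$df_total, rep(Inf, 7))
})

test_that("non-robust moderation agrees with the reference implementation", {
  # heterogeneous variances with a finite prior: hyperparameters and
  # posterior variances must match limma's method-of-moments fit
  set.seed(99)
  s2 <- exp(rnorm(25, -1, 1.2))
  d <- 20L
  fits <- tibble::tibble(
    analyte = sprintf("m%02d", 1:25), log2_fc = rnorm(25), s2 = s2,
    df_residual = rep(d, 25), v_unscaled = rep(0.1, 25), n = 24
  )
  fits$se_raw <- sqrt(fits$s2 * fits$v_unscaled)
  mod <- ebayes_moderate(fits)
  sq <- limma::squeezeVar(s2, df = d)
  expect_true(is.finite(mod$d0))
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$table$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("robust moderation winsorizes the variance outlier", {
  set.seed(7)
  s2 <- c(exp(rnorm(15, -2, 0.3)), 50) # one gross variance outlier
  fits <- tibble::tibble(
    analyte = sprintf("m%02d", 1:16), log2_fc = rnorm(16), s2 = s2,
    df_residual = rep(30L, 16), v_unscaled = rep(0.1, 16), n = 34
  )
  fits$se_raw <- sqrt(fits$s2 * fits$v_unscaled)
  plain <- ebayes_moderate(fits)
  rob <- ebayes_moderate(fits, robust = TRUE)
  # the outlier inflates the apparent variance heterogeneity, collapsing the
  # plain prior df; winsorizing restores confidence in the prior
  expect_gt(rob$d0, plain$d0)
  expect_true(rob$robust)
})

test_that("moderation requires residual degrees of freedom", {
  fits <- tibble::tibble(analyte = c("a", "b"), log2_fc = c(1, 2),
                         s2 = c(NA_real_, NA_real_),
                         df_residual = c(0L, 0L),
                         v_unscaled = c(0.1, 0.1), n = 2,
                         se_raw = NA_real_)
  expect_error(ebayes_moderate(fits), class = "trpflux_no_residual_df")
})

test_that("gradient reproduces exact Spearman values on known patterns", {
  an <- kp_analytes()
  # strictly decreasing magnitude, distances deduplicated: rho = -1
  strict <- tibble::tibble(
    analyte = c("Trp", "FK", "Kyn", "OH-Kyn", "OH-AA"),
    log2_fc = c(-0.6, -0.5, -0.3, -0.2, -0.1)
  )
  g1 <- fold_change_gradient(strict, an, n_perm = 200, seed = 1)
  expect_equal(g1$rho, -1)

  # the default graded pattern with ties on both axes: exact tie-adjusted rho
  graded <- tibble::tibble(
    analyte = an$analyte,
    log2_fc = c(-0.6, -0.45, -0.45, -0.3, -0.2, -0.1, -0.05)
  )
  g2 <- fold_change_gradient(graded, an, n_perm = 200, seed = 1)
  expect_equal(g2$rho, oracle_spearman(abs(graded$log2_fc), an$pathway_distance))
  expect_equal(g2$rho, -27 / sqrt(27 * 27.5), tolerance = 1e-12)

  # constant magnitudes: degenerate, rho reported as 0
  flat <- tibble::tibble(analyte = an$analyte, log2_fc = rep(-0.3, 7))
  g3 <- fold_change_gradient(flat, an, n_perm = 200, seed = 1)
  expect_true(g3$degenerate)
  expect_equal(g3$rho, 0)
})

test_that("gradient permutation p is small for a clean monotone pattern", {
  an <- kp_analytes()
  graded <- tibble::tibble(
    analyte = an$analyte,
    log2_fc = c(-0.6, -0.45, -0.45, -0.3, -0.2, -0.1, -0.05)
  )
  g <- fold_change_gradient(graded, an, n_perm = 9999, seed = 4)
  expect_lt(g$p_value, 0.05)
})

test_that("gradient preconditions are enforced", {
  an <- kp_analytes()
  expect_error(
    fold_change_gradient(tibble::tibble(analyte = c("Trp", "Kyn"),
                                        log2_fc = c(-1, -0.5)), an),
    class = "trpflux_undefined_gradient"
  )
  same_dist <- tibble::tibble(analyte = c("OH-Kyn", "AA"), log2_fc = c(-1, -0.5))
  expect_error(fold_change_gradient(same_dist, an),
               class = "trpflux_undefined_gradient")
})
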