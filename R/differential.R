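#' Per-analyte linear model of log2 ratios
#'
#' Fits, for every analyte, the ordinary-least-squares model
#' `log_ratio ~ class + plex + channel` with treatment contrasts (reference
#' levels: control, first plex, channel 126). Factors with a single observed
#' level are silently dropped (a single-plex dataset reduces to
#' `class + channel`). Rows with a missing response are dropped per analyte.
#' The class coefficient is the tumor-vs-control log2 fold change; the plex
#' and channel factors absorb the technical (batch) variance of the
#' multiplexed design.
#'
#' @param ratios Long ratio tibble from [build_ratio_matrix()] with columns
#'   `analyte`, `log_ratio`, `class`, `plex_id`, `channel`.
#' @return A tibble of class `kp_fits`, one row per analyte: `log2_fc`
#'   (class coefficient), `se_raw`, `s2` (residual variance), `df_residual`,
#'   `v_unscaled` (unscaled coefficient variance), `n`.
#' @examples
#' study <- simulate_study(sim_config(n_pairs = 6, seed = 2))
#' ratios <- build_ratio_matrix(study$areas, subjects = study$subjects)
#' fit_metabolite_lm(ratios)
#' @export
fit_metabolite_lm <- function(ratios) {
  req <- c("analyte", "log_ratio", "class", "plex_id", "channel")
  miss <- setdiff(req, names(ratios))
  if (length(miss) > 0) {
    rlang::abort(paste0("ratio table lacks column(s): ",
                        paste(miss, collapse = ", ")),
                 class = "trpflux_validation_error")
  }
  meta <- ratios |>
    dplyr::distinct(.data$subject_id, .data$class, .data$plex_id, .data$channel)
  y_wide <- ratios |>
    dplyr::select("subject_id", "analyte", "log_ratio") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "log_ratio")
  meta <- dplyr::left_join(dplyr::select(y_wide, "subject_id"), meta,
                           by = "subject_id")
  Y <- as.matrix(y_wide[, setdiff(names(y_wide), "subject_id")])

  build_design <- function(m) {
    m$class <- factor(m$class, levels = c("control", "tumor"))
    terms <- "class"
    if (length(unique(m$plex_id)) > 1) terms <- c(terms, "plex_id")
    if (length(unique(m$channel)) > 1) terms <- c(terms, "channel")
    m$plex_id <- factor(m$plex_id)
    m$channel <- factor(m$channel, levels = sort(unique(m$channel)))
    f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
    stats::model.matrix(f, data = m)
  }

  fit_one <- function(y, m) {
    ok <- !is.na(y)
    y <- y[ok]
    m <- m[ok, , drop = FALSE]
    X <- build_design(m)
    if (nrow(X) < ncol(X) + 1) {
      rlang::abort("too few observations for the design",
                   class = "trpflux_singular_design")
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      rlang::abort(paste0("design matrix is singular; aliased column(s): ",
                          paste(aliased, collapse = ", ")),
                   class = "trpflux_singular_design")
    }
    beta <- qr.coef(qx, y)
    res <- y - X %*% beta
    d <- nrow(X) - qx$rank
    s2 <- if (d > 0) sum(res^2) / d else NA_real_
    xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
    j <- match("classtumor", colnames(X))
    v <- xtx_inv[j, j]
    tibble::tibble(
      log2_fc = unname(beta[j]),
      se_raw = sqrt(s2 * v),
      s2 = s2,
      df_residual = d,
      v_unscaled = v,
      n = length(y)
    )
  }

  out <- purrr::map_dfr(colnames(Y), function(a) {
    dplyr::bind_cols(tibble::tibble(analyte = a), fit_one(Y[, a], meta))
  })
  class(out) <- c("kp_fits", class(out))
  out
}

# solve trigamma(y) = x by Newton iteration
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks the per-analyte residual variances toward a common prior value
#' estimated across analytes and computes moderated t-statistics with
#' augmented degrees of freedom. The prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by the method of moments on `log(s2)`
#' (digamma/trigamma inversion by Newton iteration); the posterior variance
#' is `s2_post = (d0*s0^2 + d*s2)/(d0 + d)` and
#' `t_mod = log2_fc / sqrt(s2_post * v)` is referred to a t distribution
#' with `d + d0` degrees of freedom. With `robust = TRUE`, `log(s2)` is
#' winsorized at the `winsor` quantiles before moment estimation — a
#' documented simplification of the fully robust variance-outlier
#' down-weighting. When the trigamma moment equation has no positive
#' solution the prior is a point mass (`d0 = Inf`) at the geometric mean of
#' the observed variances, so equal observed variances shrink to themselves
#' and the moderated t equals the ordinary t.
#'
#' @param fits A `kp_fits` tibble from [fit_metabolite_lm()].
#' @param robust Winsorize log variances before moment estimation.
#' @param winsor Lower/upper winsorization quantiles (default 0.05, 0.95).
#' @param alpha Significance level used to set the `significant` column
#'   (default 0.05).
#' @param moderate If `FALSE`, skip shrinkage and report ordinary
#'   t-statistics (fallback for very small analyte panels).
#' @return Object of class `kp_moderated`: list with `table` (per analyte:
#'   `log2_fc`, `se_raw`, `s2`, `df_residual`, `s2_post`, `t_mod`,
#'   `df_total`, `p_value`, `significant`), hyperparameters `d0`, `s0_sq`,
#'   and flags. Use [tidy()] / [glance()] to extract them.
#' @examples
#' study <- simulate_study(sim_config(n_pairs = 6, seed = 2))
#' ratios <- build_ratio_matrix(study$areas, subjects = study$subjects)
#' mod <- ebayes_moderate(fit_metabolite_lm(ratios))
#' tidy(mod)
#' @export
ebayes_moderate <- function(fits, robust = FALSE, winsor = c(0.05, 0.95),
                            alpha = 0.05, moderate = TRUE) {
  stopifnot(is.data.frame(fits),
            all(c("analyte", "log2_fc", "s2", "df_residual", "v_unscaled")
                %in% names(fits)))
  d <- fits$df_residual
  s2 <- fits$s2
  if (all(d == 0 | is.na(s2))) {
    rlang::abort("no analyte has residual degrees of freedom",
                 class = "trpflux_no_residual_df")
  }
  if (!moderate) {
    d0 <- 0
    s0 <- NA_real_
    s2_post <- s2
  } else {
    use <- d > 0 & is.finite(s2) & s2 > 0
    if (sum(use) < 2) {
      rlang::abort("need >= 2 analytes with positive residual variance",
                   class = "trpflux_no_residual_df")
    }
    e <- log(s2[use]) - digamma(d[use] / 2) + log(d[use] / 2)
    if (robust) {
      qs <- stats::quantile(e, winsor, names = FALSE, type = 7)
      e <- pmin(pmax(e, qs[1]), qs[2])
    }
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(d[use] / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # point-mass prior: common variance = geometric mean of observed s2
      d0 <- Inf
      s0 <- exp(mean(log(s2[use])))
    }
    s2_post <- if (is.finite(d0)) (d0 * s0 + d * s2) / (d0 + d) else rep(s0, length(s2))
    # analytes with no residual df take the prior
    s2_post[d == 0 | !is.finite(s2)] <- if (is.finite(d0)) s0 else s0
  }
  df_total <- d + d0
  t_mod <- fits$log2_fc / sqrt(s2_post * fits$v_unscaled)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  tab <- dplyr::mutate(
    tibble::as_tibble(fits),
    s2_post = s2_post,
    t_mod = t_mod,
    df_total = df_total,
    p_value = p,
    significant = p < alpha
  )
  structure(
    list(table = tab, d0 = d0, s0_sq = s0, robust = robust,
         alpha = alpha, moderated = moderate),
    class = "kp_moderated"
  )
}

#' @export
print.kp_moderated <- function(x, ...) {
  cat("<kp_moderated> ", nrow(x$table), " analytes; d0 = ",
      format(x$d0, digits = 4), ", s0^2 = ", format(x$s0_sq, digits = 4),
      if (x$robust) " (robust/winsorized)", "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Bootstrap stability of the prior degrees of freedom
#'
#' With only a handful of analytes the moment estimate of `d0` is unstable;
#' this diagnostic reports the bootstrap SD of `d0` over resampled analyte
#' sets (infinite estimates are tallied separately).
#'
#' @param fits A `kp_fits` tibble.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed.
#' @return Tibble with `d0_hat`, `boot_sd` (finite resamples), and
#'   `frac_infinite`.
#' @export
d0_stability <- function(fits, n_boot = 200, seed = 1L) {
  set.seed(seed)
  d0_of <- function(f) ebayes_moderate(f)$d0
  d0_hat <- d0_of(fits)
  boots <- replicate(n_boot, {
    idx <- sample(nrow(fits), replace = TRUE)
    tryCatch(d0_of(fits[idx, ]), error = function(e) NA_real_)
  })
  fin <- boots[is.finite(boots)]
  tibble::tibble(
    d0_hat = d0_hat,
    boot_sd = if (length(fin) > 1) stats::sd(fin) else NA_real_,
    frac_infinite = mean(!is.finite(boots), na.rm = TRUE)
  )
}

#' Fold-change gradient along the pathway distance
#'
#' Orders the analytes by their enzymatic distance from Trp and measures the
#' association between the magnitude of the tumor-vs-control log2 fold
#' change and the distance: Spearman rank correlation with average-rank tie
#' handling, and a permutation p-value obtained by permuting the distance
#' labels. A negative rho with small p reproduces the observation that the
#' decrease shrinks with each enzymatic step away from Trp.
#'
#' @param results A `kp_moderated` object or tibble with columns `analyte`
#'   and `log2_fc`.
#' @param analytes Analyte definition table (default [kp_analytes()]).
#' @param n_perm Number of label permutations (default 9999).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param seed Optional seed for the permutations.
#' @return Object of class `kp_gradient`: list with the distance-ordered
#'   `table`, `rho`, `p_value`, `n_perm`, `alternative` and `degenerate`
#'   (constant |log2FC|, rho reported as 0 by convention).
#' @export
fold_change_gradient <- function(results, analytes = kp_analytes(),
                                 n_perm = 9999,
                                 alternative = c("two.sided", "less", "greater"),
                                 seed = NULL) {
  alternative <- match.arg(alternative)
  tab <- if (inherits(results, "kp_moderated")) results$table else
    tibble::as_tibble(results)
  stopifnot(all(c("analyte", "log2_fc") %in% names(tab)))
  tab <- dplyr::inner_join(
    tab, dplyr::select(analytes, "analyte", "pathway_distance"), by = "analyte")
  if (nrow(tab) < 3) {
    rlang::abort("gradient needs >= 3 analytes with fold changes",
                 class = "trpflux_undefined_gradient")
  }
  if (length(unique(tab$pathway_distance)) < 2) {
    rlang::abort("gradient undefined: all pathway distances equal",
                 class = "trpflux_undefined_gradient")
  }
  x <- abs(tab$log2_fc)
  dist <- tab$pathway_distance
  degenerate <- stats::sd(x) == 0
  if (degenerate) {
    rho <- 0
    p <- NA_real_
  } else {
    rho <- stats::cor(x, dist, method = "spearman")
    if (!is.null(seed)) set.seed(seed)
    rx <- rank(x)
    rperm <- replicate(n_perm, stats::cor(rx, rank(sample(dist))))
    eps <- 1e-12
    p <- switch(alternative,
      two.sided = (1 + sum(abs(rperm) >= abs(rho) - eps)) / (n_perm + 1),
      less = (1 + sum(rperm <= rho + eps)) / (n_perm + 1),
      greater = (1 + sum(rperm >= rho - eps)) / (n_perm + 1)
    )
  }
  ordered <- tab |>
    dplyr::mutate(abs_log2_fc = abs(.data$log2_fc)) |>
    dplyr::arrange(.data$pathway_distance, .data$analyte)
  structure(
    list(table = ordered, rho = rho, p_value = p, n_perm = n_perm,
         alternative = alternative, degenerate = degenerate),
    class = "kp_gradient"
  )
}

#' @export
print.kp_gradient <- function(x, ...) {
  cat("<kp_gradient> Spearman rho(|log2FC|, distance) = ",
      format(x$rho, digits = 4), ", permutation p = ",
      format(x$p_value, digits = 4),
      if (x$degenerate) " [degenerate: constant |log2FC|]", "\n", sep = "")
  print(dplyr::select(x$table, "analyte", "pathway_distance", "log2_fc"))
  invisible(x)
}
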