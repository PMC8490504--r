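#' Mean-ratio regression of metabolite levels on a clinical covariate
#'
#' Ordinary least squares of the metabolite level (dependent) on the
#' standardized covariate, summarised the forest-plot way: the standardized
#' slope `b` with standard error `SE_b` is converted to a mean ratio
#' `MR = e^b` with 95% confidence interval
#' `[e^(b - z*SE_b), e^(b + z*SE_b)]`, `z = 2` by default (a deliberate
#' round multiplier; pass `z_mult = 1.96` for the exact normal quantile).
#'
#' @param data Tibble with the level and covariate columns (typically the
#'   ratio matrix joined with subject metadata, tumor subjects only).
#' @param level Unquoted column holding the metabolite level.
#' @param covariate Unquoted covariate column (e.g. tumor volume,
#'   cumulative bevacizumab dose).
#' @param by Optional unquoted grouping column (typically `analyte`).
#' @param z_mult CI multiplier on the SE scale (default 2).
#' @return Tibble of class `kp_associations`, one row per group: `b`,
#'   `se_b`, `mr`, `ci_lo`, `ci_hi`, `p_value`, `n`.
#' @examples
#' study <- simulate_study(sim_config(n_pairs = 8, seed = 5))
#' ratios <- build_ratio_matrix(study$areas, subjects = study$subjects)
#' tumor <- dplyr::filter(ratios, class == "tumor")
#' regress_on_covariate(tumor, log_ratio, tumor_volume_cm3, by = analyte)
#' @export
regress_on_covariate <- function(data, level, covariate, by = NULL,
                                 z_mult = 2) {
  lv <- rlang::enquo(level)
  cv <- rlang::enquo(covariate)
  byq <- rlang::enquo(by)
  one <- function(d) {
    y <- dplyr::pull(d, !!lv)
    x <- dplyr::pull(d, !!cv)
    ok <- stats::complete.cases(y, x)
    y <- y[ok]; x <- x[ok]
    if (length(y) < 4) {
      rlang::abort("need >= 4 complete (level, covariate) pairs",
                   class = "trpflux_insufficient_data")
    }
    if (stats::sd(x) == 0) {
      rlang::abort("covariate has zero variance",
                   class = "trpflux_degenerate_covariate")
    }
    z <- (x - mean(x)) / stats::sd(x)
    n <- length(y)
    b <- sum((z - mean(z)) * y) / sum((z - mean(z))^2)
    a <- mean(y) - b * mean(z)
    res <- y - a - b * z
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 / sum((z - mean(z))^2))
    tstat <- b / se
    tibble::tibble(
      b = b, se_b = se,
      mr = exp(b),
      ci_lo = exp(b - z_mult * se),
      ci_hi = exp(b + z_mult * se),
      p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
      n = n
    )
  }
  out <- if (rlang::quo_is_null(byq)) {
    one(data)
  } else {
    data |>
      dplyr::group_by(!!byq) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  }
  class(out) <- c("kp_associations", class(out))
  out
}

#' Pooled-variance two-sample t-test of metabolite levels by a binary feature
#'
#' Two-tailed unpaired Student's t-test (equal variances pooled,
#' `df = n1 + n2 - 2`) of the level between the two strata of a binary
#' molecular feature (e.g. MGMT promoter methylation, EGFR amplification,
#' PTEN loss, prior bevacizumab).
#'
#' @param data Tibble with level and feature columns.
#' @param level Unquoted level column.
#' @param feature Unquoted binary feature column.
#' @param by Optional unquoted grouping column.
#' @return Tibble, one row per group: stratum means/sizes, `t`, `df`,
#'   `p_value`.
#' @export
ttest_by_feature <- function(data, level, feature, by = NULL) {
  lv <- rlang::enquo(level)
  ft <- rlang::enquo(feature)
  byq <- rlang::enquo(by)
  one <- function(d) {
    y <- dplyr::pull(d, !!lv)
    g <- dplyr::pull(d, !!ft)
    ok <- stats::complete.cases(y, g)
    y <- y[ok]; g <- g[ok]
    lev <- sort(unique(g))
    if (length(lev) != 2 || min(table(g)) < 2) {
      rlang::abort("each stratum of the binary feature needs >= 2 subjects",
                   class = "trpflux_insufficient_group")
    }
    ht <- stats::t.test(y[g == lev[1]], y[g == lev[2]], var.equal = TRUE)
    tibble::tibble(
      level_1 = as.character(lev[1]), level_2 = as.character(lev[2]),
      mean_1 = mean(y[g == lev[1]]), mean_2 = mean(y[g == lev[2]]),
      n_1 = sum(g == lev[1]), n_2 = sum(g == lev[2]),
      t = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value
    )
  }
  if (rlang::quo_is_null(byq)) one(data)
  else data |>
    dplyr::group_by(!!byq) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Robust FDR-based outlier removal (ROUT analogue)
#'
#' Robust center (median) and scale (1.4826 x MAD); each value's two-sided
#' tail probability from a t distribution with `n - 1` degrees of freedom on
#' its standardized residual; Benjamini-Hochberg adjustment; values with
#' adjusted q below `q` are removed. The false-discovery rate `Q` among
#' removed points defaults to 1%. When the MAD is zero on non-constant data
#' the scale falls back to IQR/1.349 (a message is emitted).
#'
#' @param values Numeric vector (n >= 8).
#' @param q FDR threshold among removed values (default 0.01).
#' @return Object of class `rout_report`: tibble with `value`, `z`,
#'   `p_value`, `q_value`, `removed`, plus attributes `center`, `scale`,
#'   `q`. [rout_keep()] returns the surviving values directly.
#' @examples
#' x <- c(rnorm(20), 10)
#' rout_remove(x)$removed
#' @export
rout_remove <- function(values, q = 0.01) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) {
    rlang::abort("rout_remove needs >= 8 finite values",
                 class = "trpflux_insufficient_data")
  }
  center <- stats::median(values)
  scale <- stats::mad(values)
  if (scale == 0 && stats::sd(values) > 0) {
    scale <- stats::IQR(values) / 1.349
    rlang::inform("MAD is zero on non-constant data; using IQR-based scale")
  }
  if (scale == 0) {
    z <- rep(0, n)
  } else {
    z <- (values - center) / scale
  }
  p <- 2 * stats::pt(-abs(z), df = n - 1)
  qv <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(value = values, z = z, p_value = p,
                        q_value = qv, removed = qv < q)
  structure(out, center = center, scale = scale, q = q,
            class = c("rout_report", class(out)))
}

#' @rdname rout_remove
#' @export
rout_keep <- function(values, q = 0.01) {
  rep <- rout_remove(values, q = q)
  rep$value[!rep$removed]
}

#' Simulate survival records with a log-linear metabolite effect
#'
#' Exponential event times with hazard `base_hazard * exp(beta * level)`,
#' `level ~ Normal(0, 1)`, and independent exponential censoring tuned to
#' the requested censoring fraction. Used for calibration studies of the
#' univariate Cox fit.
#'
#' @param n Number of subjects.
#' @param beta True log hazard ratio per unit level.
#' @param base_hazard Baseline hazard per day.
#' @param censoring Target censoring fraction (default 0.3).
#' @param seed Seed.
#' @return Tibble: `time`, `event`, `level`.
#' @export
simulate_survival <- function(n, beta = 0.5, base_hazard = 0.002,
                              censoring = 0.3, seed = 1L) {
  set.seed(seed)
  x <- stats::rnorm(n)
  t_event <- stats::rexp(n, base_hazard * exp(beta * x))
  cens_rate <- base_hazard * censoring / (1 - censoring)
  t_cens <- stats::rexp(n, cens_rate)
  tibble::tibble(
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    level = x
  )
}
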