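#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the Cox partial likelihood for a single
#' covariate, with Breslow tie handling by default (Efron optional). The
#' Wald standard error comes from the observed information; following the
#' forest-plot convention of the serum analysis, the hazard-ratio confidence
#' interval is `exp(beta +/- z_mult * SE)` with `z_mult = 2` by default. The
#' score test at `beta = 0` (identical to the log-rank test for a binary
#' covariate without ties) is reported alongside.
#'
#' @param data Tibble holding the survival columns.
#' @param time,event,covariate Unquoted column names: follow-up time (> 0),
#'   event indicator (0/1), and the metabolite level (or any numeric
#'   covariate).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param z_mult CI multiplier (default 2).
#' @param tol Convergence tolerance on the Newton step (default 1e-8).
#' @param max_iter Iteration cap (default 25).
#' @return Object of class `kp_cox`: `beta`, `se`, `hr`, `ci_lo`, `ci_hi`,
#'   `p_value` (Wald), `score_chisq` and `score_p` at beta = 0, `loglik`,
#'   `loglik_null`, `n`, `n_events`, `iterations`.
#' @examples
#' surv <- simulate_survival(n = 60, beta = 0.5, seed = 2)
#' fit <- cox_univariate(surv, time, event, level)
#' tidy(fit)
#' @export
cox_univariate <- function(data, time, event, covariate,
                           ties = c("breslow", "efron"), z_mult = 2,
                           tol = 1e-8, max_iter = 25) {
  ties <- match.arg(ties)
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  x <- dplyr::pull(data, {{ covariate }})
  ok <- stats::complete.cases(tm, ev, x)
  tm <- tm[ok]; ev <- as.integer(ev[ok]); x <- as.numeric(x[ok])
  if (any(tm <= 0)) {
    rlang::abort("survival times must be positive",
                 class = "trpflux_validation_error")
  }
  if (sum(ev) < 1) {
    rlang::abort("need at least one event", class = "trpflux_validation_error")
  }
  if (stats::sd(x[tm >= min(tm[ev == 1])]) == 0) {
    rlang::abort("covariate is constant among subjects at risk; beta not identifiable",
                 class = "trpflux_nonidentifiable")
  }

  ord <- order(tm)
  tm <- tm[ord]; ev <- ev[ord]; x <- x[ord]
  n <- length(tm)

  # log partial likelihood, score and information at beta
  eval_at <- function(beta) {
    w <- exp(beta * x)
    # reverse cumulative sums: S*(i) over the risk set {j : tm_j >= tm_i}
    s0 <- rev(cumsum(rev(w)))
    s1 <- rev(cumsum(rev(w * x)))
    s2 <- rev(cumsum(rev(w * x^2)))
    # risk-set values per unique time: take the first index of each tie group
    first <- !duplicated(tm)
    grp <- cumsum(first)
    i0 <- which(first)
    ll <- 0; U <- 0; I <- 0
    for (g in seq_along(i0)) {
      idx <- which(grp == g & ev == 1L)
      dk <- length(idx)
      if (dk == 0) next
      S0 <- s0[i0[g]]; S1 <- s1[i0[g]]; S2 <- s2[i0[g]]
      xs <- sum(x[idx])
      if (ties == "breslow" || dk == 1) {
        ll <- ll + beta * xs - dk * log(S0)
        U <- U + xs - dk * S1 / S0
        I <- I + dk * (S2 / S0 - (S1 / S0)^2)
      } else {
        # Efron: average out the tied events' own contribution
        wd <- sum(w[idx]); wdx <- sum((w * x)[idx]); wdx2 <- sum((w * x^2)[idx])
        for (r in seq_len(dk)) {
          f <- (r - 1) / dk
          S0r <- S0 - f * wd
          S1r <- S1 - f * wdx
          S2r <- S2 - f * wdx2
          ll <- ll - log(S0r)
          U <- U - S1r / S0r
          I <- I + S2r / S0r - (S1r / S0r)^2
        }
        ll <- ll + beta * xs
        U <- U + xs
      }
    }
    list(ll = ll, U = U, I = I)
  }

  null <- eval_at(0)
  score_chisq <- null$U^2 / null$I

  beta <- 0
  cur <- null
  iter <- 0
  repeat {
    iter <- iter + 1
    step <- cur$U / cur$I
    new_beta <- beta + step
    new <- eval_at(new_beta)
    halvings <- 0
    while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) && halvings < 30) {
      step <- step / 2
      new_beta <- beta + step
      new <- eval_at(new_beta)
      halvings <- halvings + 1
    }
    beta <- new_beta
    cur <- new
    if (!is.finite(beta) || abs(beta) > 50) {
      rlang::abort(
        paste0("Cox likelihood appears monotone (perfect separation): ",
               "|beta| diverged past 50 at iteration ", iter),
        class = "trpflux_cox_divergence"
      )
    }
    if (abs(step) < tol) break
    if (iter >= max_iter) {
      rlang::abort(paste0("Cox Newton-Raphson did not converge in ", max_iter,
                          " iterations (last step ", format(step), ")"),
                   class = "trpflux_cox_divergence")
    }
  }
  se <- 1 / sqrt(cur$I)
  structure(
    list(
      beta = beta, se = se, hr = exp(beta),
      ci_lo = exp(beta - z_mult * se), ci_hi = exp(beta + z_mult * se),
      p_value = 2 * stats::pnorm(-abs(beta / se)),
      score_chisq = score_chisq,
      score_p = stats::pchisq(score_chisq, df = 1, lower.tail = FALSE),
      loglik = cur$ll, loglik_null = null$ll,
      n = n, n_events = sum(ev), iterations = iter,
      ties = ties, z_mult = z_mult
    ),
    class = "kp_cox"
  )
}

#' @export
print.kp_cox <- function(x, ...) {
  cat("<kp_cox> beta = ", format(x$beta, digits = 5),
      " (SE ", format(x$se, digits = 4), "), HR = ",
      format(x$hr, digits = 4), " [", format(x$ci_lo, digits = 4), ", ",
      format(x$ci_hi, digits = 4), "], Wald p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  cat("  ", x$n, " subjects, ", x$n_events, " events, ", x$ties,
      " ties, ", x$iterations, " Newton iterations\n", sep = "")
  invisible(x)
}

#' Per-analyte univariate survival association
#'
#' Runs [cox_univariate()] of overall survival on each analyte's level and
#' assembles the forest-plot table.
#'
#' @param ratios Long ratio tibble joined with survival metadata; tumor
#'   subjects with non-missing `survival_days`/`event` are used.
#' @param standardize Standardize each analyte's levels before fitting
#'   (default TRUE; the effect is then per SD of the log2 ratio).
#' @param ... Passed to [cox_univariate()].
#' @return Tibble of class `kp_associations`: one row per analyte with
#'   `b` (= beta), `se_b`, `mr` (= HR), `ci_lo`, `ci_hi`, `p_value`, `n`.
#' @export
survival_associations <- function(ratios, standardize = TRUE, ...) {
  dat <- ratios |>
    dplyr::filter(!is.na(.data$survival_days), !is.na(.data$event),
                  !is.na(.data$log_ratio))
  out <- dat |>
    dplyr::group_by(.data$analyte) |>
    dplyr::group_modify(function(d, key) {
      lvl <- if (standardize) as.numeric(scale(d$log_ratio)) else d$log_ratio
      d$level <- lvl
      fit <- cox_univariate(d, survival_days, event, level, ...)
      tibble::tibble(b = fit$beta, se_b = fit$se, mr = fit$hr,
                     ci_lo = fit$ci_lo, ci_hi = fit$ci_hi,
                     p_value = fit$p_value, n = fit$n,
                     n_events = fit$n_events)
    }) |>
    dplyr::ungroup()
  class(out) <- c("kp_associations", class(out))
  out
}
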