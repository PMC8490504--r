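#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a moderated-test result
#' @param x A `kp_moderated` object.
#' @param ... Unused.
#' @return Per-analyte tibble of estimates, moderated t and p-values.
#' @method tidy kp_moderated
#' @export
tidy.kp_moderated <- function(x, ...) x$table

#' @rdname tidy.kp_moderated
#' @method glance kp_moderated
#' @export
glance.kp_moderated <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, robust = x$robust,
                 alpha = x$alpha, moderated = x$moderated,
                 n_analytes = nrow(x$table),
                 n_significant = sum(x$table$significant, na.rm = TRUE))
}

#' Tidy a fold-change gradient
#' @param x A `kp_gradient` object.
#' @param ... Unused.
#' @return Distance-ordered per-analyte tibble.
#' @method tidy kp_gradient
#' @export
tidy.kp_gradient <- function(x, ...) x$table

#' @rdname tidy.kp_gradient
#' @method glance kp_gradient
#' @export
glance.kp_gradient <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, n_perm = x$n_perm,
                 alternative = x$alternative, degenerate = x$degenerate)
}

#' Tidy a univariate Cox fit
#' @param x A `kp_cox` object.
#' @param ... Unused.
#' @return One-row tibble with `beta`, `se`, `hr`, CI bounds and p-values.
#' @method tidy kp_cox
#' @export
tidy.kp_cox <- function(x, ...) {
  tibble::tibble(beta = x$beta, se = x$se, hr = x$hr,
                 ci_lo = x$ci_lo, ci_hi = x$ci_hi, p_value = x$p_value)
}

#' @rdname tidy.kp_cox
#' @method glance kp_cox
#' @export
glance.kp_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 loglik_null = x$loglik_null, score_chisq = x$score_chisq,
                 score_p = x$score_p, iterations = x$iterations,
                 ties = x$ties)
}

#' Tidy a QC report
#' @param x A `qc_report` object.
#' @param ... Unused.
#' @return Per-cell tibble with standardized residuals and flags.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) x$cells

#' @rdname tidy.qc_report
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells), n_flagged = sum(x$cells$flagged),
                 min_r_squared = min(x$channels$r_squared),
                 r2_min = x$r2_min, resid_k = x$resid_k)
}

#' Tidy a steady-state result
#' @param x A `kp_steady_state` object.
#' @param ... Unused.
#' @return Tibble of species concentrations (mM).
#' @method tidy kp_steady_state
#' @export
tidy.kp_steady_state <- function(x, ...) x$concentrations

#' @rdname tidy.kp_steady_state
#' @method glance kp_steady_state
#' @export
glance.kp_steady_state <- function(x, ...) {
  tibble::tibble(residual = x$residual, rel_residual = x$rel_residual,
                 converged = x$converged)
}
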