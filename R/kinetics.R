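#' Reactions of the kynurenine-pathway kinetic model
#'
#' A minimal irreversible Michaelis-Menten network for tryptophan catabolism:
#' transporter-mediated uptake of extracellular Trp, the serotonin-branch
#' first step (TPH, truncated at OH-Trp), the parallel dioxygenases IDO1 and
#' TDO2 producing N-formylkynurenine, AFMID to kynurenine, then the KMO /
#' KYNU branch point, KYNU acting on OH-Kyn, and HAAO draining OH-AA toward
#' the NAD+ branch (treated as a sink). Every internal species additionally
#' has first-order clearance so a finite steady state exists even when
#' downstream capacity is zero.
#'
#' @return Tibble with `reaction`, `substrate`, `product` (NA = sink) and
#'   `genes` (list column mapping transcripts to the reaction).
#' @export
kp_reactions <- function() {
  tibble::tibble(
    reaction = c("uptake", "TPH", "IDO1", "TDO2", "AFMID",
                 "KMO", "KYNU_a", "KYNU_b", "HAAO"),
    substrate = c("Trp_ext", "Trp", "Trp", "Trp", "FK",
                  "Kyn", "Kyn", "OH-Kyn", "OH-AA"),
    product = c("Trp", "OH-Trp", "FK", "FK", "Kyn",
                "OH-Kyn", "AA", "OH-AA", NA_character_),
    genes = list("SLC7A5", c("TPH1", "TPH2"), "IDO1", "TDO2", "AFMID",
                 "KMO", "KYNU", "KYNU", "HAAO")
  )
}

#' @rdname kp_reactions
#' @export
kp_species <- function() c("Trp", "OH-Trp", "FK", "Kyn", "OH-Kyn", "AA", "OH-AA")

#' Load kinetic parameters
#'
#' Reads the versioned parameter file (Vmax, Km, clearance, extracellular
#' Trp concentration, expression pseudo-count). The shipped defaults are the
#' package's own; pass a path to use a custom file.
#'
#' @param path YAML file; defaults to the parameter file shipped with the
#'   package.
#' @return List with `trp_ext` (mM, default 0.01), `epsilon`, `k_clear`,
#'   `vmax` and `km` (named per reaction).
#' @export
kp_params <- function(path = system.file("extdata", "kp_params.yaml",
                                         package = "trpflux")) {
  p <- yaml::read_yaml(path)
  rx <- kp_reactions()$reaction
  p$vmax <- unlist(p$vmax)[rx]
  p$km <- unlist(p$km)[rx]
  if (anyNA(p$vmax) || anyNA(p$km)) {
    rlang::abort("parameter file must give vmax and km for every reaction",
                 class = "trpflux_config_error")
  }
  if (any(p$vmax < 0) || any(p$km <= 0) || p$k_clear < 0 || p$trp_ext < 0 ||
      p$epsilon <= 0) {
    rlang::abort("kinetic parameters out of range",
                 class = "trpflux_config_error")
  }
  p
}

#' Build an expression-scaled kinetic model for one sample
#'
#' Scales each reaction's reference Vmax by the sample's transcript
#' abundance of the mapped gene(s) relative to the cohort reference mean:
#' `Vmax_r = Vmax_ref_r * (E_r + eps) / (Ebar_r + eps)`, where genes mapping
#' to the same reaction are summed before scaling. A sample with a missing
#' mapped gene is not modelled: the function signals a
#' `trpflux_sample_excluded` warning and returns `NULL`, mirroring the
#' removal of samples with missing expression values.
#'
#' @param expression_row Named numeric vector of the sample's per-gene
#'   abundances (TPM-like).
#' @param reference Named numeric vector of reference (cohort mean) per-gene
#'   abundances.
#' @param params Parameter list from [kp_params()].
#' @param epsilon Pseudo-count; defaults to `params$epsilon`.
#' @return Object of class `kinetic_model` (list with `vmax`, `km`,
#'   `k_clear`, `trp_ext`), or `NULL` with a warning when the sample lacks a
#'   mapped gene.
#' @export
build_kinetic_model <- function(expression_row, reference,
                                params = kp_params(),
                                epsilon = params$epsilon) {
  rx <- kp_reactions()
  grp_sum <- function(v, genes) {
    if (!all(genes %in% names(v)) || anyNA(v[genes])) return(NA_real_)
    sum(v[genes])
  }
  e <- vapply(rx$genes, grp_sum, numeric(1), v = expression_row)
  eref <- vapply(rx$genes, grp_sum, numeric(1), v = reference)
  if (anyNA(e)) {
    bad <- unique(unlist(rx$genes[is.na(e)]))
    rlang::warn(paste0("sample excluded: missing expression for ",
                       paste(bad, collapse = ", ")),
                class = "trpflux_sample_excluded")
    return(NULL)
  }
  if (anyNA(eref)) {
    rlang::abort("reference means missing mapped genes",
                 class = "trpflux_config_error")
  }
  scale <- (e + epsilon) / (eref + epsilon)
  kc <- params$k_clear
  if (length(kc) == 1) kc <- stats::setNames(rep(kc, 7), kp_species())
  structure(
    list(vmax = params$vmax * scale, km = params$km,
         k_clear = kc[kp_species()], trp_ext = params$trp_ext,
         scale = stats::setNames(scale, rx$reaction)),
    class = "kinetic_model"
  )
}

#' Reference (unscaled) kinetic model
#' @param params Parameter list from [kp_params()].
#' @return A `kinetic_model` with all scaling factors equal to 1.
#' @export
kp_reference_model <- function(params = kp_params()) {
  g <- stats::setNames(rep(1, length(kp_genes())), kp_genes())
  build_kinetic_model(g, g, params = params)
}

# reaction rates at state x (named species vector)
kp_rates <- function(x, model) {
  mm <- function(r, s) model$vmax[[r]] * s / (model$km[[r]] + s)
  c(
    uptake = mm("uptake", model$trp_ext),
    TPH = mm("TPH", x[["Trp"]]),
    IDO1 = mm("IDO1", x[["Trp"]]),
    TDO2 = mm("TDO2", x[["Trp"]]),
    AFMID = mm("AFMID", x[["FK"]]),
    KMO = mm("KMO", x[["Kyn"]]),
    KYNU_a = mm("KYNU_a", x[["Kyn"]]),
    KYNU_b = mm("KYNU_b", x[["OH-Kyn"]]),
    HAAO = mm("HAAO", x[["OH-AA"]])
  )
}

# time derivatives at state x
kp_rhs <- function(x, model) {
  v <- kp_rates(x, model)
  kc <- model$k_clear
  c(
    "Trp" = v[["uptake"]] - v[["TPH"]] - v[["IDO1"]] - v[["TDO2"]] -
      kc[["Trp"]] * x[["Trp"]],
    "OH-Trp" = v[["TPH"]] - kc[["OH-Trp"]] * x[["OH-Trp"]],
    "FK" = v[["IDO1"]] + v[["TDO2"]] - v[["AFMID"]] - kc[["FK"]] * x[["FK"]],
    "Kyn" = v[["AFMID"]] - v[["KMO"]] - v[["KYNU_a"]] - kc[["Kyn"]] * x[["Kyn"]],
    "OH-Kyn" = v[["KMO"]] - v[["KYNU_b"]] - kc[["OH-Kyn"]] * x[["OH-Kyn"]],
    "AA" = v[["KYNU_a"]] - kc[["AA"]] * x[["AA"]],
    "OH-AA" = v[["KYNU_b"]] - v[["HAAO"]] - kc[["OH-AA"]] * x[["OH-AA"]]
  )
}

#' Steady state of the kinetic model
#'
#' Integrates the stiff ODE system from zero internal concentrations
#' (deSolve, lsoda) until the derivative norm is negligible relative to the
#' state, then polishes the root of the algebraic system by damped Newton
#' iteration with a numerical Jacobian. At the returned state the flux
#' balance of every internal species holds to ~1e-10 relative to the
#' largest flux.
#'
#' @param model A `kinetic_model`.
#' @param t_max Maximum integration time (h).
#' @param deriv_tol Relative derivative tolerance ending the integration
#'   phase.
#' @param max_newton Newton iteration cap.
#' @return Object of class `kp_steady_state`: `concentrations` (tibble
#'   species/conc_mM), `fluxes` (tibble reaction/flux_mM_h including
#'   clearance fluxes), `residual`, `rel_residual`, `converged`.
#' @examples
#' ss <- steady_state(kp_reference_model())
#' ss$concentrations
#' @export
steady_state <- function(model, t_max = 1e6, deriv_tol = 1e-9,
                         max_newton = 60) {
  stopifnot(inherits(model, "kinetic_model"))
  if (any(model$k_clear <= 0)) {
    rlang::abort("all clearance rates must be positive for a bounded steady state",
                 class = "trpflux_config_error")
  }
  sp <- kp_species()
  f <- function(x) kp_rhs(stats::setNames(pmax(x, 0), sp), model)

  # phase 1: stiff integration toward the attractor
  ode_fn <- function(t, y, parms) list(unname(f(y)))
  x <- stats::setNames(rep(0, 7), sp)
  t_hi <- 1
  repeat {
    sol <- deSolve::lsoda(y = unname(x), times = c(0, t_hi), func = ode_fn,
                          parms = NULL, rtol = 1e-10, atol = 1e-14)
    x <- stats::setNames(pmax(sol[nrow(sol), -1], 0), sp)
    dx <- f(x)
    if (max(abs(dx)) < deriv_tol * max(max(abs(x)), 1) || t_hi >= t_max) break
    t_hi <- t_hi * 10
  }

  # phase 2: damped Newton polish
  num_jac <- function(x) {
    J <- matrix(0, 7, 7)
    fx <- f(x)
    for (j in 1:7) {
      h <- max(1e-8, 1e-6 * abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (f(xp) - fx) / h
    }
    J
  }
  res_norm <- function(x) max(abs(f(x)))
  cur <- res_norm(x)
  converged <- FALSE
  for (it in seq_len(max_newton)) {
    if (cur < 1e-14 * max(max(abs(x)), 1)) { converged <- TRUE; break }
    J <- num_jac(x)
    step <- tryCatch(solve(J, -f(x)), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- pmax(x + lam * step, 0)
      new <- res_norm(xn)
      if (new < cur || lam < 1e-8) break
      lam <- lam / 2
    }
    if (new >= cur) { converged <- cur < 1e-10; break }
    x <- xn
    cur <- new
  }
  if (cur < 1e-12 * max(max(abs(x)), 1)) converged <- TRUE

  v <- kp_rates(x, model)
  clear_flux <- model$k_clear * x
  fluxes <- tibble::tibble(
    reaction = c(names(v), paste0("clear_", sp)),
    flux_mM_h = c(unname(v), unname(clear_flux))
  )
  max_flux <- max(abs(fluxes$flux_mM_h), 1e-300)
  resid <- res_norm(x)
  if (!converged && resid > 1e-8 * max_flux) {
    rlang::abort(
      paste0("steady state did not converge: residual ", format(resid),
             " vs max flux ", format(max_flux)),
      class = "trpflux_convergence_error"
    )
  }
  structure(
    list(
      concentrations = tibble::tibble(species = sp, conc_mM = unname(x)),
      fluxes = fluxes,
      residual = resid,
      rel_residual = resid / max_flux,
      converged = TRUE
    ),
    class = "kp_steady_state"
  )
}

#' @export
print.kp_steady_state <- function(x, ...) {
  cat("<kp_steady_state> relative flux-balance residual ",
      format(x$rel_residual, digits = 3), "\n", sep = "")
  print(x$concentrations)
  invisible(x)
}

#' Steady states for a cohort of expression profiles
#'
#' Builds one expression-scaled model per sample (reference = mean per-gene
#' abundance over all samples, or a supplied named vector) and solves each
#' to steady state. Samples with missing mapped genes are excluded (recorded
#' in the `"excluded_samples"` attribute), mirroring the handling of
#' missing expression values.
#'
#' @param expression Long tibble (`sample_id`, `group`, `gene`, `tpm`), as
#'   from [simulate_expression()].
#' @param params Parameter list from [kp_params()].
#' @param reference `"overall"` (default: mean over all samples) or a named
#'   per-gene numeric vector.
#' @return Tibble: one row per modelled sample with `sample_id`, `group`,
#'   one column per species (mM) and `flux_` columns per reaction; attribute
#'   `"excluded_samples"` lists skipped samples.
#' @export
simulate_steady_states <- function(expression, params = kp_params(),
                                   reference = "overall") {
  wide <- expression |>
    dplyr::select("sample_id", "group", "gene", "tpm") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "tpm")
  gene_cols <- setdiff(names(wide), c("sample_id", "group"))
  if (identical(reference, "overall")) {
    reference <- colMeans(wide[, gene_cols, drop = FALSE], na.rm = TRUE)
  }
  excluded <- character(0)
  rows <- vector("list", nrow(wide))
  for (i in seq_len(nrow(wide))) {
    ex <- unlist(wide[i, gene_cols])
    model <- withCallingHandlers(
      build_kinetic_model(ex, reference, params = params),
      trpflux_sample_excluded = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(model)) {
      excluded <- c(excluded, wide$sample_id[i])
      next
    }
    ss <- steady_state(model)
    conc <- stats::setNames(ss$concentrations$conc_mM,
                            ss$concentrations$species)
    fx <- ss$fluxes
    fx <- stats::setNames(fx$flux_mM_h, paste0("flux_", fx$reaction))
    rows[[i]] <- tibble::as_tibble(c(
      list(sample_id = wide$sample_id[i], group = wide$group[i]),
      as.list(conc), as.list(fx[1:9])
    ))
  }
  out <- dplyr::bind_rows(rows)
  if (length(excluded) > 0) {
    rlang::inform(paste0(length(excluded),
                         " sample(s) excluded for missing expression: ",
                         paste(excluded, collapse = ", ")))
  }
  attr(out, "excluded_samples") <- excluded
  out
}

#' Compare simulated metabolite concentrations between cohorts
#'
#' For each metabolite: ROUT-style outlier removal within each cohort
#' ([rout_remove()]), then a pooled-variance two-tailed unpaired t-test.
#' Reports mean and SEM per cohort. Metabolites with fewer than 3 surviving
#' values in either cohort are skipped with a warning.
#'
#' @param steady_states Output of [simulate_steady_states()] with exactly
#'   two groups.
#' @param rout_q ROUT FDR threshold (default 0.01).
#' @param species Species columns to compare (default [kp_species()]).
#' @return Tibble of class `kp_cohort_comparison`: per species the group
#'   means, SEMs, sample/removed counts, `t`, `df`, `p_value`.
#' @export
compare_cohorts <- function(steady_states, rout_q = 0.01,
                            species = kp_species()) {
  grp <- unique(steady_states$group)
  if (length(grp) != 2) {
    rlang::abort("compare_cohorts needs exactly two groups",
                 class = "trpflux_validation_error")
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- purrr::map(species, function(sp) {
    a <- steady_states[[sp]][steady_states$group == grp[1]]
    b <- steady_states[[sp]][steady_states$group == grp[2]]
    ka <- if (length(a) >= 8) rout_keep(a, q = rout_q) else a
    kb <- if (length(b) >= 8) rout_keep(b, q = rout_q) else b
    if (length(ka) < 3 || length(kb) < 3) {
      rlang::warn(paste0("skipping ", sp, ": fewer than 3 values survive outlier removal"))
      return(NULL)
    }
    if (stats::sd(c(ka, kb)) == 0 || identical(sort(ka), sort(kb))) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(ka) + length(kb) - 2),
                 p.value = 1)
    } else {
      tt <- stats::t.test(ka, kb, var.equal = TRUE)
    }
    tibble::tibble(
      species = sp,
      group_1 = grp[1], group_2 = grp[2],
      n_1 = length(ka), n_2 = length(kb),
      removed_1 = length(a) - length(ka), removed_2 = length(b) - length(kb),
      mean_1 = mean(ka), sem_1 = sem(ka),
      mean_2 = mean(kb), sem_2 = sem(kb),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kp_cohort_comparison", class(out))
  out
}
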