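# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (loops, closed forms, grid search) and share
# no code with the implementations they verify.

# least squares by the normal equations
oracle_ols <- function(X, y) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  d <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / d
  list(beta = drop(beta), s2 = s2, d = d, xtx_inv = solve(xtx))
}

# method-of-moments empirical Bayes on log variances, trigamma inversion by
# uniroot bisection (independent of the package's Newton iteration)
oracle_ebayes <- function(s2, d) {
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    half_d0 <- stats::uniroot(function(y) trigamma(y) - evar,
                              lower = 1e-8, upper = 1e8,
                              tol = 1e-14)$root
    d0 <- 2 * half_d0
    s0 <- exp(emean + digamma(half_d0) - log(half_d0))
  } else {
    d0 <- Inf
    s0 <- exp(mean(log(s2)))
  }
  s2_post <- if (is.finite(d0)) (d0 * s0 + d * s2) / (d0 + d) else rep(s0, length(s2))
  list(d0 = d0, s0_sq = s0, s2_post = s2_post)
}

# Breslow log partial likelihood by naive loops
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t_k in sort(unique(time[event == 1]))) {
    dead <- which(time == t_k & event == 1)
    risk <- which(time >= t_k)
    ll <- ll + beta * sum(x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# log-rank chi-square by the classical hypergeometric computation
oracle_logrank_chisq <- function(time, event, group) {
  o_minus_e <- 0
  v <- 0
  for (t_k in sort(unique(time[event == 1]))) {
    at_risk <- time >= t_k
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t_k & event == 1)
    d1 <- sum(time == t_k & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Spearman rho with average-rank ties via explicit rank-Pearson
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# convenience: run the standard quantitation pipeline on a simulated study
run_pipeline <- function(study, qc = FALSE) {
  areas <- study$areas
  if (qc) {
    rep <- qc_linearity(areas)
    areas <- replace_low_quality_reference(areas, rep)
  }
  ex <- exclude_pairs(areas, study$subjects)
  build_ratio_matrix(ex$areas, subjects = ex$subjects)
}

cell_key <- function(d) paste(d$analyte, d$plex_id, d$channel)
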