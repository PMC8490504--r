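---
title: "Models and methods behind trpflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trpflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpflux)
library(dplyr)
```

trpflux implements a complete analysis chain for multiplexed, isobaric-label
(TMT sixplex) quantitation of serum tryptophan (Trp) and its
kynurenine-pathway metabolites, together with the downstream statistics such
a study needs: reference-design normalization, empirical-Bayes moderated
differential abundance, the enzymatic-distance fold-change gradient,
clinical association statistics, and an expression-scaled kinetic model of
the pathway. Because serum cohorts of this kind are typically not publicly
deposited, the package also contains a first-class synthetic-data generator
that reproduces the statistical structure of the design, so every stage is
testable end to end. This vignette explains the models, the defaults, and
the design decisions — including what the simulations can and cannot tell
you about real data.

## The measurement design being emulated

One sixplex carries four subject sera on reporter channels 126, 128, 129 and
130 (two tumor, two control, randomized over the channels), a pooled
reference serum on channel 131 (an aliquot of the same pool — made from 34
individual sera — in every plex), and pure labeled standards on channel 127
to aid peak assignment. Abundances are only comparable across plexes as
ratios to the shared reference; the analysis therefore works on
$\log_2[X(i,j)/X(\mathrm{ref},j)]$ per subject $i$ and analyte $j$.

The generator (`sim_config()`, `simulate_study()`) draws, on the log2 scale,

$$\log_2 A(j, i, p, c) = \mu_j + \beta_j\,[\text{tumor}_i] + u_{ij} +
  \pi_p + \gamma_c, \qquad
  A_{\text{obs}} = 2^{\log_2 A}\,(1 + \varepsilon),\;
  \varepsilon \sim N(0, \mathrm{CV}_j),$$

with per-analyte baselines $\mu_j$, class effects $\beta_j$, between-subject
deviations $u_{ij}$ (SD 0.35 log2 units, i.e. roughly a 27% biological CV —
serum metabolites are more variable between donors than technically),
random plex offsets $\pi_p$ (SD 0.25 log2) and fixed channel offsets
$\gamma_c$ (channel bias is systematic in isobaric labeling, hence fixed
rather than redrawn per plex). Technical CVs default to 5–15% depending on
the analyte. The reference channel carries the mean natural-scale abundance
of the first 34 simulated subjects with its own technical noise.

The default class effects are $\beta = -0.6, -0.45, -0.45, -0.3, -0.2,
-0.1, -0.05$ log2 units for Trp, OH-Trp, FK, Kyn, OH-Kyn, AA and OH-AA — a
magnitude that decreases monotonically with the number of enzymatic steps
from Trp (distances 0, 1, 1, 2, 3, 3, 4). These are configurable defaults
that reproduce the qualitative substrate-limitation gradient, not estimates
of any particular cohort's values. Tumor subjects additionally receive a
volume-linked component for the proximal metabolites (negative slopes per SD
of log tumor volume) and survival times whose hazard decreases with the
subject's latent kynurenine level. One subtlety worth recording: the volume
term is standardized against its generating distribution, not within-sample;
within-sample standardization would pin the term's cohort sum to exactly
zero, an artificial constraint that measurably deflates the null
distribution of the downstream t-statistics.

What the generator does **not** emulate: chromatographic peak shape and
integration, isotopic impurity leakage between reporter channels,
plex-by-analyte interactions, non-lognormal heavy tails, missingness
mechanisms, and any correlation structure between analytes beyond the
shared design factors. Passing tests on synthetic data therefore validate
the statistical machinery under the stated model, not robustness to every
artifact of a real LC-MS/MS campaign.

## Quality control and the ratio matrix

Reporter-area QC follows the linearity idea — each channel's areas across
plexes should be proportional to the plex's overall intensity, with
coefficient about 1. The operationalization in `qc_linearity()`:

* The per-plex summary is the **median of the four subject-position
  channels**, with the channel under assessment left out of its own median.
  Letting a channel predict itself is degenerate in the extreme: the
  low-noise reference *is* the plex median in most plexes, which collapses
  the residual scale.
* Slopes come from a through-origin fit that is refit after masking cells
  beyond the residual cutoff, so that one grossly corrupted cell flags
  itself without dragging the slope or condemning its whole channel.
* Standardized residuals are computed on the **log scale** (reporter noise
  is multiplicative; raw-scale robust z-scores inherit lognormal skew and
  flag 1.5–4% of clean cells). The outlier mask uses median/MAD; the final
  standardization uses the SD of the masked residuals, which is less noisy
  than the MAD at ~22 plexes per channel. The default cutoff is
  `resid_k = 3`.
* A channel whose uncentered $R^2$ falls below `r2_min` has all its cells
  flagged. The default is 0.5: with realistic between-subject spread a
  *clean* channel's uncentered $R^2$ concentrates around 0.85–0.95 with a
  sampling tail reaching ~0.75, while grossly broken channels fall below
  ~0.4. A threshold of 0.8 sits inside the clean-channel null and cannot
  deliver percent-level false-flag rates; 0.5 separates the two regimes.

With these choices the QC achieves, on the default study conditions with
10× reference corruption at 5% rate, recall 1.0 with a false-flag rate
below 1% — the package's QC contract, verified in `test-acceptance.R`.

Only flagged **reference** cells are repaired (median of channels
126/128/129/130 of the same plex, marked `replaced`); flagged subject cells
are marked but never altered — imputing subject measurements would
fabricate data. Pairs flagged for technical problems or IDH-mutant status
are excluded together with their matched partner before testing
(`exclude_pairs()`). `build_ratio_matrix()` then forms the log2
sample/reference ratios; missing values propagate (an analyte missing in
more than half the subjects warns), and raw ratios are kept alongside.

## Differential abundance

Per analyte, `fit_metabolite_lm()` fits the fixed-effect model

$$\text{logRatio} \sim \text{Class} + \text{TMTPlex} + \text{channel}$$

by OLS with treatment contrasts (control, first plex, channel 126 as
reference levels), so the class coefficient is directly the
tumor-vs-control log2 fold change. The plex factor absorbs both plex-scale
effects and the shared reference noise of each plex; the channel factor
absorbs systematic channel bias. Factors with a single observed level are
dropped (a single-plex study reduces to `Class + channel`); a rank-deficient
design is an error that names the aliased columns rather than a silent
coefficient drop. Only the four subject channels enter the model — the
reference channel provides denominators, not responses.

`ebayes_moderate()` shrinks the per-analyte residual variances $s_j^2$ (with
$d_j$ degrees of freedom) toward a prior by the classical method of moments
on $\log s^2$: with
$e_j = \log s_j^2 - \psi(d_j/2) + \log(d_j/2)$, the prior degrees of freedom
solve $\psi'(d_0/2) = \widehat{\mathrm{Var}}(e) - \overline{\psi'(d/2)}$
(Newton inversion of the trigamma function) and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. The posterior variance
is $s^2_{\text{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and the moderated t
uses $d + d_0$ degrees of freedom. Two choices deserve a note:

* **Degenerate moment equation.** When the observed variances are less
  dispersed than pure sampling noise allows, the trigamma equation has no
  positive solution and the prior is a point mass ($d_0 = \infty$). We set
  $s_0^2$ to the **geometric mean** of the observed variances in this
  branch, so that exactly equal variances shrink to themselves and the
  moderated t coincides exactly with the ordinary t — the limit a no-op
  shrinkage should have. (The bias-corrected alternative,
  $\exp(\bar e)$, differs from the common value by a factor
  $e^{\psi(d/2)-\log(d/2)}$ and breaks that exactness.)
* **Robust option.** The `robust = TRUE` flag winsorizes $\log s^2$ at the
  5%/95% quantiles before moment estimation. This is a documented
  simplification of the fully robust empirical-Bayes variant (which
  down-weights outlier variances via their predictive distribution); it
  protects $d_0$ from single-variance outliers, which is the failure mode
  that matters for a 7-analyte panel.

With only 7 analytes, $d_0$ estimation is unstable; `d0_stability()` reports
a bootstrap SD, and `ebayes_moderate(moderate = FALSE)` is the documented
ordinary-t fallback. No multiple-testing correction is applied by default
(the analysis works at a fixed $\alpha = 0.05$ across 7 planned analytes);
`p.adjust` on the tidy output is one line for those who want it.

`fold_change_gradient()` quantifies the substrate-limitation signature:
Spearman rank correlation (average-rank ties) between $|\log_2 FC|$ and the
enzymatic distance from Trp, with a permutation p-value over distance-label
permutations. The scientific hypothesis is directional — the decrease
*attenuates* with distance — so the package's calibration analyses test
$\rho < 0$ one-sided; the function default is two-sided for exploratory
use. A constant $|\log_2 FC|$ vector is reported as $\rho = 0$ with a
degeneracy flag rather than an error.

## Clinical associations

`regress_on_covariate()` regresses the metabolite level on the standardized
covariate (tumor volume, cumulative bevacizumab dose) and reports the
forest-plot quantities $MR = e^b$ and $CI = e^{b \pm 2\,SE_b}$. The
multiplier 2 (not 1.96) is deliberate and matches the reporting convention
of the serum analysis; `z_mult = 1.96` restores the exact normal quantile.
Group comparisons over binary molecular features use the pooled-variance
(Student) two-sample t-test — equal variances are assumed by design, not
Welch-corrected.

`cox_univariate()` implements Newton–Raphson maximization of the Cox
partial likelihood with Breslow tie handling (Efron behind a flag; at daily
resolution ties are rare and Breslow is the simplest well-defined choice),
Wald standard errors from the observed information, and hazard-ratio
intervals again via $e^{\beta \pm 2\,SE}$. The score test at $\beta = 0$ is
returned and equals the log-rank chi-square for a binary covariate without
ties — a classical identity the tests verify against an independent
hypergeometric computation and against `survival::survdiff`. Monotone
likelihoods (perfect separation) and constant covariates raise classed
errors instead of wandering to $\pm\infty$. By default the survival
analysis standardizes each analyte's levels, so hazard ratios are per SD of
the log2 ratio; raw levels are an option, as the original scale choice is
not recoverable from the reporting.

`rout_remove()` is a median/MAD analogue of robust-regression outlier
removal with FDR control: standardized residuals against the robust center,
two-sided t tail probabilities (df $n-1$), Benjamini–Hochberg adjustment,
removal at $Q = 1\%$ by default. It is deliberately *not* the proprietary
robust-nonlinear-regression procedure of the original software; for
location-scale data (the use here) the median/MAD version has the same
operating characteristics — false-removal rate $\le 2\%$ on clean Normal
samples of 100, recall 1.0 for 10$\sigma$ contamination — which the
acceptance tests measure. A zero MAD on non-constant data falls back to an
IQR-based scale with a message.

## The kinetic model

`kp_reactions()` defines a minimal irreversible Michaelis–Menten network:
transporter uptake of extracellular Trp (fixed at 0.01 mM, an upper bound
for free Trp in blood), the serotonin-branch first step (TPH, truncated at
OH-Trp since the measured panel ends there), the parallel dioxygenases IDO1
and TDO2 to N-formylkynurenine, AFMID to kynurenine, the KMO/KYNU branch
point, KYNU acting on 3-OH-kynurenine, and HAAO draining 3-OH-anthranilic
acid toward the NAD$^+$ branch, which — like kynurenic acid — is treated as
a sink. Every internal species has first-order clearance so that a finite
steady state exists even with zero downstream capacity. All $V_{max}$, $K_m$
and clearance defaults live in `inst/extdata/kp_params.yaml`; they are
order-of-magnitude plausible artifact defaults, not published kinetic
constants, and analyses should treat them as a versioned configuration.

Transcript abundances scale capacities linearly with a pseudo-count:
$V_{max,r} = V^{\text{ref}}_{max,r}\,(E_r + \epsilon)/(\bar E_r +
\epsilon)$, genes summed within a mapping group (TPH1+TPH2 → TPH; KYNU
drives both KYNU reactions), $\epsilon = 0.01$. This is the simplest rule
that is invariant to a global rescaling of the expression matrix when the
reference mean is recomputed on the same cohort. A sample missing a mapped
gene is excluded with a record, not modelled with a guess.

`steady_state()` integrates the stiff ODE system from zero internal
concentrations (deSolve/lsoda, doubling time horizons until
$\|\dot x\|_\infty < 10^{-9}\max(\|x\|_\infty, 1)$) and then polishes the
algebraic root by damped Newton iteration with a numerical Jacobian,
clamping at zero. Integrate-then-polish is robust to stiff transients that
defeat Newton from a cold start; the returned state balances fluxes to
better than $10^{-8}$ relative to the largest flux (typically $10^{-12}$).
`compare_cohorts()` applies per-cohort outlier removal and pooled t-tests
to the simulated concentrations, mean ± SEM style. The default expression
fold changes for the tumor-like cohort elevate the catabolic enzymes
(IDO1 4×, TDO2 3×, KMO/KYNU 2×) and the transporter 3× — LAT1/SLC7A5 is
among the most strongly overexpressed amino-acid transporters in
glioblastoma, and an uptake increase of this size is required for the
intracellular substrate pool to sustain elevated OH-Trp alongside the
stronger dioxygenase pull; with it, all five downstream metabolites
(OH-Trp, FK, Kyn, OH-Kyn, OH-AA) rise in the high-expression cohort, the
directionality the model is meant to reproduce. Whether such simulated
pools correspond to intracellular or exported metabolite is ambiguous; the
package reports them as intracellular concentrations.

## Numerical choices, problem sizes, limitations

* Trigamma inversion and the Cox Newton iteration both converge to relative
  steps below $10^{-8}$; the Cox fitter halves steps when the likelihood
  decreases and declares divergence past $|\beta| > 50$.
* Permutation p-values use the add-one estimator $(1 + \#\{\ge\})/(B+1)$,
  which can never return zero.
* The calibration studies in `test-acceptance.R` and
  `scripts/acceptance.R` use 1000 null cohorts (43 pairs each) for type-I
  error, 200 cohorts for effect/gradient recovery, 100 corruption seeds for
  QC operating characteristics, 500 simulated survival cohorts (n = 200,
  30% censoring) for Cox interval coverage, and 100 random
  parameterizations for kinetic flux balance — sizes chosen so each
  quantity's Monte-Carlo error is well below the property being asserted.
* Known limitations: no isotope-impurity correction or peak-level modelling;
  the moderated-t "robust" option is winsorization, not full outlier
  down-weighting; the kinetic parameterization is a stand-in, so only
  directional, not quantitative, conclusions transfer; survival simulation
  uses exponential event and censoring times.
```
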