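---
title: "Brain network topology across the menstrual cycle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain network topology across the menstrual cycle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cyclegraph` implements a longitudinal MEG-style brain-network analysis of
the menstrual cycle: phase-based functional connectivity, minimum-spanning-tree
(MST) topology, a three-time-point nonparametric statistical plan, and a
cross-validated multilinear model linking sex-hormone changes to topological
and psychological changes. Because no public recordings exist for this kind
of study, the package also ships a calibrated synthetic-study generator so
that every stage — from raw multichannel signals to the final hormone model —
can be exercised and tested end to end. This vignette documents the models,
the tunable parameters, the numerical choices, and the limits of what the
synthetic studies can establish.

## The study design being emulated

The emulated design observes `n_subjects = 24` naturally cycling women at
three phases of one cycle: early follicular (T1, cycle days 1–4),
peri-ovulatory (T2, days 13–15) and mid-luteal (T3, days 21–23). At each
session three kinds of data are collected:

* **Source-level neural signals** on the 90 regions of the AAL atlas
  (`aal90_labels()`), band-limited to the canonical delta/theta/alpha/beta/
  gamma bands.
* **Serum hormones**: estradiol (pg/ml), progesterone (ng/ml), LH and FSH
  (mIU/ml), each with an assay detection limit (11.8, 0.2, 0.07 and
  0.3 respectively).
* **Psychological scores**: Rosenberg self-esteem, the six Ryff well-being
  dimensions (environmental mastery among them), and the BDI/BAI
  inventories used as inclusion gates (BDI < 10, BAI < 21).

Two within-cycle contrasts summarize change: the *follicular contrast*
(T2 − T1) and the *luteal contrast* (T3 − T2).

## Phase linearity measurement (PLM)

For two signals with instantaneous phases $\phi_x(t)$, $\phi_y(t)$, let
$z(t) = e^{i\,\Delta\phi(t)}$ with $\Delta\phi = \phi_x - \phi_y$ be the
interferometric signal. The PLM is the fraction of the power spectrum of
$z$ lying within $\pm B$ of zero frequency:

$$\mathrm{PLM} \;=\;
\frac{\int_{-B}^{B}\bigl|\int_0^T e^{i\Delta\phi(t)}e^{-i2\pi f t}\,dt\bigr|^2\,df}
     {\int_{-\infty}^{\infty}\bigl|\int_0^T e^{i\Delta\phi(t)}e^{-i2\pi f t}\,dt\bigr|^2\,df}
\in [0,1],$$

with $2B = 1$ Hz by default (`plm_params(B = 0.5)`). A phase difference
that evolves almost linearly (near-constant frequency offset smaller than
$B$) concentrates power near zero frequency and scores high.

Implementation choices:

* **Phases** come from the analytic signal (FFT single-sideband
  reconstruction) of the band-filtered trace; filtering is a zero-phase
  (forward–backward) fourth-order Butterworth design (`bandpass()`).
* **Spectrum**: one discrete Fourier transform of the whole epoch — a
  rectangle-rule realization of the finite-$T$ integrals at frequency
  resolution $1/T$, no zero padding by default (`pad_factor`).
* **Parseval guard**: since $|z| = 1$, the total two-sided power must equal
  $n_{\mathrm{fft}} \cdot n$; every call verifies this to $10^{-6}$
  relative.
* **The 0 Hz bin** (`dc_policy`): a *constant* phase difference — the
  signature of volume conduction or a shared source rather than genuine
  interaction — puts its power exactly into the 0 Hz bin. The default
  `"exclude"` removes that bin from numerator and denominator, so constant
  offsets score 0; `"include"` evaluates the literal integral. Both are
  first-class and tested.
* **Epoching**: epochs are consumed as provided; epochs shorter than
  `min_epoch_s = 4` s are rejected with a warning. Matrices are computed
  per epoch (`plm_epoch_matrices()`); topology is averaged across epochs.

## MST topology

Connectivity matrices are reduced to their maximum-weight spanning tree —
the *minimum* spanning tree in the MEG convention of treating similarity
as inverse distance — via Kruskal's algorithm on edges sorted by
descending weight (`max_spanning_tree()`). Ties are broken by
lexicographic node-pair order; with continuous PLM weights ties have
measure zero, but the deterministic rule makes every tree reproducible.
A `weight_transform = "reciprocal"` option reports distance weights
instead; the edge set is provably identical.

Per tree the package computes: **leaf fraction** $L_f$ (fraction of
degree-1 nodes; denominator $N$ by default, $M = N-1$ via option),
**degree divergence** $K = \langle k^2\rangle/\langle k\rangle$,
**tree hierarchy** $T_h = L/(2 M \cdot BC_{\max})$ (normalized so
$T_h \le 1$; the unnormalized ratio $L/BC_{\max}$ is available as
`formula = "literal"`), **diameter** (hop count, two-sweep BFS), nodal
**degree**, and nodal **betweenness centrality** — the fraction of the
$(N-1)(N-2)/2$ node pairs whose unique tree path crosses the node,
computed exactly from the component sizes left by removing the node
(trees need no general shortest-path machinery). Metrics are averaged
across epochs to one value per subject, session and band.

## Statistical plan

* Normality gate: Shapiro–Wilk (`shapiro_wilk()`), logged alongside
  parametric tests.
* Hormones: one-way ANOVA across the three phases
  (`anova_oneway()` / `anova_from_summary()`; the summary form consumes
  printed group means/SDs directly), paired-t post hocs. The one-way
  layout (df = 2, 69 at n = 24) matches the emulated analysis; a
  repeated-measures ANOVA is deliberately out of scope.
* Topology: Friedman test across sessions per variable
  (`friedman_test3()`), Benjamini–Hochberg adjustment within the declared
  family (`bh_fdr()`), Wilcoxon signed-rank post hocs reported unadjusted
  (`wilcoxon_signed_rank()`, zeros dropped by Wilcoxon's rule, exact p for
  up to 25 untied pairs).
* The Friedman statistic follows the rank-sum formula
  $\chi^2 = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$ on mid-ranks. For
  three untied conditions with $n \le 12$ the p-value is **exact**: the
  full permutation distribution over the $6^n$ equally likely rank
  assignments is computed by dynamic programming over column rank sums.
  Beyond that the $\chi^2$ approximation is used (its type-I error at
  $n = 24$ is within half a percentage point of nominal, as the test suite
  verifies).
* Deltas: `compute_deltas()` emits the two contrasts per subject and
  variable; subjects missing a session are dropped with a warning.

## Hormone → topology model

`fit_ols()` fits, by ordinary least squares, the change in a topological
variable (the hub's betweenness) on the four hormone changes, with four
nuisance covariates: a contrast indicator (follicular vs luteal, absorbing
the repeated-measures structure), age, education and cycle length. One row
per subject per contrast gives 48 observations and 9 estimated parameters.
Hormone predictors are z-scored by default (`standardize_predictors`;
coefficient signs unaffected). `loocv()` refits the model once per
left-out observation (a `loo_unit = "subject"` variant removes both rows
of a subject) and reports

* the PRESS-based cross-validated $R^2 = 1 - \mathrm{PRESS}/SS_{tot}$,
* the squared correlation between observed and predicted values, and
* standardized prediction residuals.

The refit loop is the implementation; the hat-matrix identity
$e_i/(1-h_{ii})$ serves as an independent oracle in the tests. The
LOOCV $R^2$ can never exceed the in-sample $R^2$, and the suite asserts
it. `spearman_cor()` (exact permutation p for $n \le 9$, t approximation
above) and `vif()` ($1/(1-R_j^2)$) complete the correlation screen and
collinearity diagnostics.

## The synthetic-study generator

`generator_config()` fixes the study conditions; `generate_study()` draws
a complete bundle. What each channel emulates:

**Hormones.** Each hormone × session is a detection-limit-truncated normal
with a subject random intercept (intra-class correlation
`hormone_icc = 0.3`; the emulated study reports only marginal moments, so
the within-subject correlation is a free design choice set to a moderate
value). The configured mean/SD are the *observed* marginal moments: the
underlying normal parameters are solved numerically, integrating the
random intercept by Gauss–Hermite quadrature, so that the truncated
marginal reproduces the published session means and SDs to well under 1%.
Truncation is realized by resampling residuals (exact inverse-CDF tail
sampling in deep-truncation regimes), never by clipping, so no point mass
forms at the limit. One published target — early-follicular progesterone,
0.3 ± 0.1 with a 0.2 ng/ml floor — sits exactly on the boundary of what a
truncated normal can represent ($(\mathrm{mean}-a)/\mathrm{sd} \to 1$ is
the exponential-tail limit of the family); the calibration caps the
standardized truncation depth at 8 and matches those moments to ~1%,
at the cost of a nearly exponential shape and a vanishing within-subject
correlation for that one marginal.

**Psychological scores.** All scores are session-independent noise except
the environmental-mastery luteal change, which is a monotone function
(normal scores) of the subject's luteal estradiol change plus Gaussian
noise. The Gaussian-copula conversion $\rho_P = 2\sin(\pi\rho_S/6)$ makes
the population Spearman correlation equal the configured
`mastery_rho = 0.712`. The same mechanism couples the scalar latent
hub-betweenness delta channel at `bc_rho = 0.541`. At $n = 24$ the mean
*sample* Spearman correlation is attenuated by roughly 0.001–0.005
relative to the population value — well inside the Monte-Carlo tolerances
used.

**The model channel.** `generate_model_panel()` builds the 48-row
regression problem with signal carried only by the estradiol change.
`model_r2 = 0.47` targets the *cross-validated* explained variance at the
design size, because that is the quantity the emulated analysis reports;
the generator converts it to a population signal fraction through the
homogeneous-leverage PRESS approximation
$E[R^2_{cv}] \approx 1 - (1 - R^2_{pop})\,n^2/((n-p)(n-1))$,
which simulation confirms to about 0.01 at this design size.

**Signals.** Oscillator recordings are discrete-time noisy Kuramoto-style
phase dynamics: node $i$ advances by $2\pi f_i/f_s$ plus Gaussian jitter
(`phase_jitter = 0.08` rad/sample) and is pulled toward its neighbours by
a uniform coupling budget (`base_coupling = 0.04` per node, spread over
the $N-1$ neighbours); natural frequencies are detuned per node
(`detune_sd = 1` Hz) around the band centre; observations are
$\cos\theta$ plus noise (`obs_noise = 0.2`), sampled at `fs = 256` Hz
(sufficient for all bands up to 48 Hz; the acquisition-grade 1,024 Hz can
be restored in the config). The hub — `"Cingulum_Post_R"`, kept present
by label substitution when networks are reduced below 36 nodes — has its
coupling row and column multiplied by the session's `hub_gain`, default
(1, 2, 1) so hub connectivity peaks at T2; the subject-level luteal gain
change is copula-coupled to the estradiol change at `bc_rho`.

These coupling parameters were calibrated once, by locating the Kuramoto
locking transition: above roughly twice the default budget the network
synchronizes globally and the hub is indistinguishable; far below it
nothing is. At the defaults, a doubled hub gain raises the hub's mean PLM
by ~0.1 over the other nodes, which the MST converts into a clear
betweenness peak at T2.

**A deliberate limitation worth understanding.** The generator is
*stationary*: genuine coupling expresses itself as zero-lag phase locking,
whose interferometric power falls exactly into the 0 Hz bin — the bin the
volume-conduction-robust `dc_policy = "exclude"` is designed to discard.
On simulated recordings the DC-including estimator is therefore the one
that sees the injected coupling, and `topology_study_table()` defaults to
it; on real, nonstationary recordings the exclude policy is the
appropriate default and remains `plm_params()`'s. Passing tests on this
generator consequently demonstrate the correctness of the machinery and
the detectability of coupling differences — not that the exclude policy
is optimal for any particular real dataset. The generator also makes no
attempt at 1/f spectra, amplitude dynamics, artifacts, or source-leakage
geometry.

## Determinism and problem sizes

Identical configuration (seed included) reproduces byte-identical
artifacts; the pipeline writes a JSON manifest with the configuration
hash and per-file MD5 hashes (`run_study_pipeline()`). The repeated-run
studies in the test suite use a reduced design — 8 subjects, 20 nodes,
two 4-s epochs — which keeps one full study at about two seconds while
preserving every qualitative property of the full 24 × 90 design; the
structural checks run one full-size 90-node recording. Monte-Carlo sizes
follow the quantities being estimated: 1,000 replicates for correlation
recovery, 500 for cross-validated $R^2$, 100 runs for power and null
calibration, 5,000 for type-I error of each test.

## Known limitations

* Scalar effect channels (mastery, hub BC, model response) are separate
  latent draws calibrated to their respective published associations; the
  generator does not force one latent variable to satisfy all printed
  correlations simultaneously (the published values themselves
  over-determine a single-variable model).
* The follicular-contrast associations are left as noise; only the
  luteal-contrast effects are injected.
* The Friedman exact p enumerates rankings for $k = 3$ only; other $k$
  use the asymptotic approximation.
* `anova_oneway()` treats phases as independent groups (matching the
  emulated df); no repeated-measures or mixed-model alternative is
  provided.
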