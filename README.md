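# cyclegraph

Brain network topology across the menstrual cycle, from phase-based MEG
connectivity to hormone–topology–well-being models.

`cyclegraph` is for researchers who study how large-scale brain network
organization changes with the hormonal state — specifically the design in
which naturally cycling women are measured at the early-follicular (T1),
peri-ovulatory (T2) and mid-luteal (T3) phases, with source-level neural
recordings, serum hormone assays (estradiol, progesterone, LH, FSH) and
psychological questionnaires at each session. The package implements the
full analysis chain and, because raw recordings of such studies are not
publicly deposited, a calibrated synthetic-study generator so the chain is
testable end to end.

## What it computes

**Connectivity — the phase linearity measurement (PLM).** For signals with
instantaneous phases φ_x, φ_y (analytic signal of the zero-phase
Butterworth band-filtered trace), the PLM is the fraction of spectral power
of the interferometric signal z(t) = exp(i·Δφ(t)) within ±B of zero
frequency (2B = 1 Hz by default):

    PLM = ∫₋B^B |Z(f)|² df / ∫₋∞^∞ |Z(f)|² df  ∈ [0, 1]

Computed per epoch for every pair of the 90 AAL regions and five canonical
bands (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–48 Hz).
The exact 0 Hz bin — where a constant phase difference, the signature of
volume conduction, lands — is excluded by default (`plm_params()`).

**Topology — the minimum spanning tree.** Each connectivity matrix is
reduced by Kruskal's algorithm to the N−1 strongest-edge loop-less
backbone, and characterized by leaf fraction Lf, degree divergence
K = ⟨k²⟩/⟨k⟩, tree hierarchy Th = L/(2·M·BCmax), diameter, nodal degree
and betweenness centrality (exact on trees), averaged across epochs.

**Statistics.** Hormones: one-way ANOVA across phases (raw data or printed
summary statistics) with paired-t post hocs. Topology: Friedman tests
across the three sessions (exact permutation p for small n),
Benjamini–Hochberg FDR within declared families, Wilcoxon signed-rank post
hocs. Changes are summarized by the follicular (T2−T1) and luteal (T3−T2)
contrasts.

**Modeling.** An OLS model predicts the topology change (hub betweenness)
from the four hormone changes plus nuisance covariates (repeated-measures
indicator, age, education, cycle length), validated by leave-one-out
cross-validation (PRESS R², standardized prediction residuals); Spearman
correlation screens with FDR and variance-inflation-factor diagnostics
complete the chain.

**Synthetic studies.** `generator_config()` + `generate_study()` draw
hormone panels matching the published session means/SDs above the assay
detection limits, well-being scores whose luteal environmental-mastery
change tracks the estradiol change (population Spearman ρ = 0.712),
latent hub-betweenness changes coupled at ρ = 0.541, a model channel
calibrated to a cross-validated R² of 0.47, and coupled noisy phase
oscillators whose hub ("Cingulum_Post_R", right posterior cingulate)
doubles its coupling at T2.

## Worked example

A reduced synthetic study (24 subjects, 20-node networks) through the full
pipeline:

```r
library(cyclegraph)
cfg <- generator_config(n_subjects = 24, n_nodes = 20, seed = 1)
res <- run_study_pipeline(cfg, "demo_run")
print(res$hormone_anova, digits = 3)
```

```
       hormone    F df1 df2        p    p_fdr
1    estradiol 32.1   2  69 1.36e-10 2.73e-10
2 progesterone 77.7   2  69 2.11e-18 8.43e-18
3           lh 13.2   2  69 1.43e-05 1.65e-05
4          fsh 13.0   2  69 1.65e-05 1.65e-05
```

All four hormones vary strongly across the cycle phases, as injected from
the published session means. The topology comparison singles out the hub:

```r
print(subset(res$session_stats, select = c(variable, statistic, p, p_fdr)), digits = 3)
```

```
           variable statistic      p p_fdr
1     leaf_fraction      1.00 0.6065 0.758
2 degree_divergence      1.90 0.3875 0.646
3    tree_hierarchy      0.00 1.0000 1.000
4          diameter      2.15 0.3420 0.646
5            bc_hub      6.90 0.0318 0.159
```

The hub's betweenness is the only variable with evidence of a session
effect (Friedman χ² = 6.90, raw p = 0.032; at this reduced network size a
single run does not always survive the five-variable FDR family). The
hormone-delta model recovers estradiol as the significant positive
predictor of the hub betweenness change:

```
model: in-sample R2 = 0.741, LOOCV R2 = 0.631
         term estimate    se    t       p
2 d_estradiol     1.26 0.199 6.35 1.7e-07
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/cyclegraph.R`:

```sh
Rscript inst/scripts/cyclegraph.R simulate --config cfg.yaml --out out/
Rscript inst/scripts/cyclegraph.R run-all  --config cfg.yaml --out out/
```

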