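---
title: "Methods: how RBPs coordinate their target mRNAs"
author: "rbpregulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how RBPs coordinate their target mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpregulon)
```

## The question

RNA-binding proteins (RBPs) bind elements in the 3' UTRs of their target
mRNAs and control their stability — a post-transcriptional regulon,
functionally analogous to a bacterial operon. Two observations need
reconciling: across many growth conditions most RBPs are *co-expressed*
with their targets (the more RBP, the more target mRNA on average), yet
the *dispersion* of expression among a regulon's members shrinks as the
RBP rises. This package implements the three analyses that establish and
explain that pattern in budding yeast, against synthetic data with known
ground truth:

1. **Co-expression statistics.** Per condition, the mean, standard
   deviation and coefficient of deviation (CD = SD/mean) of each
   regulon's log expression; Spearman correlations of each summary with
   the RBP's own expression across conditions; a four-way classification
   of every RBP by the sign pair (rho with the mean, rho with the CD).
2. **Knockout degradation analysis.** With deletion-strain (KO)
   expression standing in for "before the RBP acts" and wild type for
   "after", the per-target degradation efficiency (KO − WT)/KO, its
   correlation with expression level, and a variance-ratio F-test on the
   between-strain CD difference among targets.
3. **A TF–RBP regulation model.** A Hill-kinetics ODE whose Monte-Carlo
   sweep over the (m, j) plane produces the four-region phase diagram
   explaining when co-expression-with-buffering arises.

## Co-expression statistics

Expression values are RPKM-like and log-transformed before any summary
(default base 10, pseudocount 1; the pseudocount is exposed because raw
zero values would otherwise be lost — with strictly positive input a
pseudocount of 0 is exact). For regulon *G_r* of RBP *r* in condition
*c*, with log values *x_gc*:

- mean_rc = mean of *x_gc* over *g* in *G_r*
- sd_rc = sample SD (n − 1 denominator)
- cd_rc = sd_rc / mean_rc

CD is computed on the log values as stored — rescaling all values leaves
it unchanged, recentering does not. When |mean| < 1e−8 the ratio is
flagged undefined and the condition is excluded from CD correlations
rather than producing an exploding value.

Targets are defined by the q < 0.001 rule of genome-wide RBP target
compendia, and a regulator is analysed only when *more than 10* targets
survive filtering (at least 11). Self-targets are removed before
counting so a regulator's co-expression with its regulon is never
self-induced. Correlations default to Spearman (average ranks for ties;
exact null distribution for n ≤ 10, asymptotic beyond), two-sided
p-values, with Pearson selectable. Raw per-regulator p-values are
reported; Benjamini–Hochberg adjustment is available but off by default.

The sign pair (rho_mean, rho_cd) classifies each regulator:
`pos_mean_neg_cd` — co-expressed and buffering — is the regime of
interest. A rho of exactly 0 (measure-zero with continuous data) falls
deterministically on the negative side of its axis and flags the
regulator as degenerate.

## Knockout degradation analysis

Degradation efficiency is computed on the raw RPKM scale — the literal
"fraction of expression lost" — while the expression level it is plotted
against is log2 of the deletion-strain value. Negative efficiencies
(targets *higher* in WT) are retained and counted, not floored: removing
them would bias the efficiency–expression correlation upward.

The dispersion contrast reports the CD of target log2 expression in each
strain and tests the difference with a variance-ratio F-test on the same
log values, F = var(KO)/var(WT) with a two-sided p from F(n−1, n−1). An
F-test compares variances, not CDs; the two CDs are reported alongside
so the dispersion change is also seen relative to the mean. Zero WT
variance yields a flagged infinite F at the limiting p of 0.

## The regulation model

Each of 100 target genes *i* follows

d[TG]_i/dt = A_i [TF]^{n_i} / (T_i^{n_i} + [TF]^{n_i}) − k_i [TG]_i − j [RBP] [TG]_i

with [TF] = m·[RBP]. Per-gene parameters are drawn independently and
uniformly over open intervals: tg0 in (0,1), A in (1,2), T in (0,4), n
in (1,4), k in (0,1); the system-level spaces are [RBP] in (0,2), m in
(0,2), j in (0,1). The tg0 < A ordering holds by construction. With
constant TF and RBP the equation is linear and solves exactly:

TG(t) = SS + (tg0 − SS)·e^{−(k + j·rbp)·t}, SS = A·Hill/(k + j·rbp).

The numerical integrator (`deSolve`, lsoda at rtol 1e−10) exists to
validate this closed form — they agree to < 1e−6 after 50 time
constants — and the sweep uses the closed form directly.

**Observation time.** This is the one genuinely open design choice, and
it matters. At steady state the across-gene mean is *increasing in
[RBP] everywhere* in the sampled spaces: the Hill numerator grows at
least like rbp (n > 1 keeps the production elasticity above the
degradation term's), so every (m, j) cell classifies `pos_mean_neg_cd`
and no phase structure exists. The model assigns initial conditions a
parameter space, and initial conditions only matter at finite time —
so the sweep's default evaluates the closed form at t_obs = 0.5 time
units, roughly a quarter of the typical decay timescale (k in (0,1)
gives a median time constant of 2). There, degradation can outpace
production where j is large and m small, and all four sign classes
appear, with `pos_mean_neg_cd` dominating the plane and occupying the
high-m/low-j corner — co-expression with buffering where transcript
generation outweighs RBP-mediated decay, the incoherent-feed-forward-
loop-like regime. Steady-state evaluation (`t_obs = Inf`) remains
available.

Within one replicate, gene kinetics are drawn once and held fixed across
all RBP levels — the regulon is the *same* set of genes observed at
different regulator abundances; redrawing per level would destroy the
within-replicate correlation being measured. RBP levels are an evenly
spaced grid over (0,2) (endpoints excluded). Correlations inside the
model are Pearson by default (continuous, near-monotone relationships;
`cor.test`'s default), Spearman selectable to mirror the expression
pipeline. Replicates with a degenerate (constant) statistic are
discarded and redrawn, with the count reported.

Reproducibility: a master seed is mixed with each cell's grid indices
into an independent per-cell seed, so cells are order-insensitive and a
sub-grid recomputes bit-identically.

**Problem sizes.** The full-scale sweep (100 genes, 1,000 RBP levels,
10,000 replicates per cell) is the model's reference configuration; the
package's tests, analysis scripts and acceptance script run a
desk-scale profile — a 10×10 grid with 200 replicates × 200 RBP levels
— which already resolves the four regions crisply (replicate-averaged
correlations have Monte-Carlo standard errors well under the magnitudes
being classified).

## What the synthetic data emulate

The generators replace the study's external inputs (a 148-profile
RNA-Seq compendium, an RBP target compendium, and a paired WT/deletion
RNA-Seq experiment) with seeded fixtures whose ground truth is known.

**Co-expression fixture.** Regulator log expression R_rc ~ N(mu_r, 1)
across conditions; target log expression

base + base_dev_g + coact·R_rc + scale(R_rc)·(h_g·R_rc + eps_gc)

with scale(R) = 1 − damping·R/max(R). The three knobs are separable:
`coactivation_strength` moves only the regulon mean with the RBP
(rho_mean > 0); `damping_strength` multiplies the across-target
dispersion down as the RBP rises (rho_cd < 0); the per-target gains
h_g ~ N(0, gain_sd) make targets respond heterogeneously to shared
activation, so with damping *off* the dispersion grows with activation
and the planted class flips to `pos_mean_pos_cd` — the contrast the
classifier must distinguish. Defaults (30 RBPs × 15 targets, 300
background genes, 148 conditions, coactivation 0.5, damping 0.8, noise
SD 1 on a log2 scale around level 5 ≈ 32 RPKM) are ordinary magnitudes
for condition-series yeast expression data. Planted targets carry
q < 0.001; each regulator also gets decoy associations at q ≥ 0.001
that the filter must remove.

**Knockout fixture.** KO expression is log-normal (log2 mean 5, SD
1.5); efficiency e_g = min(0.5 + dependence·u_g + noise, 0.95) with u_g
the centred expression rank (centred so the mean efficiency stays at
0.5 whatever the dependence strength); WT = KO·(1 − e_g), so
`degradation_efficiency()` inverts the generator exactly at pseudocount
0. The 0.95 cap keeps WT positive. With `damping = FALSE` the
efficiencies are shuffled across targets: same distribution, no
expression dependence.

**What passing does not show.** The fixtures are log-normal with
homoscedastic condition noise; they do not emulate RNA-Seq count
overdispersion, condition-correlated batch structure, overlapping
regulons, or measurement error in target assignment. Recovery there
demonstrates that the statistics detect the planted structure at
realistic sizes and noise — not that real compendia are this clean.

## Numerical choices and degenerate inputs

- Sample (n − 1) SD throughout, matching `sd()`/`var()`.
- Loaders reject missing cells, duplicate gene ids and negative raw
  values with coordinates named; no imputation, no format sniffing
  beyond the single TSV dialect.
- Constant vectors anywhere a correlation is taken yield flagged
  results (`degenerate = TRUE`, rho = NA), never NaN propagation.
- The across-gene SD inside the sweep uses the sum-of-squares identity
  clamped at zero to guard against cancellation.
- Pipelines validate inputs before creating any output, refuse to
  overwrite unless asked, and write a manifest (parameters + seed) that
  makes deterministic stages bit-reproducible.

## Known limitations

- One TF and one RBP per regulon; no combinatorial regulation, no
  stochastic (Langevin/Gillespie) kinetics, no fitting to real data.
- The four-region classification is a sign rule on averaged
  correlations; cells near a boundary get a hard label however close
  the average is to zero (the per-cell mean correlations are written
  out so boundary proximity can be inspected).
- The variance-ratio test assumes approximate normality of log
  expression among targets; heavy-tailed regulons would call for a
  robust dispersion test.
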