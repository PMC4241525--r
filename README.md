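# rbpregulon

How do RNA-binding proteins (RBPs) coordinate the expression of their
target mRNAs? In budding yeast, most RBPs are *co-expressed* with their
post-transcriptional regulons across conditions, yet at the same time
they *reduce the expression variation* among those targets — the more
regulator, the tighter the regulon. `rbpregulon` implements the full
analysis chain behind that observation for computational biologists who
want to test it, on their own data or against synthetic data with known
ground truth:

- **Co-expression statistics.** For each RBP *r* and condition *c*, the
  mean, SD and coefficient of deviation (CD = SD/mean) of the regulon's
  log expression, and Spearman correlations of each summary with the
  RBP's own expression across conditions. The sign pair
  (ρ_mean, ρ_CD) classifies every RBP into one of four
  regulator–target relationships; `pos_mean_neg_cd` (ρ_mean > 0,
  ρ_CD < 0) is co-expression with buffering.
- **Knockout analysis.** With deletion-strain expression approximating
  a target's level *before* the RBP acts, the per-target degradation
  efficiency e_g = (KO − WT)/KO, its correlation with expression level,
  and a variance-ratio F-test on the CD difference between strains.
- **Regulation model.** Target gene *i* obeys the Hill-kinetics ODE

  d[TG]_i/dt = A_i [TF]^{n_i} / (T_i^{n_i} + [TF]^{n_i}) − k_i [TG]_i − j [RBP] [TG]_i

  with [TF] = m·[RBP]. A Monte-Carlo sweep over the (m, j) plane —
  m the TF:RBP ratio, j the RBP-mediated decay rate — correlates the
  RBP level with the across-gene mean and CD of transcript abundance
  and colors each cell by the sign pair: the four-region phase diagram
  that explains when buffering arises.
- **Synthetic data.** Seeded generators that plant known co-regulation,
  variance damping and expression-biased decay, so the whole pipeline is
  testable end to end without any external download.

## Worked example

The `analysis/` scripts run the three studies in order on generated
inputs and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # fixtures: compendium + knockout pair
Rscript analysis/02_coexpression.R    # per-RBP summaries -> classification
Rscript analysis/03_knockout.R        # degradation efficiency + CD contrast
Rscript analysis/04_phase_diagram.R   # (m, j) Monte-Carlo sweep
```

Output of stage 2 (30 planted regulons, 148 conditions):

```
30 regulators analysed over 148 conditions
fraction buffering (pos_mean_neg_cd): 1.000
planted-class recovery: 100.0%
```

Every planted variance-damped regulon is recovered as co-expressed and
buffering: its RBP's expression correlates positively with the regulon
mean and negatively with the regulon CD. Stage 3, on a 200-target
knockout pair with expression-biased decay:

```
efficiency vs KO expression: spearman rho = 0.979 (p = 8.67e-139)
CD of target log2 expression: WT 0.150 vs KO 0.262
variance-ratio F(199,199) = 5.17, two-sided p = 0
```

Degradation efficiency rises with expression level, and deleting the
RBP inflates the dispersion among its targets (higher CD in the KO
strain; the two-sided p underflows at this effect size). Stage 4:

```
region composition of the 10x10 grid:
neg_mean_neg_cd neg_mean_pos_cd pos_mean_neg_cd pos_mean_pos_cd
             11              15              73               1
high-m/low-j corner (m=1.90, j=0.050): pos_mean_neg_cd (rho_mean=0.98, rho_cd=-0.99)
```

All four relationships appear on the (m, j) plane; buffering dominates
(73% of cells) and owns the corner where transcript generation by the
TF outweighs degradation by the RBP — the regime analogous to an
incoherent feed-forward loop.

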