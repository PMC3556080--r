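---
title: "Scoring siRNA sensitization screens and knockdown expression consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring siRNA sensitization screens and knockdown expression consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensiscreen)
```

## The design and the model

An arrayed drug-modifier screen asks, gene by gene, whether RNAi
silencing changes a cell line's sensitivity to a drug. Each library gene
is represented by siRNA wells (a pool of four duplexes in the primary
screen, individual duplexes in deconvolution) on paired plates: one plate
receives vehicle, its partner the drug. Each plate also carries wells
transfected with a non-targeting control siRNA (GL2, against firefly
luciferase), which measure the plate's own baseline.

The measurement model behind both the scoring and the simulator is
multiplicative:

$$\mathrm{raw} = \mu \cdot \pi_{plate} \cdot \gamma_{gene} \cdot
  \iota_{drug \times gene} \cdot \varepsilon$$

with $\pi_{plate}$ a factor shared by *all* wells of a plate (batch,
reagent, reader drift), $\gamma_{gene}$ the drug-independent viability
cost of the knockdown, $\iota$ the drug–gene interaction (only in the
drug arm of true sensitizers), and $\varepsilon$ lognormal — viability
fluorescence is positive and right-skewed, and a multiplicative error
keeps every downstream ratio scale-free.

Normalizing each well by the median GL2 value of its own plate cancels
$\pi_{plate}$ exactly; this is a property the test suite asserts
(multiplying any plate by any constant changes no SI, p-value or hit
call). The **sensitization index**

$$SI_g = \frac{\overline{V_g^{drug}/GL2^{drug}}}
              {\overline{V_g^{vehicle}/GL2^{vehicle}}}$$

also cancels $\gamma_{gene}$, isolating the interaction: $SI < 1$ is
sensitization, $SI = 1$ no interaction. Replicate wells are summarized by
the arithmetic mean of normalized viabilities before the ratio (the
per-well-normalize-then-summarize convention of plate-screen tooling); a
geometric-mean summary is available via `summary = "geometric"` since the
two differ under multiplicative noise, though negligibly at the noise
levels typical of a passing assay.

## Hit calling: a dual gate

Hits must clear two independent gates, and both inequalities are strict:

* **statistical** — the drug-arm coefficient of a per-gene linear model
  on log2 normalized viability, BH-adjusted across the genes of the
  screen, below `fdr_threshold` (default 0.15);
* **biological** — SI below `si_threshold` (default 0.85, i.e. a > 15%
  viability decrease under drug relative to vehicle).

The linear model with a single arm indicator is exactly the two-sample
pooled-variance t-test on log2 values; `score_screen(moderate = TRUE)`
(the default) additionally shrinks per-gene residual variances toward a
common prior (`limma::squeezeVar`), which stabilizes the test when each
gene has only a few replicate wells. Two-sided p-values are used
throughout: directionality is enforced by the SI gate, not the test.

Deconvolution validation re-screens hits with their four individual
duplexes and requires at least 2 of 4 to independently meet the same dual
criterion — the classic guard against off-target pool artifacts. Genes
screened with fewer duplexes are evaluated against the available count,
with a warning. For multi-drug specificity panels,
`drug_specificity_matrix()` assembles the gene × drug SI matrix and
per-drug sensitizer counts; when the "best two duplexes" of each gene are
re-pooled for such panels, `best_sirnas()` selects the two with the
lowest primary-screen SI, ties broken by duplex id, and returns the
selection explicitly so it can be kept with the run provenance — one
defensible reading of a convention the field leaves unstated.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `si_threshold` | 0.85 | biological gate on SI (dimensionless ratio) |
| `fdr_threshold` | 0.15 | statistical gate on BH-adjusted p |
| `min_confirming_sirnas` | 2 of 4 | deconvolution validation rule |
| `moderate` | `TRUE` | empirical-Bayes variance moderation |
| `summary` | `"mean"` | replicate summary inside the SI |
| Z′ gate | 0.5 | assay-window QC threshold |

## The expression arm

After validation, each hit gene is silenced individually and profiled.
With very few control samples (two is typical), gene-wise significance
testing is underpowered, so the analysis leans on effect sizes:

* `compute_logfc()` — per-sample log2 fold change against the
  *arithmetic mean of the control samples* on the log2 scale;
* `universal_change_genes()` — an **intersection** criterion: a gene
  counts only if it passes |log2FC| ≥ 1 (a halving or doubling) in
  *every* knockdown sample. This is deliberately conservative: under
  residual noise of sd 0.3 the chance a null gene passes in all 14
  samples is astronomically small, so the emitted lists need no further
  correction. A reporting tier (mean < −1.5) marks the strongest
  consensus genes, and a near-threshold flag (consistent sign in all
  samples, |mean| ≥ 0.85) surfaces borderline genes such as a
  consistently −0.9-shifted gene that the hard cutoff would hide — it is
  a reporting convenience, not a discovery criterion, and 0.85 was chosen
  so such a gene is caught while sign-consistent noise (which at sd 0.3
  has |mean| far below 0.85) is not;
* `pooled_t_statistics()` — per-gene two-sample t with pooled variance
  (df = n_kd + n_controls − 2), the input to gene-set testing;
* `gene_set_rank_test()` — Wilcoxon rank-sum of a set's t-statistics
  against all other genes'. Cytogenetic-band sets come from
  `region_sets_from_cytoband()`, which collapses sub-bands to the major
  band (19q13.1, 19q13.2 → "19q13") because regional signals are reported
  at that resolution; sub-band sets are a flag away. Curated pathway
  collections are consumed as GMT. Regions and pathways are
  Bonferroni-corrected as *separate* families, since they are reported
  separately.

## Numerical choices

* **Rank-sum p-values.** Exact null distribution (`pwilcox`) whenever
  both the set and its complement have fewer than 50 members and the
  statistics are tie-free; otherwise the normal approximation with tie
  and continuity corrections. The normal tail is off by orders of
  magnitude for extreme small sets (for the 5 top-ranked genes of 50 the
  exact two-sided p is 2/C(50,5) ≈ 9.4 × 10⁻⁷ versus ≈ 5 × 10⁻⁴
  approximate), and the exact path matches full subset enumeration to
  machine precision.
* **Zero-variance cells.** A noiseless gene with identical arms gets
  p = 1 (not NaN); a noiseless gene with a real planted effect gets
  p → 0. The boundary between "identical" and "effect" is |coef| <
  10⁻⁸ on the log2 scale, so floating-point round-off from rescaling
  never manufactures significance.
* **Insufficient replication** (< 2 wells per arm) conservatively yields
  p = 1 with a warning rather than an error, so one bad gene cannot
  abort a screen.
* **Ties and degenerate sets.** A gene set covering every measured gene
  has no complement and is returned with p = 1 and a warning; undersized
  sets are skipped and listed.
* **Seeds.** Every simulator refuses to run without one; identical seeds
  give bit-identical outputs, and pipeline manifests record them.

## What the simulator does and does not emulate

`simulate_screen()` reproduces the screen geometry (a 53-gene library
with 4 duplexes per gene, 5 GL2 wells per plate, paired vehicle/drug
plates, 3 replicate wells per gene and condition — the replicate count is
a parameter, as published layouts rarely state it), multiplicative plate
effects shared with control wells, per-duplex knockdown efficacies
(linear attenuation of the interaction factor; a pool's efficacy is the
maximum over its duplexes), and lognormal measurement noise.
`simulate_expression()` reproduces the expression geometry (22,011 genes
× 14 knockdowns + 2 controls by default) with planted universal shifts,
band-coordinated regional shifts over a synthetic ISCN-style band
universe, and Gaussian residuals.

Not emulated: spatial within-plate artifacts (edge effects, gradients),
transfection-efficiency drift between plates beyond the scalar plate
factor, probe-level microarray noise and normalization residue,
correlated off-target signatures shared between duplexes, and
knockdown-induced secondary regulation (every non-planted gene is null).
Passing tests therefore certify the *scoring machinery* — normalization
cancels what it claims to cancel, planted truth is recovered, error
rates hold under the stated noise model — not robustness to artifacts the
model excludes; on real plates the Z′ gate and the design report are the
first line of defense.

## Problem sizes and operating characteristics

The acceptance checks run 100 simulated screens (53 genes, 37 planted
sensitizers at interaction factor 0.7, lognormal σ = 0.1) and verify
recall ≥ 0.9 of planted sensitizers with empirical FDR among called hits
within its nominal 0.15; and 100 simulated expression datasets at 5,000
genes (the generator's 22,011-gene default is unnecessary for measuring
estimator bias, and 5,000 keeps the hundred-seed loops brisk), verifying
that seed-averaged recovery of planted shifts (−2.2 / −1.65 / +1.33,
σ = 0.3) is within ±0.05 and that a single +0.4 regional shift ranks its
band first in at least 95 of 100 seeds. A per-seed shift estimate has
sampling sd ≈ 0.23 under these conditions (14 knockdowns sharing a
2-sample control baseline), so ±0.05 is a statement about bias across
seeds, not single-dataset error.

## Known limitations

* Vehicle/drug plate pairing falls back to plate order when no explicit
  `pair_id` column is present; explicit pairing always wins and is
  recommended.
* The consensus stage assumes the expression matrix is already
  normalized and gene-summarized (e.g. RMA); no probe-level processing
  is attempted.
* With only two control samples the pooled-t ranks are dominated by the
  knockdown-side variance; the gene-set stage inherits this and is best
  read as a ranking, which is how the Bonferroni-corrected report
  presents it.
* The near-threshold flag is descriptive; genes it marks should be
  confirmed orthogonally (e.g. qRT-PCR) before any claim.
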