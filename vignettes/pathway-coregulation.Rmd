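---
title: "Scoring coordinated pathway regulation in miRNA perturbation screens"
author: "pathcoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring coordinated pathway regulation in miRNA perturbation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcoreg)
```

## The problem

A miRNA gain-of-function screen transfects hundreds of miRNA mimics, one per
well, into a cell line and reads out the abundance of a few dozen proteins by
reverse-phase protein array (RPPA). Individual miRNA effects on proteins are
typically mild (fractions of a log2 unit), yet a miRNA that nudges *many*
proteins of one signalling pathway in a functionally coherent direction can
still reprogram that pathway. `pathcoreg` quantifies exactly this: it turns
per-protein differential effects into a per-miRNA, per-pathway **Pathway
Coregulatory (PC) score** and attaches a resampling-based empirical FDR to
it.

## From spots to effects

Raw data are spot-level antibody intensities with a per-spot total-protein
estimate. Two preprocessing steps are applied by `normalizeSignals()`:

1. **Total-protein normalization** — each signal is divided by its spot's
   total-protein value, removing loading differences.
2. **Block correction** — slides are printed in blocks (spotting groups);
   per antibody, each block's values are shifted additively so the block
   median equals the antibody's overall median. With one block the shift is
   identically zero, and the correction is idempotent.

`differentialEffects()` then contrasts, within each transfection round, the
log2 signals of each miRNA's biological replicates against the pooled
samples of the two distinct mimic negative controls. Technical spot
replicates are averaged per biological sample first, so the test operates on
sample-level values. Two tests are available:

* **Moderated t (default).** Per round, each protein's residual variance
  $s_p^2$ (pooled across all conditions, $d_p$ degrees of freedom) is shrunk
  towards a prior: $\tilde s_p^2 = (d_0 s_0^2 + d_p s_p^2)/(d_0 + d_p)$,
  with $(d_0, s_0^2)$ estimated by method of moments under the scaled-F
  model $s^2 \sim s_0^2 F_{d, d_0}$ from the observed per-protein variance
  distribution. The t statistic uses $d_0 + d_p$ degrees of freedom. When
  the observed variance dispersion is no larger than sampling noise predicts
  ($\mathrm{cv}^2 d \le 2$), the prior is taken as infinitely informative
  and every protein uses the pooled variance. The moderation matters because
  each contrast has only 2 miRNA vs 4 control samples.
* **Welch t** — a per-pair unequal-variance fallback with Satterthwaite
  degrees of freedom, useful when the common-variance-per-protein assumption
  is suspect.

Multiple testing uses Benjamini–Hochberg across all (miRNA, protein) pairs
in the dataset (one experiment-wide family, matching a single dataset-wide
q threshold); per-protein correction is available via `bhScope`. The default
per-interaction significance threshold is $q \le 0.001$.

Edge policies: non-positive normalized signals are set missing rather than
clipped (no fabricated fold changes); a pair with fewer than two usable
observations on either side is flagged `missing`; a zero-standard-error pair
is reported at $p = 1$ rather than undefined; pooling of the two control
kinds is the default reading of the two-negative-controls design, with a
per-control contrast (Stouffer-combined) behind `controlPooling`.

## The PC score

A curated annotation assigns each measured protein a role per pathway:
**activator** or **repressor** of the pathway's output. A significant effect
of miRNA $m$ on protein $t$ (at $q \le 0.001$) becomes a signed *pathway
effect* $e_{mt}$:

| protein effect | activator | repressor |
|---|---|---|
| downregulated | $-1$ | $+1$ |
| upregulated | $+1$ | $-1$ |

Non-significant or missing pairs contribute $0$. The PC score is the
measurement-weighted sum

$$\mathrm{PC}(m, P) \;=\; \frac{\sum_{t \in P} e_{mt}}{\#\{t \in P:\ t
\text{ measured for } m\}} \;\in\; [-1, +1],$$

so $-1$ is a miRNA that pushes every measured protein of the pathway in the
repressive direction. Effects enter as signs, not magnitudes, because the
transformation is categorical (a mild but coherent push counts the same as a
strong one); a magnitude-weighted variant (signed $|\log_2\mathrm{FC}|$) is
available via `weighting = "magnitude"`. The denominator counts proteins
actually measured for that miRNA, so missingness shrinks the denominator
rather than diluting the score.

## Resampling null and empirical FDR

Observed scores are compared with scores from `B = 10000` resampling
rounds. Independently for each protein column, the column's significant
effects are reassigned to miRNAs drawn uniformly without replacement from
the full library, preserving the column's multiset of up/down effects —
i.e. the null keeps each protein's marginal regulation profile and breaks
only the coordination across proteins within a miRNA. An alternative that
pools direction (preserving only the per-protein interaction count,
redrawing signs from the column's empirical frequencies) sits behind
`directionPooled`.

Each miRNA is tested against its own null sample with the two-sided
add-one empirical p-value
$p = \bigl(1 + \#\{b: |\mathrm{PC}^{null}_b| \ge |\mathrm{PC}^{obs}|\}\bigr)/(B+1)$,
which is never zero and is exact under the permutation distribution.
Benjamini–Hochberg runs across miRNAs *within* each pathway (each pathway
is read as its own family; the distributions differ strongly with the
pathway's role composition), and miRNAs at $q \le 0.05$ are classified by
score sign: negative = pathway **repressor**, positive = **activator**.
The permutation stream is driven by one seeded RNG with miRNAs and proteins
processed in sorted order, so results are reproducible across platforms.

## What the synthetic generator emulates

`simulateScreen()` produces screens with the structure the analysis
assumes, plus ground truth, so every stage is testable without external
data. Defaults (see `simConfig()`):

* **Library and panel.** 200 miRNAs against three pathways with role
  compositions WNT 7 activators + 7 repressors, MET 14 + 3, ITG 18 + 3 —
  one balanced pathway and two repressor-poor ones, the qualitative
  imbalance this kind of curated panel shows. (The generator scales to
  ~800 x 62 if asked.)
* **Design.** Two biological replicates per miRNA; two distinct negative
  controls with two replicates each; lysates printed in technical
  triplicate spots; four spotting blocks with multiplicative
  per-(block, antibody) offsets (log2 s.d. 0.1); log-normal per-protein
  baselines around $2^{10}$; per-spot total-protein factors log-normal
  (sdlog 0.15); 2% spot-level missingness.
* **Noise.** Gaussian on the log2 scale per spot, s.d. 0.25. Averaging the
  triplicate spots gives sample-level noise of $0.25/\sqrt{3} \approx 0.14$,
  which is what makes mild planted effects detectable at $q \le 0.001$ with
  a 2-vs-4 contrast — the same role triplicate printing plays on real
  arrays.
* **Planted signal.** Five planted regulator miRNAs per pathway, each
  perturbing 80% of the pathway's proteins role-consistently; true protein
  downregulations average $-0.54$ log2FC and upregulations $+0.49$
  (s.d. 0.1). The default `mixed` planting uses a 4:1 repress:activate
  split; combined with the role composition above this reproduces the
  roughly 2:1 down:up imbalance of significant effects such screens report.

What it does **not** emulate: spatial spot geometry and scanner artifacts,
dilution series, antibody cross-reactivity, heavy-tailed or correlated
noise, and miRNAs with diffuse off-pathway activity. Passing tests
therefore certify the statistical machinery under a well-specified
generative model, not robustness to every failure mode of real arrays.

A note on reading census numbers: the mean of *significant* log2FCs is
selection-biased away from zero relative to the planted truth (only effects
that clear a stringent threshold are averaged), so the reported mean
significant downregulation is somewhat stronger than the planted $-0.54$.
This is a property of thresholded summaries, not a generator error.

## Test and acceptance problem sizes

The packaged checks run the scoring oracles exactly (sign rules, score
formula, BH step-up, Fisher hypergeometric, all to closed form), compare
Monte-Carlo empirical p-values with exhaustive enumeration on instances of
up to 6 miRNAs x 3 proteins at $B = 10{,}000$ (3 binomial s.e. tolerance),
and exercise the full pipeline over 20 seeded screens at the default
conditions for both null calibration (no planted signal; classification
rate vs the 5% FDR level) and planted-repressor recovery (target: at least
90% recovered). The acceptance script repeats the end-to-end run and
reports census, recovery and calibration quantities from 10 replicate
screens.

## Known limitations

* Roles are binary per (protein, pathway); context-dependent proteins are
  not representable, mirroring the one-role-per-pair curation the score
  expects.
* The score treats the pathway as a flat signed membership, not a wired
  graph: no propagation, no epistasis.
* With very few measured proteins the score is coarse (steps of
  $1/n_\mathrm{measured}$) and the resampling null is discrete; empirical
  p-values are then conservative by construction.
* The moderated test assumes a common residual variance per protein within
  a round; gross heteroscedasticity across conditions favours
  `method = "welch"`.
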