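# pathcoreg

Pathway coregulation scoring for miRNA gain-of-function protein screens.

miRNAs individually fine-tune protein abundance — typical effects in a
reverse-phase protein array (RPPA) screen sit around half a log2 unit — yet
a single miRNA can still switch a signalling pathway by nudging many of the
pathway's proteins in a functionally coherent direction. `pathcoreg` is for
analysts of such screens: it takes spot-level RPPA intensities (or a
pre-computed miRNA x protein effect table) plus a curated
activator/repressor pathway annotation, and identifies the miRNAs that
coordinately repress or activate each pathway.

## The score

Each significant protein effect (Benjamini–Hochberg q ≤ 0.001 versus pooled
mimic negative controls) is mapped to a signed pathway effect using the
protein's role: down(activator) → −1, down(repressor) → +1, up(activator)
→ +1, up(repressor) → −1. The **Pathway Coregulatory (PC) score** of miRNA
*m* on pathway *P* is

    PC(m, P) = Σ_{t ∈ P} e_mt / #{t ∈ P measured for m}   ∈ [−1, +1]

Significance comes from a resampling null: each protein column's
significant effects are reassigned 10,000x to random miRNAs (preserving
per-protein up/down counts), each miRNA's observed score is tested against
its own null with a two-sided add-one empirical p-value, and BH at 5% FDR
within each pathway classifies miRNAs as pathway *repressors* (negative
score) or *activators* (positive score).

The package also includes the surrounding analyses — spot normalization and
block correction, an empirical-Bayes moderated t (Welch fallback) for the
miRNA-vs-controls contrasts, screen census summaries, predicted
binding-site enrichment (Fisher exact per protein and direction), 3'UTR
length vs regulation-count correlation — and a synthetic-screen generator
with ground truth that makes the whole pipeline testable end to end.

## Worked example

```r
library(pathcoreg)

sim <- simulateScreen(simConfig(seed = 42))        # 200 miRNAs, 52 proteins, 3 pathways
et  <- differentialEffects(normalizeSignals(sim$signals))
cs  <- summarizeEffects(et)
res <- pcScore(et, sim$annotation, B = 10000, seed = 7)
```

The census reports mild, downregulation-skewed significant effects:

    significant: 76 of 10400 pairs (55 down / 21 up), mean down -0.69, mean up 0.70

`pcScore()` classifies each (miRNA, pathway); here 13 of the 15 planted
regulators are recovered with no false positives among the 585 unplanted
pairs:

          activator none repressor
      ITG         1  195         4
      MET         0  196         4
      WNT         0  196         4

       mirna pathway      score     p_emp    qvalue classification
     mir0065     WNT -0.5000000 9.999e-05 0.0049995      repressor
     mir0047     MET -0.4117647 9.999e-05 0.0049995      repressor
     mir0128     MET -0.4117647 9.999e-05 0.0049995      repressor

A score of −0.5 means the miRNA pushed half of the pathway's measured
proteins in the repressive direction (and none the other way); p_emp =
1/(B+1) is the resolution floor of the 10,000-round null.
`recoveryReport(res, sim$truth$classes)` and `overlapSummary(res)` give
per-pathway sensitivity/specificity against the generator's ground truth
and the cross-pathway Venn counts.

Real data enter through `readRawSignals()` (spot-level TSV with a column
mapping), `readEffectTable()` (pre-computed long-format effects),
`readPathwayAnnotation()` and `readPredictionSet()`.

## See also

The vignette (`vignettes/pathway-coregulation.Rmd`) documents the model,
its assumptions, the generator's design and the package's numerical
choices.
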