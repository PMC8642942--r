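Package: pathcoreg
Title: Pathway Coregulation Scoring for miRNA Perturbation Protein Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of miRNA gain-of-function reverse-phase protein array
    (RPPA) screens. Normalizes spot-level antibody signals to total protein
    and removes spotting-block effects, tests each miRNA against pooled mimic
    negative controls with an empirical-Bayes moderated t (Welch fallback) and
    Benjamini-Hochberg correction, and converts significant protein effects
    into signed pathway effects using a curated activator/repressor
    annotation. The per-miRNA Pathway Coregulatory (PC) score summarizes the
    coordinated effect of a miRNA on a pathway; significance is assessed
    against a per-protein resampling null with an empirical FDR. Includes
    predicted binding-site enrichment and 3'UTR-length correlation analyses,
    and a synthetic-screen generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, Normalization, Pathways, Network, DifferentialExpression
RoxygenNote: 7.3.3
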