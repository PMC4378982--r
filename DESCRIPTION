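Package: luxseq
Title: Light-Induction Genomics: Replicate-Free Differential Expression,
    Poisson Peak Calling, Nucleosome Mapping and Motif Spacing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated re-usable pipeline for dissecting light-induced
    transcription and chromatin dynamics in fungal genomes. Implements a
    replicate-free negative-binomial exact test for differential expression
    with median-of-ratios normalization and a blind mean-variance fit; a
    sliding-window Poisson ChIP-seq peak caller with enrichment filtering
    and strand-aware peak-to-gene annotation; an MNase-seq
    nucleosome-occupancy pipeline (fragment classification, midpoint
    coverage, percentile normalization, kernel smoothing, +1 nucleosome
    location, metagene profiles, repeat-length estimation, footprint
    profiles); prediction-interval classification of light-regulated
    binding sites; and tandem-motif spacing analysis. Ships a synthetic
    data generator that plants recorded ground truth (induced genes,
    binding sites, phased nucleosome arrays, footprints, motifs) so every
    stage can be validated end-to-end, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
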