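Package: slimscan
Title: Short Linear Motif Scanning with PSSM Scoring and Target-Decoy Enrichment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline prediction of short linear motifs (SLiMs) in protein
    sequences. Compiles ELM-style regular-expression motif patterns with
    capturing groups, scans FASTA proteomes for matches with configurable
    flanks and overlap handling, scores matches on a normalized 0-100 scale
    with a position-specific scoring matrix (PSSM) trained from aligned motif
    instances, and estimates match significance with a target-decoy approach:
    decoy proteomes are built by residue shuffling that preserves protein
    lengths, global composition, the initial methionine and, optionally, the
    composition of intrinsically disordered regions. Includes enrichment
    statistics (two-proportion tests, Benjamini-Hochberg correction,
    enriched/depleted calls, ratio-versus-score-threshold curves), analytical
    pattern-match probabilities under a background residue model, annotation
    of matches with post-translational modification sites (PhosphoSitePlus
    and dbPTM table dialects), disordered-region overlap and generic sequence
    features, auxiliary-motif co-search, a synthetic-data generator for all
    input types, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
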