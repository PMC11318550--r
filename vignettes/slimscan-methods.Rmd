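---
title: "slimscan: statistical methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slimscan: statistical methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `slimscan`, the
choices that were genuinely open when the package was designed, and the
limits of what its synthetic-data tests demonstrate.

## The problem

Short linear motifs (SLiMs) are described by permissive regular expressions:
a typical pattern matches once every few hundred residues of random
sequence, so a proteome-scale search returns thousands of hits of which very
few are functional. `slimscan` layers three orthogonal kinds of evidence on
top of the raw pattern match: a position-specific score (how much does this
particular match resemble known instances), a target–decoy comparison (does
this motif match the real dataset more often than a randomized one), and
biological context (modification sites, disorder, a co-occurring second
motif).

## The supported pattern subset

Patterns may use literals, character classes (with negation and ranges),
`.`, bounded quantifiers `{m}`, `{m,n}`, `?`, non-nested capturing groups
and top-level alternation. Unbounded `*`/`+`, look-around and
backreferences are rejected at compile time. The restriction is deliberate:
every construct in the subset admits an exact match probability and a
finite set of length expansions, which the probability calculator and the
PSSM normalization rely on. ELM-class patterns fall almost entirely inside
this subset.

Two normalizations are applied at compile time and are visible in
`slim_motif$compiled`:

* `.` becomes the explicit 20-residue class, and negated classes are
  resolved to their complement within the 20 standard residues. As a
  consequence non-standard residues (X, U, B, Z) never match any pattern
  position. This is the safe default for scanning translated or annotated
  sequences containing placeholder residues.
* Matching at a given start position is greedy (leftmost-greedy PCRE
  semantics). For variable-length patterns this fixes which span is
  reported, making match counts reproducible run to run.

With `overlapping = TRUE` (default) a match attempt is made at every start
position; with `FALSE` scanning resumes after each match end. Overlapping
is the default because SLiM instances can overlap and because the
per-position match count is what the analytical probability predicts; both
modes are exposed.

## Pattern probability

For an i.i.d. background `b` over the 20 residues, the probability that the
pattern matches at a fixed position is computed as a sum over all bounded
quantifier expansions of the product of per-position class probabilities
(the class probability is the sum of `b` over its members; `.` contributes
1). Sums over expansions are taken **without** inclusion–exclusion, so for
patterns whose expansions overlap the value can exceed the true union
probability (and a warning is emitted when it exceeds 1). This convention
was chosen because it is the one used by ELM-style pattern probabilities,
which this calculator is meant to be comparable with. The calculator takes
the background as a parameter (presets: uniform 1/20 and an average
Swiss-Prot composition) rather than fixing one convention.

For the seven-group phospho-acceptor pattern
`(.)(.)([^IRFW])([ST])([ILMVFWY])([ILMVFWY])(.)` under a uniform
background the value is `(16/20)(2/20)(7/20)(7/20) = 0.0098` — note that
`[ILMVFWY]` has seven members; this number is verified in the test suite
both in closed form and against the Monte-Carlo match frequency on i.i.d.
sequences.

## PSSM training and scoring

One PSSM column per capturing group. For group `g` and residue `a`, the
training count `c(g,a)` adds `1/len` for each occurrence of `a` inside
group `g` of an instance, where `len` is that group's length in that
instance — each instance contributes exactly one unit of mass per non-empty
column, so variable-length groups do not outweigh fixed ones. Smoothed
frequencies `f = (c + k)/(Σc + 20k)` (Laplace pseudocount `k`, default 1 —
training sets for motifs without a gold standard are small and need
smoothing) become weights `w = log2(f / b)`.

A match's raw score is the sum over groups of the *mean* weight of the
residues in the group (the scoring-side counterpart of the `1/len`
training weighting); empty groups contribute 0 and residues outside the
alphabet score the column minimum rather than erroring. Reported scores
are `100 (S - s_min) / (s_max - s_min)` clipped to `[0, 100]`, where
`s_min`/`s_max` are the raw-score extrema over residues admissible under
each group's character class. Restricting the extrema to the class (rather
than all 20 residues) makes 100 attainable by a real pattern-compatible
sequence — the per-column argmax "consensus" scores exactly 100 — and was
preferred over normalizing by the observed score range, which would make
scores dataset-dependent. If every training instance realizes identical
per-column residue sets the range degenerates (`s_min = s_max`); the
trainer then warns and scores are reported as `NA`.

Two properties of this scheme are worth stating explicitly:

* Training is invariant to instance order. It is *not* invariant to
  duplicating every instance with a fixed pseudocount — the smoothing
  fraction shrinks as counts grow, by design. Duplication together with a
  proportionally scaled pseudocount reproduces the PSSM exactly, and that
  is the form the test suite asserts.
* Recovery of a generating distribution is measured on the
  maximum-likelihood column frequencies (`pssm$counts` normalized), not on
  the smoothed `f`: the pseudocount is a deliberate bias toward uniform
  that contributes ~0.017 L1 per column at 2,000 instances (17 empty cells
  × 1/2020 plus shrinkage of the support) and does not vanish at that
  sample size. The acceptance test requires the *median over five
  2,000-instance replicates* of the worst-column L1 to stay below 0.05;
  a single replicate's worst column exceeds 0.05 in roughly 15% of draws
  from sampling variation alone, so the median is the robust form of the
  convergence claim.

## Decoy generation

A decoy record is a per-protein permutation of the target record: length
and residue multiset are conserved exactly, and position 1 is held fixed
(default) so that the near-universal initial methionine is neither a
spurious depletion nor an enrichment signal for Met-anchored motifs. In
`preserve_idr` mode the sequence is cut at the boundaries of annotated
disordered intervals and each segment — disordered and ordered alike — is
shuffled within itself before re-concatenation, conserving per-segment
composition exactly. This matters because IDRs are compositionally biased
(polar/proline rich); a whole-sequence shuffle redistributes that bias and
can distort the chance-match rate of disorder-favoured motifs. Where an
annotated IDR starts at position 1, position 1 is still held fixed, so the
first-residue guarantee is unconditional. "Shuffle the annotated regions
separately" could also be read as pooling all IDR residues of a protein
before redistributing them across IDR segments; the per-segment reading is
implemented because it is strictly stronger (it implies the pooled
composition is preserved), and the pooled variant is not built.

Each decoy run consumes one seeded RNG stream in dataset order, the seed is
recorded on the output, and decoy accessions get a `decoy_` prefix so they
cannot accidentally join against real PTM or feature tables.

## Enrichment statistics

The per-motif enrichment ratio is
`(n_target / aa_target) / (n_decoy / aa_decoy)`. Counts are normalized by
dataset size *in residues*: the number of scanned positions is the natural
exposure, it is the same unit used to compare datasets of different sizes,
and for a matched target/decoy pair it cancels exactly. (Protein counts
would be an alternative denominator; residues were chosen because match
opportunities scale with sequence length, not protein number.)

Significance uses the pooled two-proportion z-test with the residue counts
as trials, two-sided; degenerate tables (both proportions 0 or both 1)
return p = 1. The z-test is the right tool in the intended regime of large
counts; Fisher's exact test is exposed as an option for small-count
tables. p-values are corrected with Benjamini–Hochberg across all motifs
in the table — the family is defined explicitly as "one enrichment table"
to avoid silently changing the correction scope. A motif is called
*enriched* iff ratio ≥ 2 and q ≤ 0.05, *depleted* iff ratio ≤ 0.5 and
q ≤ 0.05, else *non-significant*.

When a count is zero the ratio uses a Haldane-style continuity correction
(+0.5 to both counts, flagged in the output) so that log-ratio plots remain
finite; the p-value always uses the untouched counts. Ratio-versus-score
curves (`ratio_curve`) apply the same conventions at each threshold.

Overlapping matches of a motif are mildly positively correlated, so the
z-test's independence assumption is approximate; for the enriched/depleted
calls this is immaterial because the ratio threshold of 2 dominates the
decision at realistic counts.

## PTM, IDR and auxiliary annotation

All containment tests use 1-based inclusive coordinates (UniProt
convention): a site at the first or last residue of a span is connected.
PhosphoSitePlus-dialect tables are parsed with their non-tabular preamble
tolerated and `MOD_RSD` suffixes decoded; ambiguous sites (peptides
matching multiple proteins) are dropped by default since they cannot be
assigned to a position with confidence. dbPTM-dialect tables can be
validated against a proteome: chemically implausible entries (e.g.
phosphorylation recorded on alanine) and out-of-bounds positions are
*flagged but kept* by default — the tables document the issue, not a
removal policy — with a `strict` switch to drop them.

The "filter without connections" rule keeps only matches with a site of
the requested modification inside the scope span. The default scope is the
whole match; a capturing-group scope exists because modified-residue
motifs have a defined acceptor group, and for fixed-length patterns the
group scope makes the connection test positionally exact (a site can only
connect to the one match whose acceptor sits on it).

Auxiliary co-search annotates every primary match with whether its protein
contains at least one auxiliary-motif match at or above a score threshold,
plus the count and best score. It is protein-level by design: the
biological rationale (e.g. an NLS supporting NES candidates) is about the
protein carrying both motifs, not about their relative positions.

## The synthetic-data generator

`synth_proteome` draws i.i.d. residues from a chosen composition (uniform
or Swiss-Prot-like), with a deterministic initial methionine to exercise
the decoy first-residue rule. `plant_motifs` overwrites uniformly chosen,
non-overlapping spans (never covering position 1) with sampled
pattern-compatible instances and returns a ground-truth table.
`synth_ptm_table` places sites on planted acceptor positions with a given
coverage plus Poisson-distributed spurious sites, emitted in the PSP
dialect; `synth_idr_annotations` tiles sequences with
geometric-gap/Poisson-length disordered intervals whose expected coverage
equals the requested fraction. Everything is byte-reproducible from a
seed, and every generated file parses through the package's own loaders.

What the generator does **not** emulate: homology and repeat structure,
composition heterogeneity along sequences (real IDRs are compositionally
biased, synthetic ones are not), clustered or sequence-context-dependent
PTMs, and realistic disorder prediction. Tests passing on this generator
therefore demonstrate the correctness and calibration of the machinery
under its stated model — not that any particular biological motif will be
detected in real data.

## Test and acceptance problem sizes

The test suite runs entirely on generated data at sizes chosen to make the
statistical assertions sharp while staying desk-scale: scan/oracle
equivalence on 500 random sequences (30–200 aa) crossed with 50 random
patterns; probability calibration on ~1.04 million scanned positions
(2,600 proteins × 400 aa) with ten fixed-length patterns whose consecutive
classes are disjoint (so self-overlap cannot inflate the count variance),
asserting agreement within 4 standard errors; null calibration on 100
motif/table draws over five 300-protein proteome/decoy pairs (call rate
≤ 7.5% at q ≤ 0.05, total count ratio within [0.98, 1.02]); planted-motif
power with a 7-mer consensus in 50% of 500 length-400 proteins across 20
seeds (≥ 95% enriched calls); PSSM recovery at 2,000 instances as
described above; and end-to-end PTM and auxiliary-motif workflows at
250–400 proteins. `scripts/acceptance.R` recomputes the same quantities
from scratch for any seed.

## Known limitations

* The regex subset excludes unbounded quantifiers; motifs that genuinely
  need them (rare in ELM) must be rewritten with an explicit upper bound.
* Alternation is top-level only and groups cannot nest; a pattern needing
  per-group alternation must push the alternatives into character classes
  or separate motifs.
* Pattern probabilities are i.i.d.-background quantities; no Markov or
  positional composition models.
* The score normalization uses the theoretical class-restricted range;
  scores are comparable across datasets for a fixed PSSM but not across
  different PSSMs.
* Single-decoy design: uncertainty from decoy randomness is addressed by
  rerunning with different seeds, not by permutation p-values.
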