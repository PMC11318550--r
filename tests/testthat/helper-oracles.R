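# Shared oracles and small fixture builders.

AAs <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Brute-force scan oracle: anchor the compiled pattern at every start
# position independently. This is the reference semantics scan_motif() must
# reproduce ("a match attempt at every position, greedy at each start").
oracle_scan <- function(sequence, motif, overlapping = TRUE) {
  L <- nchar(sequence)
  anchored <- paste0("^(?:", motif$compiled, ")")
  suffixes <- substring(sequence, seq_len(L), L)
  m <- regexpr(anchored, suffixes, perl = TRUE)
  hit <- which(m == 1L)
  lens <- attr(m, "match.length")[hit]
  starts <- hit
  ends <- hit + lens - 1L
  if (!overlapping && length(starts) > 0L) {
    keep <- integer(0)
    nxt <- 1L
    for (i in seq_along(starts)) {
      if (starts[i] >= nxt) {
        keep <- c(keep, i)
        nxt <- ends[i] + 1L
      }
    }
    starts <- starts[keep]
    ends <- ends[keep]
  }
  data.frame(start = starts, end = ends)
}

# Random pattern over the supported subset (used by the scan-vs-oracle
# property tests).
random_supported_pattern <- function() {
  n_el <- sample(2:5, 1)
  els <- vapply(seq_len(n_el), function(i) {
    kind <- sample(c("lit", "class", "neg", "dot"), 1,
                   prob = c(0.3, 0.35, 0.2, 0.15))
    body <- switch(kind,
      lit = sample(AAs, 1),
      class = paste0("[", paste(sample(AAs, sample(2:8, 1)), collapse = ""), "]"),
      neg = paste0("[^", paste(sample(AAs, sample(2:8, 1)), collapse = ""), "]"),
      dot = "."
    )
    q <- sample(c("", "?", "{2}", "{1,2}", "{0,2}"), 1,
                prob = c(0.5, 0.15, 0.1, 0.15, 0.1))
    if (stats::runif(1) < 0.3) paste0("(", body, q, ")") else paste0(body, q)
  }, character(1))
  paste(els, collapse = "")
}

random_aa_string <- function(len, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AAs, len, replace = TRUE, prob = freqs), collapse = "")
}

tiny_dataset <- function(seqs, accs = sprintf("P%05d", seq_along(seqs))) {
  protein_dataset(data.frame(accession = accs, sequence = seqs,
                             stringsAsFactors = FALSE))
}

# Rank-based AUROC (Mann-Whitney), independent of any scoring internals.
auroc <- function(pos_scores, neg_scores) {
  r <- rank(c(pos_scores, neg_scores))
  np <- length(pos_scores)
  nn <- length(neg_scores)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

subset_match_first <- function(mm) slimscan:::subset_matches(mm, 1L)

# Multiset equality of residues
same_multiset <- function(a, b) {
  identical(sort(strsplit(a, "")[[1]]), sort(strsplit(b, "")[[1]]))
}

# The seven-group phospho-acceptor pattern used across tests, with a
# concentrated per-column generating distribution for recovery/discrimination
# fixtures.
pattern7 <- "(.)(.)([^IRFW])([ST])([ILMVFWY])([ILMVFWY])(.)"

group_probs7 <- list(
  c(K = 0.7, R = 0.2, A = 0.1),
  c(A = 0.5, G = 0.3, C = 0.2),
  c(N = 0.6, Q = 0.3, A = 0.1),
  c(S = 0.8, T = 0.2),
  c(L = 0.6, I = 0.3, M = 0.1),
  c(I = 0.5, V = 0.3, F = 0.2),
  c(A = 0.4, D = 0.3, E = 0.3)
)
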