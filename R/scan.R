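# Motif scanning.
#
# Coordinates are 1-based inclusive in every user-visible structure (matching
# UniProt feature and PTM conventions). Scanning at a given start position is
# greedy (leftmost-greedy PCRE semantics), so variable-length patterns yield
# deterministic, reproducible spans.

empty_matches <- function(motif_name = NA_character_, n_groups = 0L) {
  df <- data.frame(
    accession = character(0), motif = character(0),
    start = integer(0), end = integer(0), matched = character(0),
    score = numeric(0), flank_left = character(0), flank_right = character(0),
    stringsAsFactors = FALSE
  )
  df$group_start <- list()
  df$group_end <- list()
  structure(df, class = c("motif_matches", "data.frame"),
            motif_name = motif_name, n_groups = n_groups)
}

scan_one_sequence <- function(seq, compiled, n_groups, overlapping) {
  L <- nchar(seq)
  starts <- integer(0)
  ends <- integer(0)
  gstarts <- list()
  gends <- list()
  from <- 1L
  while (from <= L) {
    m <- regexpr(compiled, substring(seq, from), perl = TRUE)
    if (m[1] == -1L) break
    st <- from + as.integer(m[1]) - 1L
    len <- attr(m, "match.length")
    en <- st + len - 1L
    starts <- c(starts, st)
    ends <- c(ends, en)
    if (n_groups > 0L) {
      cs <- as.integer(attr(m, "capture.start")[1, ])
      cl <- as.integer(attr(m, "capture.length")[1, ])
      gs <- ifelse(cs > 0L & cl > 0L, cs + from - 1L, NA_integer_)
      ge <- ifelse(cs > 0L & cl > 0L, cs + cl + from - 2L, NA_integer_)
      gstarts[[length(gstarts) + 1L]] <- gs
      gends[[length(gends) + 1L]] <- ge
    } else {
      gstarts[[length(gstarts) + 1L]] <- integer(0)
      gends[[length(gends) + 1L]] <- integer(0)
    }
    from <- if (overlapping) st + 1L else max(en + 1L, st + 1L)
  }
  list(start = starts, end = ends, group_start = gstarts, group_end = gends)
}

#' Scan a dataset for motif matches
#'
#' Reports every occurrence of a compiled motif in every record of the
#' dataset. With `overlapping = TRUE` (the default) a match attempt is made
#' at every start position, so overlapping occurrences are all reported; with
#' `overlapping = FALSE` scanning resumes after the end of each match. At any
#' given start the match is the greedy (leftmost-greedy) one, so counts are
#' reproducible for variable-length patterns.
#'
#' @param dataset A [protein_dataset].
#' @param motif A `slim_motif` from [compile_motif()].
#' @param flank_n Number of residues of sequence context to report on each
#'   side of the match (truncated at sequence boundaries).
#' @param overlapping Report overlapping matches? See above.
#' @param filter_identical Apply [filter_identical()] to the result.
#' @return A `motif_matches` data.frame, ordered by (record order, start),
#'   with columns `accession`, `motif`, `start`, `end` (1-based inclusive),
#'   `matched`, `score` (NA until scored), `flank_left`, `flank_right`, and
#'   list columns `group_start`/`group_end` holding the per-capturing-group
#'   spans (NA for groups matching the empty string).
#' @examples
#' d <- protein_dataset(data.frame(accession = "A1", sequence = "AAASTLLA"))
#' m <- compile_motif("m7", "(.)(.)([^IRFW])([ST])([ILMVFWY])([ILMVFWY])(.)")
#' scan_motif(d, m)[, c("accession", "start", "end", "matched")]
#' @export
scan_motif <- function(dataset, motif, flank_n = 0L, overlapping = TRUE,
                       filter_identical = FALSE) {
  stopifnot(inherits(dataset, "protein_dataset"), inherits(motif, "slim_motif"))
  if (flank_n < 0L) stop("flank_n must be >= 0")
  rec <- dataset$records
  per_rec <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    per_rec[[i]] <- scan_one_sequence(rec$sequence[i], motif$compiled,
                                      motif$n_groups, overlapping)
  }
  counts <- vapply(per_rec, function(h) length(h$start), integer(1))
  if (sum(counts) == 0L) {
    return(empty_matches(motif$name, motif$n_groups))
  }
  seq_idx <- rep(seq_len(nrow(rec)), counts)
  acc_out <- rec$accession[seq_idx]
  start_out <- unlist(lapply(per_rec, `[[`, "start"), use.names = FALSE)
  end_out <- unlist(lapply(per_rec, `[[`, "end"), use.names = FALSE)
  gs_out <- unlist(lapply(per_rec, `[[`, "group_start"), recursive = FALSE)
  ge_out <- unlist(lapply(per_rec, `[[`, "group_end"), recursive = FALSE)
  seqs <- rec$sequence[seq_idx]
  matched <- substr(seqs, start_out, end_out)
  fl <- substr(seqs, pmax(1L, start_out - flank_n), start_out - 1L)
  fr <- substr(seqs, end_out + 1L, pmin(nchar(seqs), end_out + flank_n))
  df <- data.frame(
    accession = acc_out, motif = motif$name,
    start = start_out, end = end_out, matched = matched,
    score = NA_real_, flank_left = fl, flank_right = fr,
    stringsAsFactors = FALSE
  )
  df$group_start <- gs_out
  df$group_end <- ge_out
  out <- structure(df, class = c("motif_matches", "data.frame"),
                   motif_name = motif$name, n_groups = motif$n_groups)
  if (filter_identical) out <- filter_identical(out)
  out
}

#' Collapse identical sequence matches
#'
#' Keeps at most one match per distinct matched string: the highest-scoring
#' one (unscored matches count as lowest; ties keep the first in scan order).
#' Survivors retain their scan order. Useful when downstream assays use only
#' the matched sequence rather than the whole protein.
#'
#' @param matches A `motif_matches` data.frame.
#' @return The filtered `motif_matches`.
#' @export
filter_identical <- function(matches) {
  stopifnot(inherits(matches, "motif_matches"))
  if (nrow(matches) <= 1L) return(matches)
  sc <- ifelse(is.na(matches$score), -Inf, matches$score)
  keep <- logical(nrow(matches))
  for (key in unique(matches$matched)) {
    idx <- which(matches$matched == key)
    keep[idx[which.max(sc[idx])]] <- TRUE
  }
  subset_matches(matches, which(keep))
}

# Row-subset a motif_matches keeping list columns and attributes intact.
subset_matches <- function(matches, rows) {
  out <- matches[rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "motif_name") <- attr(matches, "motif_name")
  attr(out, "n_groups") <- attr(matches, "n_groups")
  for (a in c("ptm_annotated", "aux_annotated")) {
    if (!is.null(attr(matches, a))) attr(out, a) <- attr(matches, a)
  }
  class(out) <- class(matches)
  out
}

# Residues of each capturing group of one match row, as a character vector
# per group ("" for empty groups).
match_group_strings <- function(matches, row) {
  gs <- matches$group_start[[row]]
  ge <- matches$group_end[[row]]
  st <- matches$start[row]
  m <- matches$matched[row]
  vapply(seq_along(gs), function(g) {
    if (is.na(gs[g])) "" else substr(m, gs[g] - st + 1L, ge[g] - st + 1L)
  }, character(1))
}
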