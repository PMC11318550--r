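# Decoy dataset generation by residue shuffling.
#
# A decoy preserves, per record, the protein length and the residue multiset
# (so global composition is untouched), and keeps the first residue in place
# so that the prevalence of an initial methionine is not disturbed — motifs
# requiring the initial Met are neither artificially enriched nor depleted.
# The preserve-IDR variant additionally shuffles each annotated disordered
# segment (and each inter-segment region) within itself, because IDRs have a
# distinctive composition (polar/Pro rich, hydrophobics depleted) that a
# whole-sequence shuffle would smear across the protein.

#' Shuffle one sequence
#'
#' Fisher-Yates permutation of the residues using the current RNG state. With
#' `preserve_first = TRUE` position 1 is left unchanged and only positions
#' `2..L` are permuted.
#'
#' @param sequence A non-empty string.
#' @param preserve_first Keep the first residue in place (default TRUE).
#' @return A string that is a permutation of `sequence`.
#' @export
shuffle_sequence <- function(sequence, preserve_first = TRUE) {
  L <- nchar(sequence)
  if (L < 1L) stop("sequence must have length >= 1")
  from <- if (preserve_first) 2L else 1L
  if (L <= from) return(sequence)
  cs <- chars(sequence)
  idx <- from:L
  cs[idx] <- cs[sample(idx, length(idx))]
  paste(cs, collapse = "")
}

# Merge overlapping/adjacent-with-overlap intervals; returns matrix cols
# start,end sorted. Overlaps are merged with a notice upstream.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

shuffle_preserving_segments <- function(sequence, idr_start, idr_end,
                                        preserve_first) {
  L <- nchar(sequence)
  iv <- merge_intervals(idr_start, idr_end)
  # cut points: segment boundaries covering [1, L] with IDR and inter-IDR runs
  bounds_s <- integer(0)
  bounds_e <- integer(0)
  cur <- 1L
  for (i in seq_len(nrow(iv))) {
    if (iv[i, "start"] > cur) {
      bounds_s <- c(bounds_s, cur)
      bounds_e <- c(bounds_e, iv[i, "start"] - 1L)
    }
    bounds_s <- c(bounds_s, iv[i, "start"])
    bounds_e <- c(bounds_e, iv[i, "end"])
    cur <- iv[i, "end"] + 1L
  }
  if (cur <= L) {
    bounds_s <- c(bounds_s, cur)
    bounds_e <- c(bounds_e, L)
  }
  parts <- character(length(bounds_s))
  for (i in seq_along(bounds_s)) {
    seg <- substr(sequence, bounds_s[i], bounds_e[i])
    # the first-Met rule: position 1 is held fixed whenever it is the start
    # of the first segment, IDR or not
    keep_first <- preserve_first && bounds_s[i] == 1L
    parts[i] <- shuffle_sequence(seg, preserve_first = keep_first)
  }
  paste(parts, collapse = "")
}

#' Build a decoy dataset
#'
#' One decoy record per target record, with the same length and residue
#' multiset, the accession prefixed (default `"decoy_"`, preventing
#' accidental joins with real PTM/feature tables) and the first residue held
#' in place when `preserve_first_met = TRUE`. In `mode = "preserve_idr"`,
#' sequences are cut at the boundaries of their annotated disordered
#' intervals and every segment (IDR and inter-IDR alike) is shuffled within
#' itself before re-concatenation in the original order, conserving
#' per-segment composition exactly; records without annotations fall back to
#' the full shuffle.
#'
#' @param dataset A [protein_dataset].
#' @param mode `"full"` (whole-sequence shuffle) or `"preserve_idr"`.
#' @param seed Integer seed; one RNG stream per call, records consumed in
#'   dataset order, so the same seed reproduces the same decoy exactly.
#' @param preserve_first_met Hold position 1 fixed (default TRUE).
#' @param idr_features Feature table (data.frame with `accession`, `start`,
#'   `end`, `type`) supplying the disordered intervals; required in
#'   `preserve_idr` mode.
#' @param idr_type Feature type naming disordered intervals
#'   (default `"Disordered"`).
#' @param prefix Accession prefix for decoy records.
#' @return A [protein_dataset] of decoy records, in target order; the seed
#'   and mode are recorded in attributes `seed` and `mode`.
#' @export
build_decoy <- function(dataset, mode = c("full", "preserve_idr"), seed,
                        preserve_first_met = TRUE, idr_features = NULL,
                        idr_type = "Disordered", prefix = "decoy_") {
  stopifnot(inherits(dataset, "protein_dataset"))
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required for decoy generation")
  if (mode == "preserve_idr" && is.null(idr_features)) {
    stop("preserve_idr mode needs an idr_features table")
  }
  rec <- dataset$records
  idr_by_acc <- NULL
  if (!is.null(idr_features)) {
    f <- idr_features[idr_features$type == idr_type, , drop = FALSE]
    idr_by_acc <- split(f, f$accession)
  }
  decoy_seqs <- with_seed(seed, {
    vapply(seq_len(nrow(rec)), function(i) {
      seqv <- rec$sequence[i]
      ivs <- if (mode == "preserve_idr") idr_by_acc[[rec$accession[i]]] else NULL
      if (is.null(ivs) || nrow(ivs) == 0L) {
        shuffle_sequence(seqv, preserve_first = preserve_first_met)
      } else {
        L <- nchar(seqv)
        if (any(ivs$start < 1L | ivs$end > L | ivs$start > ivs$end)) {
          stop(sprintf("IDR interval out of bounds for accession %s",
                       rec$accession[i]))
        }
        ov <- order(ivs$start)
        if (any(ivs$start[ov][-1] <= ivs$end[ov][-nrow(ivs)])) {
          message(sprintf("overlapping IDR intervals merged for accession %s",
                          rec$accession[i]))
        }
        shuffle_preserving_segments(seqv, ivs$start, ivs$end,
                                    preserve_first = preserve_first_met)
      }
    }, character(1))
  })
  out <- data.frame(
    accession = paste0(prefix, rec$accession),
    gene = rec$gene,
    description = rec$description,
    sequence = decoy_seqs,
    stringsAsFactors = FALSE
  )
  ds <- protein_dataset(out, name = paste0(prefix, dataset$name))
  attr(ds, "seed") <- as.integer(seed)
  attr(ds, "mode") <- mode
  ds
}
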