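# Result export: match FASTA and TSV tables with a metadata preamble.

#' Write matches as FASTA
#'
#' One entry per match, in input order. The header encodes
#' `accession:start-end motif score=...` (1-based inclusive coordinates;
#' score `NA` when unscored); the sequence is the matched substring without
#' flanks. This is the training-set format consumed by [train_pssm()] via
#' [read_fasta()].
#'
#' @param matches A `motif_matches` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches_fasta <- function(matches, path) {
  stopifnot(inherits(matches, "motif_matches"))
  if (nrow(matches) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  headers <- sprintf("%s:%d-%d %s score=%s",
                     matches$accession, matches$start, matches$end,
                     matches$motif,
                     ifelse(is.na(matches$score), "NA",
                            sprintf("%.1f", matches$score)))
  set <- Biostrings::AAStringSet(stats::setNames(matches$matched, headers))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

# Serialize list columns for the TSV: per-group spans as "s-e" joined by ';',
# site/feature tables as compact summaries.
flatten_matches <- function(matches) {
  df <- as.data.frame(matches)
  out <- df[c("accession", "motif", "start", "end", "matched", "score",
              "flank_left", "flank_right")]
  if (!is.null(df$group_start)) {
    out$groups <- vapply(seq_len(nrow(df)), function(i) {
      gs <- df$group_start[[i]]
      ge <- df$group_end[[i]]
      if (length(gs) == 0L) return("")
      paste(ifelse(is.na(gs), "-", paste0(gs, "-", ge)), collapse = ";")
    }, character(1))
  }
  if (!is.null(df$ptm_connected)) {
    out$ptm_connected <- df$ptm_connected
    out$ptm_sites <- vapply(df$ptm_sites, function(s) {
      if (is.null(s) || nrow(s) == 0L) "" else
        paste(paste0(s$residue, s$position, ":", s$modification), collapse = ";")
    }, character(1))
  }
  if (!is.null(df$idr_overlap_percent)) {
    out$idr_overlap_percent <- df$idr_overlap_percent
  }
  if (!is.null(df$features)) {
    out$features <- vapply(df$features, function(f) {
      if (is.null(f) || nrow(f) == 0L) "" else
        paste(paste0(f$type, "[", f$start, "-", f$end, "]"), collapse = ";")
    }, character(1))
  }
  for (col in c("aux_found", "aux_count", "aux_best_score")) {
    if (!is.null(df[[col]])) out[[col]] <- df[[col]]
  }
  out
}

#' Write a results table as TSV
#'
#' Writes matches or enrichment records as a tab-separated table with a
#' header row, preceded by `#`-prefixed comment lines carrying run metadata
#' (seed, options, ...). Match list columns (group spans, PTM sites,
#' features) are serialized into compact text columns.
#'
#' @param x A `motif_matches` data.frame or any plain data.frame (e.g. an
#'   enrichment table or ratio curve).
#' @param path Output path.
#' @param metadata Named list written as `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path, metadata = list()) {
  df <- if (inherits(x, "motif_matches")) flatten_matches(x) else
    as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# slimscan ", utils::packageVersion("slimscan")), con)
  for (key in names(metadata)) {
    writeLines(sprintf("# %s: %s", key,
                       paste(format(metadata[[key]]), collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV
#'
#' @param path Path written by [write_results_tsv()].
#' @return A data.frame (comment lines skipped).
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
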