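# Protein datasets and FASTA / identifier-list I/O.
#
# A protein_dataset is a thin ordered container over protein records
# (accession, optional gene symbol and description, sequence). total_aa, the
# summed residue count, is the denominator used when match counts are
# normalized across datasets of different sizes.

#' Construct a protein dataset
#'
#' @param records A data.frame with columns `accession`, `sequence` and
#'   optionally `gene`, `description`, `header`. Accessions must be unique
#'   and sequences non-empty; sequences are uppercased.
#' @param name Dataset name (used in report metadata).
#' @return A `protein_dataset`: a list with `records` (the data.frame, input
#'   order preserved), `name` and `total_aa`.
#' @export
protein_dataset <- function(records, name = "dataset") {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  if (nrow(records) > 0 && !all(c("accession", "sequence") %in% names(records))) {
    stop("records must have 'accession' and 'sequence' columns")
  }
  if (nrow(records) == 0) {
    records <- data.frame(accession = character(0), gene = character(0),
                          description = character(0), sequence = character(0),
                          stringsAsFactors = FALSE)
  }
  for (col in c("gene", "description")) {
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  }
  records$accession <- as.character(records$accession)
  records$sequence <- toupper(as.character(records$sequence))
  if (any(!nzchar(records$accession) | is.na(records$accession))) {
    stop("every record needs a non-empty accession")
  }
  if (any(nchar(records$sequence) < 1L)) {
    stop("every record needs a sequence of length >= 1")
  }
  dup <- unique(records$accession[duplicated(records$accession)])
  if (length(dup) > 0) {
    stop("duplicate accessions in dataset: ", paste(dup, collapse = ", "))
  }
  rownames(records) <- NULL
  structure(list(records = records, name = as.character(name),
                 total_aa = sum(nchar(records$sequence))),
            class = "protein_dataset")
}

#' @export
print.protein_dataset <- function(x, ...) {
  cat(sprintf("protein_dataset '%s': %d records, %d residues\n",
              x$name, nrow(x$records), x$total_aa))
  if (nrow(x$records) > 0) {
    show <- utils::head(x$records$accession, 5)
    cat("  ", paste(show, collapse = ", "),
        if (nrow(x$records) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.protein_dataset <- function(x) nrow(x$records)

# Parse a FASTA header line (without '>') into accession/gene/description.
# Supports the UniProt "db|ACC|NAME desc GN=GENE ..." convention and falls
# back to the first whitespace-delimited token.
parse_fasta_header <- function(header) {
  first <- sub("\\s.*$", "", header)
  acc <- if (grepl("^[A-Za-z0-9]+\\|[^|]+\\|", first)) {
    strsplit(first, "|", fixed = TRUE)[[1]][2]
  } else {
    first
  }
  gene <- if (grepl("GN=", header, fixed = TRUE)) {
    sub("^.*GN=(\\S+).*$", "\\1", header)
  } else {
    NA_character_
  }
  desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else NA_character_
  list(accession = acc, gene = gene, description = desc)
}

#' Read a FASTA file into a protein dataset
#'
#' Parsing is done with `Biostrings::readAAStringSet()`; headers are decoded
#' with the UniProt `db|ACC|NAME` convention when present (otherwise the first
#' whitespace-delimited token is the accession), `GN=` tokens populate the
#' gene field, and the raw header is kept for round-tripping. Sequences are
#' uppercased and line breaks removed.
#'
#' @param path Path to a FASTA file.
#' @param name Dataset name; defaults to the file name.
#' @return A [protein_dataset].
#' @export
read_fasta <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(protein_dataset(data.frame(accession = character(0),
                                      sequence = character(0)), name = name))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA: sequence data before first header at line %d",
                 nonblank[1]))
  }
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  parsed <- lapply(headers, parse_fasta_header)
  records <- data.frame(
    accession = vapply(parsed, `[[`, character(1), "accession"),
    gene = vapply(parsed, `[[`, character(1), "gene"),
    description = vapply(parsed, `[[`, character(1), "description"),
    sequence = toupper(as.character(aas)),
    header = headers,
    stringsAsFactors = FALSE
  )
  dup <- unique(records$accession[duplicated(records$accession)])
  if (length(dup) > 0) {
    stop("duplicate accessions in FASTA: ", paste(dup, collapse = ", "))
  }
  protein_dataset(records, name = name)
}

#' Write a protein dataset to FASTA
#'
#' Raw headers captured by [read_fasta()] are reused when present so that a
#' read/write round trip preserves headers; otherwise headers are rebuilt
#' from accession, gene and description.
#'
#' @param dataset A [protein_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "protein_dataset"))
  rec <- dataset$records
  headers <- if (!is.null(rec$header) && all(!is.na(rec$header))) {
    rec$header
  } else {
    vapply(seq_len(nrow(rec)), function(i) {
      h <- rec$accession[i]
      if (!is.na(rec$description[i]) && nzchar(rec$description[i])) {
        h <- paste(h, rec$description[i])
      }
      if (!is.na(rec$gene[i]) && nzchar(rec$gene[i]) &&
          !grepl("GN=", h, fixed = TRUE)) {
        h <- paste0(h, " GN=", rec$gene[i])
      }
      h
    }, character(1))
  }
  set <- Biostrings::AAStringSet(stats::setNames(rec$sequence, headers))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read an identifier list
#'
#' One identifier (accession or gene symbol) per line; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Resolve accessions / gene symbols against a proteome
#'
#' Each identifier is matched against record accessions (exact,
#' case-sensitive) and then against gene symbols (case-insensitive). Isoform
#' accessions such as `P04637-2` fall back to the base accession when the
#' exact isoform is absent, with a notice. Identifiers with no match are
#' returned in `missing` rather than raising an error. Duplicate identifiers
#' are collapsed; proteome record order determines nothing — the returned
#' sub-dataset follows the identifier order.
#'
#' @param ids Character vector of accessions and/or gene symbols.
#' @param proteome A [protein_dataset] to resolve against.
#' @return A list with `dataset` (a [protein_dataset] of the matched records,
#'   in identifier order, duplicates removed) and `missing` (character vector
#'   of unmatched identifiers, input order).
#' @export
resolve_identifiers <- function(ids, proteome) {
  stopifnot(inherits(proteome, "protein_dataset"))
  if (length(ids) == 0) stop("ids must be non-empty")
  ids <- as.character(ids)
  ids <- ids[!duplicated(ids)]
  rec <- proteome$records
  genes_up <- toupper(ifelse(is.na(rec$gene), "", rec$gene))
  hit_rows <- integer(0)
  missing <- character(0)
  for (id in ids) {
    row <- match(id, rec$accession)
    if (is.na(row)) {
      g <- which(genes_up == toupper(id))
      if (length(g) > 0) row <- g[1]
    }
    if (is.na(row) && grepl("-[0-9]+$", id)) {
      base <- sub("-[0-9]+$", "", id)
      row <- match(base, rec$accession)
      if (!is.na(row)) {
        message(sprintf("isoform '%s' not in proteome; using base accession '%s'",
                        id, base))
      }
    }
    if (is.na(row)) {
      missing <- c(missing, id)
    } else {
      hit_rows <- c(hit_rows, row)
    }
  }
  hit_rows <- hit_rows[!duplicated(hit_rows)]
  sub <- rec[hit_rows, , drop = FALSE]
  list(dataset = protein_dataset(sub, name = paste0(proteome$name, "_subset")),
       missing = missing)
}
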