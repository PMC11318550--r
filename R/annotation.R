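# Annotation of motif matches: PTM sites, disordered-region overlap, generic
# feature intersection, and auxiliary-motif co-search.
#
# All containment tests use 1-based inclusive coordinates: a site at the
# first or last position of a span is inside it.

# MOD_RSD suffix codes of the PhosphoSitePlus modification-site tables.
PSP_MOD_CODES <- c(
  p = "phosphorylation", ub = "ubiquitination", ac = "acetylation",
  me = "methylation", m1 = "methylation", m2 = "methylation",
  m3 = "methylation", gl = "o-glcnac", ga = "o-galnac", sm = "sumoylation",
  sc = "succinylation", ne = "neddylation", pa = "palmitoylation"
)

# Residues on which each modification is chemically plausible; used by the
# dbPTM implausible-modification check.
MOD_ACCEPTORS <- list(
  phosphorylation = c("S", "T", "Y", "H"),
  ubiquitination = c("K", "M"),
  acetylation = c("K", "M", "S", "T"),
  methylation = c("K", "R"),
  "o-glcnac" = c("S", "T"),
  "o-galnac" = c("S", "T"),
  sumoylation = "K",
  succinylation = "K"
)

normalize_modification <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("phosphoserine", "phosphothreonine", "phosphotyrosine")] <- "phosphorylation"
  x[x == "n6-acetyllysine"] <- "acetylation"
  x
}

#' Load a PhosphoSitePlus modification-site table
#'
#' Reads the PSP modification-site TSV dialect: an optional non-tabular
#' preamble, then a header line containing `ACC_ID` and `MOD_RSD` columns.
#' `MOD_RSD` entries of the form `S25-p` are decoded into residue, position
#' and modification (`-p` phosphorylation, `-ub` ubiquitination, `-ac`
#' acetylation, `-me`/`-m1`/`-m2`/`-m3` methylation, `-gl` O-GlcNAc, ...).
#' Ambiguous sites (mass-spectrometry peptides matching multiple proteins,
#' marked in the `Ambiguous_Site` column) are dropped by default.
#'
#' @param path Path to the TSV file.
#' @param modification_filter Optional modification name; only matching sites
#'   are returned.
#' @param drop_ambiguous Drop rows flagged ambiguous (default TRUE).
#' @return A data.frame of sites: `accession`, `position`, `residue`,
#'   `modification`, `source` (`"psp"`), `ambiguous`. Rows with an
#'   unparseable `MOD_RSD` are skipped with one counted warning.
#' @export
load_ptm_psp <- function(path, modification_filter = NULL,
                         drop_ambiguous = TRUE) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(grepl("ACC_ID", lines) & grepl("MOD_RSD", lines))[1]
  if (is.na(hdr)) stop("fatal parse error: no header with ACC_ID and MOD_RSD columns")
  tab <- utils::read.delim(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = TRUE)
  if (!"ACC_ID" %in% names(tab)) {
    stop("fatal parse error: missing ACC_ID accession column")
  }
  mm <- regmatches(tab$MOD_RSD,
                   regexec("^([A-Za-z])([0-9]+)-([a-z0-9]+)$", tab$MOD_RSD))
  ok <- vapply(mm, length, integer(1)) == 4L
  code <- vapply(mm[ok], `[[`, character(1), 4L)
  known <- code %in% names(PSP_MOD_CODES)
  n_skipped <- sum(!ok) + sum(!known)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d rows with unparseable MOD_RSD", n_skipped))
  }
  keep_idx <- which(ok)[known]
  mmk <- mm[keep_idx]
  sites <- data.frame(
    accession = tab$ACC_ID[keep_idx],
    position = as.integer(vapply(mmk, `[[`, character(1), 3L)),
    residue = toupper(vapply(mmk, `[[`, character(1), 2L)),
    modification = unname(PSP_MOD_CODES[vapply(mmk, `[[`, character(1), 4L)]),
    source = "psp",
    ambiguous = if ("Ambiguous_Site" %in% names(tab)) {
      as.integer(tab$Ambiguous_Site[keep_idx]) != 0L
    } else {
      FALSE
    },
    stringsAsFactors = FALSE
  )
  if (drop_ambiguous) sites <- sites[!sites$ambiguous, , drop = FALSE]
  if (!is.null(modification_filter)) {
    sites <- sites[sites$modification == normalize_modification(modification_filter), ,
                   drop = FALSE]
  }
  rownames(sites) <- NULL
  sites
}

#' Load a dbPTM-style modification table
#'
#' Reads the dbPTM TSV dialect (no header; a configurable column map gives
#' the positions of identifier, accession, position and modification type).
#' Experimentally derived tables of this kind contain occasional implausible
#' entries (e.g. phosphorylation recorded on alanine); with
#' `validate_residue = TRUE` and a proteome supplied, sites whose actual
#' residue is not a plausible acceptor for the modification, or whose
#' position exceeds the sequence, are flagged (`implausible` /
#' `out_of_bounds`) and dropped only when `strict = TRUE`.
#'
#' @param path Path to the TSV file.
#' @param col_map Named integer vector with entries `identifier`,
#'   `accession`, `position`, `modification` giving 1-based column indices.
#' @param validate_residue Check acceptor plausibility against `proteome`.
#' @param proteome Optional [protein_dataset] for residue validation.
#' @param strict Drop flagged sites instead of keeping them flagged.
#' @return A data.frame of sites: `accession`, `position`, `residue` (actual
#'   residue when a proteome is given, else NA), `modification`, `source`
#'   (`"dbptm"`), `ambiguous` (always FALSE), `implausible`,
#'   `out_of_bounds`.
#' @export
load_ptm_dbptm <- function(path,
                           col_map = c(identifier = 1L, accession = 2L,
                                       position = 3L, modification = 4L),
                           validate_residue = FALSE, proteome = NULL,
                           strict = FALSE) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("accession", "position", "modification")
  if (!all(need %in% names(col_map))) {
    stop("col_map must name accession, position and modification columns")
  }
  pos <- suppressWarnings(as.integer(tab[[col_map[["position"]]]]))
  bad <- is.na(pos) | pos < 1L
  if (any(bad)) {
    warning(sprintf("skipped %d rows with unparseable positions", sum(bad)))
  }
  sites <- data.frame(
    accession = as.character(tab[[col_map[["accession"]]]])[!bad],
    position = pos[!bad],
    residue = NA_character_,
    modification = normalize_modification(
      as.character(tab[[col_map[["modification"]]]])[!bad]),
    source = "dbptm",
    ambiguous = FALSE,
    implausible = FALSE,
    out_of_bounds = FALSE,
    stringsAsFactors = FALSE
  )
  if (validate_residue) {
    if (is.null(proteome)) stop("validate_residue = TRUE needs a proteome")
    seqs <- stats::setNames(proteome$records$sequence,
                            proteome$records$accession)
    for (i in seq_len(nrow(sites))) {
      s <- seqs[[sites$accession[i]]]
      if (is.null(s)) next
      if (sites$position[i] > nchar(s)) {
        sites$out_of_bounds[i] <- TRUE
        next
      }
      r <- substr(s, sites$position[i], sites$position[i])
      sites$residue[i] <- r
      acceptors <- MOD_ACCEPTORS[[sites$modification[i]]]
      if (!is.null(acceptors) && !(r %in% acceptors)) {
        sites$implausible[i] <- TRUE
      }
    }
    if (strict) {
      sites <- sites[!sites$implausible & !sites$out_of_bounds, , drop = FALSE]
    }
  }
  rownames(sites) <- NULL
  sites
}

#' Attach PTM sites to motif matches
#'
#' A match is "connected" when at least one site of the requested
#' modification lies within the scope span: the whole match span
#' (`scope = "whole_match"`) or the span of one capturing group
#' (`scope = g`, an integer). Containment is 1-based inclusive, so sites at
#' the span boundaries connect.
#'
#' @param matches A `motif_matches` data.frame.
#' @param sites A site data.frame from [load_ptm_psp()] /
#'   [load_ptm_dbptm()].
#' @param modification_filter Optional modification name filter.
#' @param scope `"whole_match"` or a capturing-group index.
#' @return `matches` with list column `ptm_sites` (per-match data.frame of
#'   connected sites) and logical `ptm_connected`.
#' @export
annotate_ptm <- function(matches, sites, modification_filter = NULL,
                         scope = "whole_match") {
  stopifnot(inherits(matches, "motif_matches"))
  if (!is.null(modification_filter)) {
    sites <- sites[sites$modification == normalize_modification(modification_filter), ,
                   drop = FALSE]
  }
  group_scope <- !identical(scope, "whole_match")
  if (group_scope) {
    scope <- as.integer(scope)
    if (is.na(scope) || scope < 1L || scope > attr(matches, "n_groups")) {
      stop("scope group index out of range")
    }
  }
  site_by_acc <- split(sites, sites$accession)
  ptm_list <- vector("list", nrow(matches))
  connected <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    acc_sites <- site_by_acc[[matches$accession[i]]]
    if (is.null(acc_sites) || nrow(acc_sites) == 0L) {
      ptm_list[[i]] <- acc_sites <- sites[0, , drop = FALSE]
      next
    }
    if (group_scope) {
      lo <- matches$group_start[[i]][scope]
      hi <- matches$group_end[[i]][scope]
      if (is.na(lo)) {
        ptm_list[[i]] <- acc_sites[0, , drop = FALSE]
        next
      }
    } else {
      lo <- matches$start[i]
      hi <- matches$end[i]
    }
    inside <- acc_sites$position >= lo & acc_sites$position <= hi
    ptm_list[[i]] <- acc_sites[inside, , drop = FALSE]
    connected[i] <- any(inside)
  }
  matches$ptm_sites <- ptm_list
  matches$ptm_connected <- connected
  attr(matches, "ptm_annotated") <- TRUE
  matches
}

#' Keep only matches connected to a PTM
#'
#' Applies the "filter without connections" rule: after [annotate_ptm()],
#' matches with no site in scope are removed, preserving order.
#'
#' @param matches PTM-annotated `motif_matches`.
#' @return The connected subset.
#' @export
filter_without_connections <- function(matches) {
  stopifnot(inherits(matches, "motif_matches"))
  if (is.null(attr(matches, "ptm_annotated")) || is.null(matches$ptm_connected)) {
    stop("call annotate_ptm() before filter_without_connections()")
  }
  subset_matches(matches, which(matches$ptm_connected))
}

#' Read a feature interval table
#'
#' Neutral TSV with header columns `accession`, `start`, `end`, `type` and
#' optionally `description`; `#` comment lines ignored.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of 1-based inclusive feature intervals.
#' @export
read_features <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("accession", "start", "end", "type")
  if (!all(need %in% names(tab))) {
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$description)) tab$description <- NA_character_
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(tab$start < 1L | tab$end < tab$start)) {
    stop("feature intervals must satisfy 1 <= start <= end")
  }
  tab
}

#' Percentage of a match overlapping disordered regions
#'
#' For each match, the percentage of its residues lying inside at least one
#' interval of type `idr_type` on the same accession, reported to 0.1%.
#' Matches on proteins without such intervals get 0%.
#'
#' @param matches A `motif_matches` data.frame.
#' @param features A feature data.frame (see [read_features()]).
#' @param idr_type Feature type naming disordered intervals.
#' @return `matches` with numeric column `idr_overlap_percent`.
#' @export
annotate_idr <- function(matches, features, idr_type = "Disordered") {
  stopifnot(inherits(matches, "motif_matches"))
  f <- features[features$type == idr_type, , drop = FALSE]
  by_acc <- split(f, f$accession)
  matches$idr_overlap_percent <- vapply(seq_len(nrow(matches)), function(i) {
    iv <- by_acc[[matches$accession[i]]]
    if (is.null(iv) || nrow(iv) == 0L) return(0)
    pos <- matches$start[i]:matches$end[i]
    covered <- vapply(pos, function(p) any(p >= iv$start & p <= iv$end),
                      logical(1))
    round(100 * sum(covered) / length(pos), 1)
  }, numeric(1))
  matches
}

#' Attach intersecting features to matches
#'
#' Lists, per match, every feature interval of the same accession that
#' overlaps the match span (1-based inclusive; an interval ending at
#' `start - 1` does not overlap), sorted by (start, type).
#'
#' @param matches A `motif_matches` data.frame.
#' @param features A feature data.frame (see [read_features()]).
#' @return `matches` with list column `features`.
#' @export
annotate_features <- function(matches, features) {
  stopifnot(inherits(matches, "motif_matches"))
  by_acc <- split(features, features$accession)
  matches$features <- lapply(seq_len(nrow(matches)), function(i) {
    iv <- by_acc[[matches$accession[i]]]
    if (is.null(iv) || nrow(iv) == 0L) return(features[0, , drop = FALSE])
    hit <- iv[iv$start <= matches$end[i] & iv$end >= matches$start[i], ,
              drop = FALSE]
    hit <- hit[order(hit$start, hit$type), , drop = FALSE]
    rownames(hit) <- NULL
    hit
  })
  matches
}

#' Auxiliary-motif co-search
#'
#' Searches each protein carrying a primary match for a second,
#' biologically related motif (e.g. an NLS supporting NES candidates). Every
#' primary match in a protein is annotated with whether that protein has at
#' least one auxiliary match at or above `aux_threshold`, the number of such
#' matches, and the best auxiliary score.
#'
#' @param primary_matches Primary `motif_matches`.
#' @param dataset The [protein_dataset] the primaries were found in.
#' @param aux_motif A compiled `slim_motif`; must carry a PSSM when
#'   `aux_threshold > 0`.
#' @param aux_threshold Minimum auxiliary score (0 means any match counts).
#' @param filter Keep only primaries with `aux_found` (default FALSE).
#' @return `primary_matches` with columns `aux_found`, `aux_count`,
#'   `aux_best_score`.
#' @export
annotate_auxiliary <- function(primary_matches, dataset, aux_motif,
                               aux_threshold = 0, filter = FALSE) {
  stopifnot(inherits(primary_matches, "motif_matches"),
            inherits(dataset, "protein_dataset"),
            inherits(aux_motif, "slim_motif"))
  if (aux_threshold > 0 && is.null(aux_motif$pssm)) {
    stop("aux_threshold > 0 requires a scored (PSSM-bearing) auxiliary motif")
  }
  accs <- unique(primary_matches$accession)
  sub <- dataset$records[dataset$records$accession %in% accs, , drop = FALSE]
  aux <- scan_motif(protein_dataset(sub, name = "aux_targets"), aux_motif)
  if (!is.null(aux_motif$pssm) && nrow(aux) > 0) {
    aux <- score_matches(aux, aux_motif$pssm)
  }
  aux_sc <- if (nrow(aux) > 0 && !anyNA(aux$score)) aux$score else
    rep(0, nrow(aux))
  keep <- aux_sc >= aux_threshold
  cnt <- table(factor(aux$accession[keep], levels = accs))
  best <- vapply(accs, function(a) {
    s <- aux_sc[aux$accession == a & keep]
    if (length(s) == 0L) NA_real_ else max(s)
  }, numeric(1))
  idx <- match(primary_matches$accession, accs)
  primary_matches$aux_found <- as.integer(cnt)[idx] > 0L
  primary_matches$aux_count <- as.integer(cnt)[idx]
  primary_matches$aux_best_score <- best[idx]
  attr(primary_matches, "aux_annotated") <- TRUE
  if (filter) {
    primary_matches <- subset_matches(primary_matches,
                                      which(primary_matches$aux_found))
  }
  primary_matches
}
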