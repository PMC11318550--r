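# Position-specific scoring matrices over regex capturing groups.
#
# One PSSM column per capturing group. Weights are log2 odds of smoothed
# observed frequencies against a background distribution. Variable-length
# groups are handled with per-instance unit mass at training (each residue of
# a length-k group counts 1/k) and a per-residue mean at scoring, so group
# length does not inflate a column's influence. Scores are min-max normalized
# to [0, 100] over the theoretical range attainable by pattern-compatible
# sequences (the max/min per column is taken over the residues admissible
# under the group's character class), so 100 is attainable and a mid-scale
# threshold (~50) is meaningful for ranking.

new_pssm <- function(weights, pattern, background, pseudocount, s_min, s_max,
                     admissible) {
  stopifnot(is.matrix(weights), nrow(weights) == 20L)
  rownames(weights) <- AA20
  if (!all(is.finite(weights))) stop("PSSM weights must be finite")
  if (!(s_min < s_max)) {
    warning("degenerate PSSM: s_min >= s_max; scores will be NA")
  }
  structure(list(
    weights = weights, pattern = pattern, background = background,
    pseudocount = pseudocount, s_min = s_min, s_max = s_max,
    admissible = admissible
  ), class = "pssm")
}

# Theoretical raw-score extrema over pattern-compatible content: per column,
# the max/min weight among residues admissible under that group's class.
pssm_range <- function(weights, admissible) {
  s_max <- 0
  s_min <- 0
  for (g in seq_len(ncol(weights))) {
    adm <- admissible[[g]]
    if (length(adm) == 0L) adm <- AA20
    s_max <- s_max + max(weights[adm, g])
    s_min <- s_min + min(weights[adm, g])
  }
  list(s_min = s_min, s_max = s_max)
}

#' Train a PSSM from aligned motif instances
#'
#' Each instance must match the motif pattern in full; its capturing groups
#' align the residues into columns. For capturing group `g` and amino acid
#' `a`, the count `c(g, a)` sums, over instances, `1/len` for every residue
#' `a` inside group `g`, where `len` is that group's length in that instance
#' — so every instance contributes one unit of mass per non-empty column
#' regardless of group length. Smoothed frequencies
#' `f = (c + pseudocount) / (sum(c) + 20 * pseudocount)` become log-odds
#' weights `w = log2(f / background)`.
#'
#' @param instances Character vector of instance sequences (each must match
#'   `motif` exactly, i.e. the whole string is one match), or a
#'   [protein_dataset] of instances (e.g. read from a training FASTA).
#' @param motif A `slim_motif` with at least one capturing group.
#' @param pseudocount Laplace smoothing constant added per residue
#'   (default 1; small training sets need smoothing).
#' @param background Background frequencies used for the odds denominator.
#' @return A `pssm` object: fields `weights` (20 x n_groups matrix, rows in
#'   alphabetical amino-acid order), `pattern`, `background`, `pseudocount`,
#'   `s_min`, `s_max` (normalization constants over pattern-compatible
#'   content), `admissible` (per-column residue classes) and `counts` (the
#'   raw, unsmoothed per-column residue mass; the maximum-likelihood column
#'   frequencies are `sweep(counts, 2, colSums(counts), "/")`).
#' @examples
#' m <- compile_motif("m7", "(.)(.)([^IRFW])([ST])([ILMVFWY])([ILMVFWY])(.)")
#' p <- train_pssm(rep("KKASLLA", 5), m)
#' round(coef(p)["S", 4], 2)
#' @seealso [score_matches()], [predict.pssm()], [write_pssm()]
#' @export
train_pssm <- function(instances, motif, pseudocount = 1,
                       background = aa_background("uniform")) {
  stopifnot(inherits(motif, "slim_motif"))
  if (inherits(instances, "protein_dataset")) {
    instances <- instances$records$sequence
  }
  instances <- toupper(as.character(instances))
  if (length(instances) == 0L) stop("empty instance set")
  if (motif$n_groups == 0L) stop("motif has no capturing groups")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  background <- aa_background(background)

  anchored <- paste0("^(?:", motif$compiled, ")$")
  counts <- matrix(0, nrow = 20L, ncol = motif$n_groups,
                   dimnames = list(AA20, NULL))
  for (inst in instances) {
    m <- regexpr(anchored, inst, perl = TRUE)
    if (m[1] != 1L || attr(m, "match.length") != nchar(inst)) {
      stop(sprintf("training instance '%s' does not match the motif pattern",
                   inst))
    }
    cs <- as.integer(attr(m, "capture.start")[1, ])
    cl <- as.integer(attr(m, "capture.length")[1, ])
    for (g in seq_len(motif$n_groups)) {
      if (cs[g] < 1L || cl[g] == 0L) next
      res <- chars(substr(inst, cs[g], cs[g] + cl[g] - 1L))
      res <- res[res %in% AA20]
      if (length(res) == 0L) next
      w <- 1 / cl[g]
      for (r in res) counts[r, g] <- counts[r, g] + w
    }
  }
  freqs <- sweep(counts + pseudocount, 2,
                 colSums(counts) + 20 * pseudocount, "/")
  weights <- log2(freqs / background)
  rng <- pssm_range(weights, motif$group_classes)
  out <- new_pssm(weights, pattern = motif$pattern, background = background,
                  pseudocount = pseudocount, s_min = rng$s_min,
                  s_max = rng$s_max, admissible = motif$group_classes)
  out$counts <- counts # raw (unsmoothed) per-column residue mass
  out
}

#' Score motif matches with a PSSM
#'
#' The raw score of a match is the sum over capturing groups of the mean
#' weight of the residues inside the group (zero-length groups contribute 0;
#' a residue outside the 20-letter alphabet scores its column's minimum).
#' Reported scores are min-max normalized,
#' `100 * (S - s_min) / (s_max - s_min)`, and clipped to `[0, 100]`.
#'
#' @param matches A `motif_matches` data.frame from [scan_motif()].
#' @param pssm A `pssm` whose column count equals the motif's group count.
#' @return `matches` with the `score` column filled in.
#' @export
score_matches <- function(matches, pssm) {
  stopifnot(inherits(matches, "motif_matches"), inherits(pssm, "pssm"))
  ng <- ncol(pssm$weights)
  if (attr(matches, "n_groups") != ng) {
    stop(sprintf("match group count (%d) != PSSM columns (%d)",
                 attr(matches, "n_groups"), ng))
  }
  if (nrow(matches) == 0L) return(matches)
  matches$score <- vapply(seq_len(nrow(matches)), function(i) {
    pssm_score_groups(pssm, match_group_strings(matches, i))
  }, numeric(1))
  matches
}

# Normalized score from per-group residue strings.
pssm_score_groups <- function(pssm, group_strings) {
  if (!(pssm$s_min < pssm$s_max)) return(NA_real_)
  s <- 0
  for (g in seq_along(group_strings)) {
    res <- chars(group_strings[g])
    if (length(res) == 0L) next
    w <- vapply(res, function(r) {
      if (r %in% AA20) pssm$weights[r, g] else min(pssm$weights[, g])
    }, numeric(1))
    s <- s + mean(w)
  }
  min(100, max(0, 100 * (s - pssm$s_min) / (pssm$s_max - pssm$s_min)))
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d columns over 20 amino acids\n", ncol(x$weights)))
  cat(sprintf("  pattern    : %s\n", x$pattern))
  cat(sprintf("  pseudocount: %g   raw score range: [%.3f, %.3f]\n",
              x$pseudocount, x$s_min, x$s_max))
  invisible(x)
}

#' @export
summary.pssm <- function(object, ...) {
  cons <- vapply(seq_len(ncol(object$weights)), function(g) {
    adm <- object$admissible[[g]]
    if (length(adm) == 0L) adm <- AA20
    adm[which.max(object$weights[adm, g])]
  }, character(1))
  info <- vapply(seq_len(ncol(object$weights)), function(g) {
    f <- object$background * 2^object$weights[, g]
    f <- f / sum(f)
    sum(f * log2(f / object$background))
  }, numeric(1))
  out <- list(n_columns = ncol(object$weights),
              consensus = paste(cons, collapse = ""),
              information_bits = info, pattern = object$pattern)
  class(out) <- "summary.pssm"
  out
}

#' @export
print.summary.pssm <- function(x, ...) {
  cat(sprintf("PSSM summary (%d columns), pattern %s\n", x$n_columns, x$pattern))
  cat(sprintf("  consensus          : %s\n", x$consensus))
  cat("  information (bits) : ",
      paste(sprintf("%.2f", x$information_bits), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.pssm <- function(object, ...) object$weights

#' Score new sequences or matches with a trained PSSM
#'
#' @param object A `pssm`.
#' @param newdata Either a `motif_matches` data.frame (scored via
#'   [score_matches()]) or a character vector of full-length instance
#'   sequences, each of which must match `motif` in its entirety.
#' @param motif The `slim_motif` the PSSM columns refer to; required when
#'   `newdata` is a character vector.
#' @param ... Unused.
#' @return Numeric scores in `[0, 100]` (or the scored `motif_matches`).
#' @export
predict.pssm <- function(object, newdata, motif = NULL, ...) {
  if (inherits(newdata, "motif_matches")) {
    return(score_matches(newdata, object)$score)
  }
  if (is.null(motif)) stop("motif is required to score raw sequences")
  stopifnot(inherits(motif, "slim_motif"))
  anchored <- paste0("^(?:", motif$compiled, ")$")
  vapply(toupper(as.character(newdata)), function(inst) {
    m <- regexpr(anchored, inst, perl = TRUE)
    if (m[1] != 1L || attr(m, "match.length") != nchar(inst)) {
      stop(sprintf("sequence '%s' does not match the motif pattern", inst))
    }
    cs <- as.integer(attr(m, "capture.start")[1, ])
    cl <- as.integer(attr(m, "capture.length")[1, ])
    gstr <- vapply(seq_along(cs), function(g) {
      if (cs[g] < 1L || cl[g] == 0L) "" else
        substr(inst, cs[g], cs[g] + cl[g] - 1L)
    }, character(1))
    pssm_score_groups(object, gstr)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Plot PSSM weights as a heat map
#'
#' @param x A `pssm`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pssm <- function(x, ...) {
  w <- x$weights
  graphics::image(seq_len(ncol(w)), seq_len(nrow(w)), t(w),
                  xlab = "capturing group", ylab = "", axes = FALSE,
                  main = "PSSM weights (log2 odds)", ...)
  graphics::axis(1, at = seq_len(ncol(w)))
  graphics::axis(2, at = seq_len(nrow(w)), labels = rownames(w), las = 1,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Write / read the plain-text PSSM format
#'
#' The format is `#`-prefixed metadata lines (pattern, background,
#' pseudocount, s_min, s_max, amino-acid order) followed by one row per
#' column with 20 tab-separated log2-odds weights in alphabetical amino-acid
#' order. `read_pssm(write_pssm(p))` reproduces the weights to 1e-9.
#'
#' @param pssm A `pssm`.
#' @param path File path.
#' @return `write_pssm`: `path`, invisibly. `read_pssm`: a `pssm`. If the
#'   file lacks `s_min`/`s_max`, they are recomputed from the weights and the
#'   recorded pattern, with a notice.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# slimscan PSSM v1",
    paste0("# pattern: ", pssm$pattern),
    paste0("# pseudocount: ", format(pssm$pseudocount, digits = 17)),
    paste0("# background: ", paste(format(pssm$background, digits = 17),
                                   collapse = " ")),
    paste0("# s_min: ", format(pssm$s_min, digits = 17)),
    paste0("# s_max: ", format(pssm$s_max, digits = 17)),
    paste0("# aa_order: ", paste(AA20, collapse = "")),
    paste0("# columns: ", ncol(pssm$weights))
  ), con)
  for (g in seq_len(ncol(pssm$weights))) {
    writeLines(paste(format(pssm$weights[, g], digits = 17), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  meta <- list()
  for (ml in meta_lines) {
    mm <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ml))[[1]]
    if (length(mm) == 3L) meta[[mm[2]]] <- mm[3]
  }
  if (length(data_idx) == 0L) stop("truncated PSSM file: no weight rows")
  rows <- lapply(seq_along(data_idx), function(i) {
    fields <- strsplit(lines[data_idx[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 20L) {
      stop(sprintf("PSSM parse error: row %d has %d fields, expected 20",
                   i, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("PSSM parse error: non-numeric weight in row %d", i))
    }
    vals
  })
  weights <- do.call(cbind, rows)
  rownames(weights) <- AA20
  if (!is.null(meta$columns) && as.integer(meta$columns) != ncol(weights)) {
    stop(sprintf("truncated PSSM file: header declares %s columns, found %d",
                 meta$columns, ncol(weights)))
  }
  pattern <- if (!is.null(meta$pattern)) meta$pattern else NA_character_
  background <- if (!is.null(meta$background)) {
    stats::setNames(as.numeric(strsplit(trimws(meta$background), "\\s+")[[1]]), AA20)
  } else {
    aa_background("uniform")
  }
  pseudocount <- if (!is.null(meta$pseudocount)) as.numeric(meta$pseudocount) else 1
  admissible <- if (!is.na(pattern)) {
    compile_motif("tmp", pattern)$group_classes
  } else {
    replicate(ncol(weights), AA20, simplify = FALSE)
  }
  if (is.null(meta$s_min) || is.null(meta$s_max)) {
    message("PSSM file lacks s_min/s_max; recomputing from weights and pattern")
    rng <- pssm_range(weights, admissible)
    s_min <- rng$s_min
    s_max <- rng$s_max
  } else {
    s_min <- as.numeric(meta$s_min)
    s_max <- as.numeric(meta$s_max)
  }
  new_pssm(weights, pattern = pattern, background = background,
           pseudocount = pseudocount, s_min = s_min, s_max = s_max,
           admissible = admissible)
}
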