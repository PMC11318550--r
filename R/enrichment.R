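# Target/decoy enrichment statistics.
#
# The per-motif enrichment ratio is (n_target / n_target_aa) /
# (n_decoy / n_decoy_aa): match counts normalized to dataset size in
# residues, so datasets of different sizes are comparable. Significance uses
# a two-sided pooled two-proportion z-test with the residue counts as the
# number of trials, corrected across the motif family with
# Benjamini-Hochberg. A motif is called enriched when its ratio is at least
# `ratio_cut` (default 2) AND its q-value is at most `q_cut` (default 0.05);
# depleted symmetrically at ratio <= 1/ratio_cut; anything else is
# non-significant.

#' Two-sided pooled two-proportion z-test
#'
#' `z = (k1/n1 - k2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (k1 + k2) / (n1 + n2)`; p = `2 * (1 - pnorm(|z|))`. Degenerate
#' tables with no information (both proportions 0, or both 1) return p = 1.
#' Suited to the large-count regime; for small counts use
#' `method = "fisher"` in [enrichment_table()].
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A p-value in (0, 1].
#' @export
two_proportion_pvalue <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("n must be >= 1")
  if (k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) stop("need 0 <= k <= n")
  if ((k1 == 0 && k2 == 0) || (k1 == n1 && k2 == n2)) return(1)
  phat <- (k1 + k2) / (n1 + n2)
  z <- (k1 / n1 - k2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  min(1, 2 * (1 - stats::pnorm(abs(z))))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across one motif family (all motifs in a table
#' form the family). Thin validated wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-motif target/decoy enrichment table
#'
#' @param target_counts,decoy_counts Named integer vectors of match counts,
#'   one entry per motif; both must have the same motif names.
#' @param n_target_aa,n_decoy_aa Dataset sizes in residues (the number of
#'   scanned positions; `total_aa` of the datasets).
#' @param ratio_cut Enrichment ratio threshold (default 2: enriched means at
#'   least double, depleted at most half, after size normalization).
#' @param q_cut BH-adjusted p-value threshold (default 0.05).
#' @param method `"z"` (pooled two-proportion z-test) or `"fisher"`
#'   (Fisher's exact test, for small counts).
#' @return A data.frame with one row per motif: `motif`, `n_target`,
#'   `n_decoy`, `n_target_aa`, `n_decoy_aa`, `ratio`, `log2_ratio`,
#'   `p_value`, `q_value`, `classification` (factor enriched / depleted /
#'   non_significant) and `ratio_continuity` (TRUE where a zero decoy count
#'   made the Haldane-style +0.5 continuity rule apply to the ratio; the
#'   p-value always uses the untouched counts).
#' @examples
#' enrichment_table(c(m = 200), c(m = 100), 1e6, 1e6)
#' @export
enrichment_table <- function(target_counts, decoy_counts,
                             n_target_aa, n_decoy_aa,
                             ratio_cut = 2, q_cut = 0.05,
                             method = c("z", "fisher")) {
  method <- match.arg(method)
  if (n_target_aa < 1 || n_decoy_aa < 1) stop("dataset sizes must be >= 1")
  motifs <- names(target_counts)
  if (is.null(motifs) || is.null(names(decoy_counts))) {
    stop("counts must be named by motif")
  }
  only_t <- setdiff(motifs, names(decoy_counts))
  only_d <- setdiff(names(decoy_counts), motifs)
  if (length(only_t) + length(only_d) > 0) {
    stop("motifs present in only one count map: ",
         paste(c(only_t, only_d), collapse = ", "))
  }
  decoy_counts <- decoy_counts[motifs]
  kt <- as.numeric(target_counts)
  kd <- as.numeric(decoy_counts)

  continuity <- kd == 0 | kt == 0
  kt_r <- ifelse(continuity, kt + 0.5, kt)
  kd_r <- ifelse(continuity, kd + 0.5, kd)
  ratio <- (kt_r / n_target_aa) / (kd_r / n_decoy_aa)

  p <- vapply(seq_along(kt), function(i) {
    if (method == "z") {
      two_proportion_pvalue(kt[i], n_target_aa, kd[i], n_decoy_aa)
    } else {
      stats::fisher.test(matrix(c(kt[i], n_target_aa - kt[i],
                                  kd[i], n_decoy_aa - kd[i]), 2))$p.value
    }
  }, numeric(1))
  q <- bh_adjust(p)

  classification <- rep("non_significant", length(kt))
  classification[ratio >= ratio_cut & q <= q_cut] <- "enriched"
  classification[ratio <= 1 / ratio_cut & q <= q_cut] <- "depleted"

  data.frame(
    motif = motifs, n_target = as.integer(kt), n_decoy = as.integer(kd),
    n_target_aa = n_target_aa, n_decoy_aa = n_decoy_aa,
    ratio = ratio, log2_ratio = log2(ratio),
    p_value = p, q_value = q,
    classification = factor(classification,
                            levels = c("enriched", "depleted", "non_significant")),
    ratio_continuity = continuity,
    stringsAsFactors = FALSE
  )
}

#' Count matches per motif
#'
#' Convenience wrapper turning lists of `motif_matches` into the named count
#' vectors [enrichment_table()] expects.
#'
#' @param match_list A list of `motif_matches` (one element per motif; names
#'   default to each set's motif name).
#' @return Named integer vector of match counts.
#' @export
count_matches <- function(match_list) {
  if (inherits(match_list, "motif_matches")) match_list <- list(match_list)
  nm <- names(match_list)
  if (is.null(nm)) {
    nm <- vapply(match_list, function(m) {
      v <- attr(m, "motif_name")
      if (is.null(v) || is.na(v)) "motif" else v
    }, character(1))
  }
  stats::setNames(vapply(match_list, nrow, integer(1)), nm)
}

#' Target/decoy ratio as a function of score threshold
#'
#' At each threshold `t`, only matches with `score >= t` are counted; the
#' ratio is size-normalized when `normalize_per_aa = TRUE` (needed when the
#' two datasets differ in residue count). Thresholds where a dataset has
#' zero surviving matches use the Haldane-style +0.5 continuity rule for the
#' ratio and are flagged.
#'
#' @param target_matches,decoy_matches Scored `motif_matches` (scores may be
#'   absent only when the sole threshold is 0).
#' @param thresholds Ascending numeric score thresholds (default
#'   `seq(0, 90, by = 10)`).
#' @param normalize_per_aa Normalize counts by dataset residue size.
#' @param n_target_aa,n_decoy_aa Dataset sizes in residues; required when
#'   `normalize_per_aa = TRUE`.
#' @return A data.frame with `threshold`, `n_target`, `n_decoy`, `ratio`,
#'   `continuity`. Counts are non-increasing in the threshold.
#' @export
ratio_curve <- function(target_matches, decoy_matches,
                        thresholds = seq(0, 90, by = 10),
                        normalize_per_aa = TRUE,
                        n_target_aa = NULL, n_decoy_aa = NULL) {
  thresholds <- sort(thresholds)
  st <- target_matches$score
  sd_ <- decoy_matches$score
  if (any(thresholds > 0) && (anyNA(st) || anyNA(sd_))) {
    stop("matches must be scored for thresholds > 0")
  }
  if (normalize_per_aa && (is.null(n_target_aa) || is.null(n_decoy_aa))) {
    stop("normalize_per_aa = TRUE needs n_target_aa and n_decoy_aa")
  }
  if (anyNA(st)) st <- rep(0, nrow(target_matches))
  if (anyNA(sd_)) sd_ <- rep(0, nrow(decoy_matches))
  kt <- vapply(thresholds, function(t) sum(st >= t), numeric(1))
  kd <- vapply(thresholds, function(t) sum(sd_ >= t), numeric(1))
  continuity <- kt == 0 | kd == 0
  kt_r <- ifelse(continuity, kt + 0.5, kt)
  kd_r <- ifelse(continuity, kd + 0.5, kd)
  ratio <- if (normalize_per_aa) {
    (kt_r / n_target_aa) / (kd_r / n_decoy_aa)
  } else {
    kt_r / kd_r
  }
  data.frame(threshold = thresholds, n_target = as.integer(kt),
             n_decoy = as.integer(kd), ratio = ratio, continuity = continuity)
}

#' Volcano-plot-ready table
#'
#' Projects an enrichment table onto the axes of a volcano plot:
#' `log2_ratio` against `-log10(q)`, with the classification retained.
#'
#' @param table Output of [enrichment_table()].
#' @return A data.frame with `motif`, `log2_ratio`, `neg_log10_q`,
#'   `classification`.
#' @export
volcano_table <- function(table) {
  data.frame(motif = table$motif, log2_ratio = table$log2_ratio,
             neg_log10_q = -log10(pmax(table$q_value, .Machine$double.xmin)),
             classification = table$classification,
             stringsAsFactors = FALSE)
}
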