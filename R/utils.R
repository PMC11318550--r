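# Shared constants and small helpers.

# The 20 standard amino acids in alphabetical one-letter order. This order is
# used everywhere a per-residue vector or PSSM row order is needed.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average amino-acid composition of UniProtKB/Swiss-Prot (release statistics),
# renormalized to sum to 1. Shipped as the non-uniform background preset.
SWISSPROT_FREQS <- c(
  A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07, H = 2.27,
  I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06, P = 4.74, Q = 3.93,
  R = 5.53, S = 6.64, T = 5.36, V = 6.86, W = 1.10, Y = 2.92
) / 100

#' Background amino-acid frequencies
#'
#' Returns a background distribution over the 20 standard amino acids, used by
#' [pattern_probability()], [train_pssm()] and the synthetic-data generator.
#'
#' @param composition Either `"uniform"` (1/20 per residue), `"swissprot"`
#'   (average Swiss-Prot composition), or a named numeric vector of
#'   non-negative frequencies covering all 20 standard amino acids (it is
#'   renormalized to sum to 1).
#' @return A named numeric vector of length 20 in alphabetical amino-acid
#'   order, non-negative, summing to 1.
#' @examples
#' aa_background("uniform")[["S"]]
#' @export
aa_background <- function(composition = c("uniform", "swissprot")) {
  if (is.character(composition)) {
    composition <- match.arg(composition)
    freqs <- switch(composition,
      uniform = stats::setNames(rep(1 / 20, 20), AA20),
      swissprot = SWISSPROT_FREQS[AA20] / sum(SWISSPROT_FREQS)
    )
  } else {
    if (!is.numeric(composition) || is.null(names(composition))) {
      stop("background must be 'uniform', 'swissprot' or a named numeric vector")
    }
    if (!all(AA20 %in% names(composition))) {
      stop("background vector must name all 20 standard amino acids; missing: ",
           paste(setdiff(AA20, names(composition)), collapse = ", "))
    }
    freqs <- composition[AA20]
    if (any(freqs < 0) || !all(is.finite(freqs))) {
      stop("background frequencies must be finite and non-negative")
    }
    freqs <- freqs / sum(freqs)
  }
  if (abs(sum(freqs) - 1) > 1e-9) stop("background frequencies must sum to 1")
  freqs
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All seeded package functions go through this
# so that library state is never perturbed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# splits a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# uniform draw from lo:hi that is safe when lo == hi (sample() would
# otherwise treat a single integer as a range)
sample_int_range <- function(lo, hi) {
  if (lo >= hi) lo else sample(lo:hi, 1L)
}
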