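# Motif compilation and the analytical pattern-probability model.
#
# Motif patterns are ELM-style regular expressions restricted to a subset that
# admits exact probability calculus: literals, character classes (including
# negation and ranges), '.', bounded quantifiers {m}, {m,n}, '?', capturing
# groups and top-level alternation. Unbounded '*'/'+', look-around,
# backreferences and nested groups are rejected at compile time.
#
# Non-standard residues (X, U, B, Z, ...) are tolerated in sequences but never
# match any pattern position: at compile time '.' and negated classes are
# rewritten as explicit classes over the 20 standard amino acids.

parse_error <- function(pos, msg) {
  stop(sprintf("invalid motif pattern at character %d: %s", pos, msg),
       call. = FALSE)
}

# Recursive-descent parser for the supported pattern subset. Returns a list of
# branches (top-level alternatives); each branch is a list of elements; an
# element is either an atom (allowed-residue set + quantifier) or a capturing
# group (list of atoms + its own quantifier + 1-based group index).
motif_parse <- function(pattern) {
  cs <- chars(pattern)
  n <- length(cs)
  pos <- 1L
  group_counter <- 0L

  peek <- function(k = 0L) if (pos + k <= n) cs[pos + k] else NA_character_
  advance <- function() {
    ch <- cs[pos]
    pos <<- pos + 1L
    ch
  }

  parse_class <- function() {
    open_at <- pos - 1L
    neg <- FALSE
    if (identical(peek(), "^")) {
      advance()
      neg <- TRUE
    }
    items <- character(0)
    repeat {
      ch <- peek()
      if (is.na(ch)) parse_error(open_at, "unterminated character class")
      if (ch == "]") break
      advance()
      if (!ch %in% LETTERS) {
        parse_error(pos - 1L, sprintf("unsupported character '%s' in class", ch))
      }
      if (identical(peek(), "-") && !is.na(peek(1L)) && peek(1L) != "]") {
        advance()
        hi <- advance()
        if (!hi %in% LETTERS || match(hi, LETTERS) < match(ch, LETTERS)) {
          parse_error(pos - 1L, "malformed range in character class")
        }
        items <- c(items, LETTERS[match(ch, LETTERS):match(hi, LETTERS)])
      } else {
        items <- c(items, ch)
      }
    }
    advance() # consume ']'
    items <- unique(items)
    allowed <- if (neg) setdiff(AA20, items) else intersect(items, AA20)
    if (length(allowed) == 0L) {
      parse_error(open_at, "character class admits no standard amino acid")
    }
    list(type = "atom", allowed = allowed, dot = FALSE, qmin = 1L, qmax = 1L)
  }

  parse_quant <- function(el) {
    force(el) # consume the atom before peeking at the quantifier
    ch <- peek()
    if (is.na(ch)) return(el)
    if (ch == "*" || ch == "+") {
      parse_error(pos, sprintf(
        "unbounded quantifier '%s' is unsupported; use a bounded '{m,n}'", ch))
    }
    if (ch == "?") {
      advance()
      el$qmin <- 0L
      return(el)
    }
    if (ch == "{") {
      open_at <- pos
      advance()
      digits1 <- character(0)
      while (!is.na(peek()) && grepl("[0-9]", peek())) digits1 <- c(digits1, advance())
      if (length(digits1) == 0L) parse_error(open_at, "malformed '{' quantifier")
      m <- as.integer(paste(digits1, collapse = ""))
      if (identical(peek(), "}")) {
        advance()
        el$qmin <- m
        el$qmax <- m
        return(el)
      }
      if (!identical(peek(), ",")) parse_error(pos, "malformed '{m,n}' quantifier")
      advance()
      digits2 <- character(0)
      while (!is.na(peek()) && grepl("[0-9]", peek())) digits2 <- c(digits2, advance())
      if (length(digits2) == 0L) {
        parse_error(open_at,
                    "unbounded '{m,}' quantifier is unsupported; give an upper bound")
      }
      if (!identical(peek(), "}")) parse_error(pos, "malformed '{m,n}' quantifier")
      advance()
      mx <- as.integer(paste(digits2, collapse = ""))
      if (mx < m) parse_error(open_at, "quantifier maximum below minimum")
      el$qmin <- m
      el$qmax <- mx
      return(el)
    }
    el
  }

  parse_atom <- function() {
    ch <- advance()
    if (ch == ".") {
      return(list(type = "atom", allowed = AA20, dot = TRUE, qmin = 1L, qmax = 1L))
    }
    if (ch == "[") {
      return(parse_class())
    }
    if (ch == "\\") {
      parse_error(pos - 1L,
                  "escapes/backreferences ('\\') are unsupported")
    }
    if (ch %in% c("^", "$")) {
      parse_error(pos - 1L, sprintf("anchor '%s' is unsupported", ch))
    }
    if (!ch %in% LETTERS) {
      parse_error(pos - 1L, sprintf("unsupported construct '%s'", ch))
    }
    allowed <- intersect(ch, AA20)
    if (length(allowed) == 0L) {
      parse_error(pos - 1L,
                  sprintf("literal '%s' is not a standard amino acid", ch))
    }
    list(type = "atom", allowed = allowed, dot = FALSE, qmin = 1L, qmax = 1L)
  }

  parse_group <- function() {
    open_at <- pos - 1L
    if (identical(peek(), "?")) {
      parse_error(pos, "look-around / non-capturing groups ('(?') are unsupported")
    }
    group_counter <<- group_counter + 1L
    idx <- group_counter
    atoms <- list()
    repeat {
      ch <- peek()
      if (is.na(ch)) parse_error(open_at, "unbalanced parentheses")
      if (ch == ")") break
      if (ch == "(") parse_error(pos, "nested capturing groups are unsupported")
      if (ch == "|") parse_error(pos, "alternation inside groups is unsupported")
      atoms[[length(atoms) + 1L]] <- parse_quant(parse_atom())
    }
    advance() # ')'
    if (length(atoms) == 0L) parse_error(open_at, "empty capturing group")
    list(type = "group", index = idx, atoms = atoms, qmin = 1L, qmax = 1L)
  }

  parse_branch <- function() {
    elements <- list()
    repeat {
      ch <- peek()
      if (is.na(ch) || ch == "|") break
      if (ch == ")") parse_error(pos, "unbalanced parentheses")
      el <- if (ch == "(") {
        advance()
        parse_group()
      } else {
        parse_atom()
      }
      elements[[length(elements) + 1L]] <- parse_quant(el)
    }
    if (length(elements) == 0L) parse_error(pos, "empty alternative")
    elements
  }

  branches <- list(parse_branch())
  while (identical(peek(), "|")) {
    advance()
    branches[[length(branches) + 1L]] <- parse_branch()
  }
  if (pos <= n) parse_error(pos, "unbalanced parentheses")
  list(branches = branches, n_groups = group_counter)
}

# Re-emit a parsed pattern as a PCRE string in which every position is an
# explicit class over standard amino acids (so non-standard residues never
# match). Capturing-group numbering is preserved.
emit_pattern <- function(ast) {
  emit_quant <- function(el) {
    if (el$qmin == 1L && el$qmax == 1L) return("")
    if (el$qmin == 0L && el$qmax == 1L) return("?")
    if (el$qmin == el$qmax) return(sprintf("{%d}", el$qmin))
    sprintf("{%d,%d}", el$qmin, el$qmax)
  }
  emit_atom <- function(a) {
    body <- if (length(a$allowed) == 1L) {
      a$allowed
    } else {
      paste0("[", paste(a$allowed, collapse = ""), "]")
    }
    paste0(body, emit_quant(a))
  }
  emit_el <- function(el) {
    if (el$type == "atom") return(emit_atom(el))
    inner <- paste(vapply(el$atoms, emit_atom, character(1)), collapse = "")
    paste0("(", inner, ")", emit_quant(el))
  }
  branch_str <- vapply(ast$branches, function(br) {
    paste(vapply(br, emit_el, character(1)), collapse = "")
  }, character(1))
  paste(branch_str, collapse = "|")
}

element_len_range <- function(el) {
  if (el$type == "atom") {
    return(c(el$qmin, el$qmax))
  }
  inner <- vapply(el$atoms, function(a) c(a$qmin, a$qmax), numeric(2))
  c(el$qmin * sum(inner[1, ]), el$qmax * sum(inner[2, ]))
}

#' Compile a motif pattern
#'
#' Validates and compiles an ELM-style regular-expression motif into a
#' `slim_motif` object. The supported pattern subset is: single-letter
#' literals, character classes `[...]` with negation `[^...]` and ranges,
#' `.`, bounded quantifiers `{m}`, `{m,n}` and `?`, capturing groups
#' `(...)` (not nested) and top-level alternation `|`. Unbounded `*`/`+`,
#' look-around and backreferences raise a validation error naming the
#' construct.
#'
#' Capturing groups are the scoring unit: each group maps to one PSSM column
#' (see [train_pssm()]). Non-standard residues (X, U, B, Z) in sequences
#' never match any pattern position, including `.` and negated classes.
#'
#' @param name Motif name (used in reports).
#' @param pattern Pattern string in the supported subset.
#' @param pssm Optional [pssm] object attached to the motif; its column count
#'   must equal the motif's number of capturing groups.
#' @return A `slim_motif` object with fields `name`, `pattern` (as given),
#'   `compiled` (the PCRE string actually scanned), `n_groups`, `min_len`,
#'   `max_len`, `group_classes` (per-group admissible residue sets) and
#'   optional `pssm`.
#' @examples
#' m <- compile_motif("phospho7", "(.)(.)([^IRFW])([ST])([ILMVFWY])([ILMVFWY])(.)")
#' m$n_groups
#' m$min_len
#' @seealso [scan_motif()], [pattern_probability()], [train_pssm()]
#' @export
compile_motif <- function(name, pattern, pssm = NULL) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      nchar(pattern) == 0L) {
    stop("pattern must be a non-empty string")
  }
  ast <- motif_parse(toupper(pattern))
  ranges <- vapply(unlist(lapply(ast$branches, function(br) br),
                          recursive = FALSE),
                   element_len_range, numeric(2))
  branch_ranges <- vapply(ast$branches, function(br) {
    r <- vapply(br, element_len_range, numeric(2))
    c(sum(r[1, ]), sum(r[2, ]))
  }, numeric(2))
  group_classes <- vector("list", ast$n_groups)
  for (br in ast$branches) {
    for (el in br) {
      if (el$type == "group") {
        sets <- unique(unlist(lapply(el$atoms, `[[`, "allowed")))
        group_classes[[el$index]] <- sort(unique(c(group_classes[[el$index]], sets)))
      }
    }
  }
  if (!is.null(pssm)) {
    if (!inherits(pssm, "pssm")) stop("pssm must be a 'pssm' object")
    if (ncol(pssm$weights) != ast$n_groups) {
      stop(sprintf("PSSM has %d columns but pattern has %d capturing groups",
                   ncol(pssm$weights), ast$n_groups))
    }
  }
  structure(list(
    name = as.character(name),
    pattern = pattern,
    compiled = emit_pattern(ast),
    ast = ast,
    n_groups = ast$n_groups,
    min_len = as.integer(min(branch_ranges[1, ])),
    max_len = as.integer(max(branch_ranges[2, ])),
    group_classes = group_classes,
    pssm = pssm
  ), class = "slim_motif")
}

#' @export
print.slim_motif <- function(x, ...) {
  cat(sprintf("slim_motif '%s'\n", x$name))
  cat(sprintf("  pattern : %s\n", x$pattern))
  cat(sprintf("  groups  : %d   match length: %d-%d\n",
              x$n_groups, x$min_len, x$max_len))
  cat(sprintf("  PSSM    : %s\n", if (is.null(x$pssm)) "none" else "attached"))
  invisible(x)
}

#' Analytical pattern-match probability
#'
#' Probability that the motif's regular expression matches starting at a fixed
#' position of an infinite i.i.d. random sequence drawn from `background`.
#' Computed exactly as a sum over all length expansions of the bounded
#' quantifiers: for each expanded fixed-length word, the product of its
#' per-position class probabilities (a class probability is the sum of the
#' background frequencies of its members; `.` contributes 1). Expansions are
#' summed without inclusion-exclusion, so for patterns whose expansions
#' overlap the value can exceed the true union probability (and even exceed
#' 1); a warning is emitted in that case. This mirrors the convention of
#' ELM-style pattern probabilities.
#'
#' @param motif A `slim_motif`.
#' @param background Background frequencies from [aa_background()].
#' @param max_expansions Guard on the number of quantifier expansions
#'   (default 1e6); patterns beyond it raise an error advising
#'   simplification. The value itself is computed in closed form, so the cap
#'   only bounds the combinatorial size of the implied expansion.
#' @return A single number in `[0, max_expansions]`.
#' @examples
#' pattern_probability(compile_motif("st", "[ST]"))     # 0.1 under uniform
#' pattern_probability(compile_motif("any", "."))       # 1
#' @export
pattern_probability <- function(motif, background = aa_background("uniform"),
                                max_expansions = 1e6) {
  stopifnot(inherits(motif, "slim_motif"))
  background <- aa_background(background)

  atom_p <- function(a) {
    if (a$dot) 1 else sum(background[a$allowed])
  }
  quant_sum <- function(base, qmin, qmax) {
    sum(base^(qmin:qmax))
  }
  n_expansions <- 0
  total <- 0
  for (br in motif$ast$branches) {
    p_branch <- 1
    count <- 1
    for (el in br) {
      if (el$type == "atom") {
        p_branch <- p_branch * quant_sum(atom_p(el), el$qmin, el$qmax)
        count <- count * (el$qmax - el$qmin + 1)
      } else {
        inner_p <- 1
        for (a in el$atoms) {
          inner_p <- inner_p * quant_sum(atom_p(a), a$qmin, a$qmax)
          count <- count * (a$qmax - a$qmin + 1)
        }
        p_branch <- p_branch * quant_sum(inner_p, el$qmin, el$qmax)
        count <- count * (el$qmax - el$qmin + 1)
      }
      if (count > max_expansions) {
        stop(sprintf(
          "pattern expands to more than %g fixed-length words; simplify the quantifiers",
          max_expansions))
      }
    }
    n_expansions <- n_expansions + count
    total <- total + p_branch
  }
  if (n_expansions > max_expansions) {
    stop(sprintf(
      "pattern expands to more than %g fixed-length words; simplify the quantifiers",
      max_expansions))
  }
  if (total > 1) {
    warning("pattern probability exceeds 1: overlapping length expansions are summed without inclusion-exclusion")
  }
  total
}

#' Sample pattern-compatible instance strings
#'
#' Draws random strings that match a compiled motif, by choosing a top-level
#' alternative uniformly, a repetition count uniformly within each bounded
#' quantifier, and residues from the background distribution restricted to
#' each position's admissible class. Positions inside capturing group `g` can
#' instead be drawn from an explicit categorical distribution via
#' `group_probs[[g]]` (a named probability vector over residues), which is
#' how the synthetic-data generator plants consensus-like instances.
#'
#' Uses the current RNG state; seed with `set.seed()` or call from a seeded
#' fixture function for reproducibility.
#'
#' @param motif A `slim_motif`.
#' @param n Number of instances.
#' @param background Background frequencies for unconstrained positions.
#' @param group_probs Optional list, indexed by capturing-group number, of
#'   named residue probability vectors.
#' @return Character vector of `n` strings, each matching `motif`.
#' @export
sample_motif_instances <- function(motif, n = 1,
                                   background = aa_background("uniform"),
                                   group_probs = NULL) {
  stopifnot(inherits(motif, "slim_motif"))
  background <- aa_background(background)

  draw_atom <- function(a, reps, probs = NULL) {
    if (reps == 0L) return("")
    if (!is.null(probs)) {
      paste(sample(names(probs), reps, replace = TRUE, prob = probs),
            collapse = "")
    } else {
      w <- background[a$allowed]
      if (sum(w) <= 0) w <- rep(1, length(a$allowed))
      paste(sample(a$allowed, reps, replace = TRUE, prob = w), collapse = "")
    }
  }

  out <- character(n)
  branches <- motif$ast$branches
  for (i in seq_len(n)) {
    br <- branches[[sample.int(length(branches), 1L)]]
    parts <- character(0)
    for (el in br) {
      reps_el <- if (el$qmin == el$qmax) el$qmin else
        sample(el$qmin:el$qmax, 1L)
      if (el$type == "atom") {
        parts <- c(parts, draw_atom(el, reps_el))
      } else {
        gp <- if (!is.null(group_probs) && length(group_probs) >= el$index)
          group_probs[[el$index]] else NULL
        if (!is.null(gp)) {
          bad <- setdiff(names(gp)[gp > 0], motif$group_classes[[el$index]])
          if (length(bad) > 0) {
            stop("group_probs assigns mass to residues outside the group class: ",
                 paste(bad, collapse = ", "))
          }
        }
        for (k in seq_len(reps_el)) {
          for (a in el$atoms) {
            r <- if (a$qmin == a$qmax) a$qmin else sample(a$qmin:a$qmax, 1L)
            parts <- c(parts, draw_atom(a, r, gp))
          }
        }
      }
    }
    out[i] <- paste(parts, collapse = "")
  }
  out
}

#' Read a motif definition table
#'
#' Reads a TSV with columns `name`, `pattern` and optionally `pssm` (a path,
#' relative to the table's directory, of a PSSM file readable by
#' [read_pssm()]). Lines starting with `#` are ignored. ELM class downloads
#' can be converted to this layout by keeping the identifier and pattern
#' columns.
#'
#' @param path Path to the TSV file.
#' @return A named list of `slim_motif` objects.
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(tab))) {
    stop("motif table must have 'name' and 'pattern' columns")
  }
  motifs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- NULL
    if ("pssm" %in% names(tab) && !is.na(tab$pssm[i]) && nzchar(tab$pssm[i])) {
      p <- read_pssm(file.path(dirname(path), tab$pssm[i]))
    }
    motifs[[i]] <- compile_motif(tab$name[i], tab$pattern[i], pssm = p)
  }
  stats::setNames(motifs, tab$name)
}
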