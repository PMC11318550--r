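# Synthetic-data generator.
#
# Emulates the input types of a motif-search study — a proteome FASTA, PTM
# site tables, disordered-region annotations — with controlled statistical
# structure: i.i.d. residues from a chosen background composition, planted
# motif instances with a ground-truth table, PTM sites placed on planted
# acceptor positions with configurable coverage and spurious-site noise.
# Everything is reproducible from an explicit seed.

#' Generate a synthetic proteome
#'
#' Sequences are i.i.d. draws from `composition`, except position 1 which is
#' always `M` (real proteomes have a near-universal initial methionine, and
#' the decoy builder's first-residue rule is exercised this way).
#'
#' @param n_proteins Number of records.
#' @param length Either a single protein length or a `c(min, max)` range
#'   sampled uniformly.
#' @param composition `"uniform"`, `"swissprot"` or a named frequency
#'   vector (see [aa_background()]).
#' @param seed Integer seed (mandatory).
#' @param name Dataset name.
#' @return A [protein_dataset] with accessions `SYN00001`, `SYN00002`, ...
#'   and gene symbols `SYNG1`, `SYNG2`, ...
#' @export
synth_proteome <- function(n_proteins, length = 400L,
                           composition = "uniform", seed,
                           name = "synthetic") {
  if (missing(seed)) stop("seed is mandatory for fixture generation")
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  bg <- aa_background(composition)
  if (!(length(length) %in% c(1L, 2L)) || any(length < 2L)) {
    stop("length must be a single value >= 2 or a c(min, max) range")
  }
  with_seed(seed, {
    lens <- if (base::length(length) == 1L) {
      rep(as.integer(length), n_proteins)
    } else {
      sample(as.integer(length[1]):as.integer(length[2]), n_proteins,
             replace = TRUE)
    }
    seqs <- vapply(lens, function(L) {
      paste0("M", paste(sample(AA20, L - 1L, replace = TRUE, prob = bg),
                        collapse = ""))
    }, character(1))
    protein_dataset(data.frame(
      accession = sprintf("SYN%05d", seq_len(n_proteins)),
      gene = sprintf("SYNG%d", seq_len(n_proteins)),
      description = sprintf("synthetic protein %d", seq_len(n_proteins)),
      sequence = seqs,
      stringsAsFactors = FALSE
    ), name = name)
  })
}

#' Plant motif instances into a proteome
#'
#' Overwrites, in `round(fraction * n)` randomly chosen proteins,
#' `instances_per_protein` sampled instance strings at uniformly chosen
#' spans that avoid position 1 and do not overlap each other, and returns
#' the modified dataset together with a ground-truth table of planted spans.
#'
#' @param dataset A [protein_dataset].
#' @param sampler Function `function(n)` returning `n` instance strings
#'   (e.g. a closure over [sample_motif_instances()]), or a fixed character
#'   string planted verbatim.
#' @param fraction Fraction of proteins receiving instances.
#' @param seed Integer seed (mandatory).
#' @param instances_per_protein Instances planted in each chosen protein.
#' @return A list with `dataset` (modified copy) and `truth` (data.frame
#'   `accession`, `start`, `end`, `instance`).
#' @export
plant_motifs <- function(dataset, sampler, fraction, seed,
                         instances_per_protein = 1L) {
  stopifnot(inherits(dataset, "protein_dataset"))
  if (missing(seed)) stop("seed is mandatory for fixture generation")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (is.character(sampler)) {
    fixed <- sampler
    sampler <- function(n) rep(fixed, n)
  }
  rec <- dataset$records
  n_plant <- round(fraction * nrow(rec))
  truth <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0), instance = character(0),
                      stringsAsFactors = FALSE)
  if (n_plant == 0L) {
    return(list(dataset = dataset, truth = truth))
  }
  out <- with_seed(seed, {
    chosen <- sample(seq_len(nrow(rec)), n_plant)
    t_acc <- character(0)
    t_start <- integer(0)
    t_end <- integer(0)
    t_inst <- character(0)
    for (i in chosen) {
      L <- nchar(rec$sequence[i])
      placed_s <- integer(0)
      placed_e <- integer(0)
      for (k in seq_len(instances_per_protein)) {
        inst <- sampler(1L)
        len <- nchar(inst)
        if (len > L - 1L) stop("instance longer than available sequence")
        for (attempt in 1:100) {
          st <- sample_int_range(2L, L - len + 1L)
          en <- st + len - 1L
          if (all(en < placed_s | st > placed_e)) break
          if (attempt == 100L) stop("no room to place non-overlapping instances")
        }
        substr(rec$sequence[i], st, en) <- inst
        placed_s <- c(placed_s, st)
        placed_e <- c(placed_e, en)
        t_acc <- c(t_acc, rec$accession[i])
        t_start <- c(t_start, st)
        t_end <- c(t_end, en)
        t_inst <- c(t_inst, inst)
      }
    }
    list(rec = rec, truth = data.frame(
      accession = t_acc, start = t_start, end = t_end, instance = t_inst,
      stringsAsFactors = FALSE))
  })
  o <- order(match(out$truth$accession, rec$accession), out$truth$start)
  list(dataset = protein_dataset(out$rec, name = dataset$name),
       truth = out$truth[o, , drop = FALSE])
}

#' Generate a PSP-dialect PTM table for planted instances
#'
#' Places a modification site on the acceptor position of each planted
#' instance with probability `coverage`, plus `Poisson(noise)` spurious
#' sites per protein at random positions, and formats the result in the
#' PhosphoSitePlus modification-site dialect (readable by
#' [load_ptm_psp()]). The recorded residue is always the actual residue at
#' the position.
#'
#' @param truth Truth table from [plant_motifs()].
#' @param dataset The planted [protein_dataset] (residue lookup and noise
#'   placement).
#' @param acceptor_offset 0-based offset of the modified residue within each
#'   planted instance (e.g. 3 when the 4th position is the phospho-acceptor).
#' @param coverage Probability a planted instance receives a site.
#' @param noise Mean number of spurious sites per protein.
#' @param seed Integer seed (mandatory).
#' @param mod_code PSP `MOD_RSD` suffix code (default `"p"`,
#'   phosphorylation).
#' @param path Optional path; when given the table is also written as a
#'   PSP-style TSV with a 3-line preamble.
#' @return Invisibly when written, else visibly: a data.frame in PSP layout
#'   (`GENE`, `ACC_ID`, `MOD_RSD`, `ORGANISM`, `Ambiguous_Site`).
#' @export
synth_ptm_table <- function(truth, dataset, acceptor_offset, coverage = 1,
                            noise = 0, seed, mod_code = "p", path = NULL) {
  stopifnot(inherits(dataset, "protein_dataset"))
  if (missing(seed)) stop("seed is mandatory for fixture generation")
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  seqs <- stats::setNames(dataset$records$sequence, dataset$records$accession)
  tab <- with_seed(seed, {
    acc <- character(0)
    pos <- integer(0)
    if (nrow(truth) > 0) {
      covered <- stats::runif(nrow(truth)) < coverage
      acc <- truth$accession[covered]
      pos <- truth$start[covered] + as.integer(acceptor_offset)
    }
    if (noise > 0) {
      n_spur <- stats::rpois(length(seqs), noise)
      for (i in seq_along(seqs)) {
        if (n_spur[i] > 0) {
          acc <- c(acc, rep(names(seqs)[i], n_spur[i]))
          pos <- c(pos, sample(nchar(seqs[i]), n_spur[i], replace = TRUE))
        }
      }
    }
    data.frame(acc = acc, pos = pos, stringsAsFactors = FALSE)
  })
  residues <- substr(seqs[tab$acc], tab$pos, tab$pos)
  out <- data.frame(
    GENE = tab$acc,
    ACC_ID = tab$acc,
    MOD_RSD = paste0(residues, tab$pos, "-", mod_code),
    ORGANISM = "synthetic",
    Ambiguous_Site = 0L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("synthetic PTM site dataset",
                 "generated by slimscan::synth_ptm_table", ""), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Generate synthetic disordered-region annotations
#'
#' Tiles each protein with non-overlapping `Disordered` intervals of
#' geometric-ish random lengths until about `fraction` of its residues are
#' covered.
#'
#' @param dataset A [protein_dataset].
#' @param fraction Target fraction of residues inside intervals.
#' @param mean_len Mean interval length.
#' @param seed Integer seed (mandatory).
#' @param path Optional path; when given the table is written as a feature
#'   TSV (readable by [read_features()]).
#' @return A feature data.frame (`accession`, `start`, `end`, `type`,
#'   `description`).
#' @export
synth_idr_annotations <- function(dataset, fraction, mean_len = 40, seed,
                                  path = NULL) {
  stopifnot(inherits(dataset, "protein_dataset"))
  if (missing(seed)) stop("seed is mandatory for fixture generation")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  rec <- dataset$records
  tab <- with_seed(seed, {
    acc <- character(0)
    st <- integer(0)
    en <- integer(0)
    # alternate geometric gaps and Poisson-length intervals along the whole
    # sequence; the gap mean is set so expected coverage equals `fraction`
    gap_mean <- if (fraction > 0) mean_len * (1 - fraction) / fraction else Inf
    for (i in seq_len(nrow(rec))) {
      if (fraction == 0) break
      L <- nchar(rec$sequence[i])
      cursor <- 1L
      repeat {
        gap <- if (is.finite(gap_mean) && gap_mean > 0) {
          stats::rgeom(1, 1 / (1 + gap_mean))
        } else {
          0L
        }
        s <- cursor + gap
        if (s > L) break
        len <- max(3L, stats::rpois(1, mean_len))
        e <- min(L, s + len - 1L)
        acc <- c(acc, rec$accession[i])
        st <- c(st, s)
        en <- c(en, e)
        cursor <- e + 2L
        if (cursor > L) break
      }
    }
    data.frame(accession = acc, start = st, end = en, type = "Disordered",
               description = "synthetic disordered region",
               stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# synthetic feature annotations (slimscan)", con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
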