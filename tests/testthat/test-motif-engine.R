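test_that("compile_motif computes groups and length bounds, rejects unsupported syntax", {
  m <- compile_motif("m7", pattern7)
  expect_equal(m$n_groups, 7)
  expect_equal(m$min_len, 7)
  expect_equal(m$max_len, 7)
  expect_equal(m$group_classes[[4]], c("S", "T"))

  m2 <- compile_motif("q", "([ST])(P{1,2})")
  expect_equal(m2$n_groups, 2)
  expect_equal(m2$min_len, 2)
  expect_equal(m2$max_len, 3)

  expect_error(compile_motif("bad", ""), "non-empty")
  expect_error(compile_motif("bad", "A*"), "unbounded")
  expect_error(compile_motif("bad", "A+B"), "unbounded")
  expect_error(compile_motif("bad", "(?=A)"), "look-around")
  expect_error(compile_motif("bad", "\\1"), "\\\\")
  expect_error(compile_motif("bad", "(A"), "unbalanced")
  expect_error(compile_motif("bad", "A)"), "unbalanced")
  expect_error(compile_motif("bad", "A{2,}"), "unbounded")
})

test_that("scan reports greedy per-start matches with truncated flanks", {
  d <- tiny_dataset("AAASTLLA", "A1")
  m <- compile_motif("m7", pattern7)
  # of the two 7-residue windows only [2,8] satisfies [^IRFW][ST] at 3,4
  mm <- scan_motif(d, m, flank_n = 3)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$start, 2)
  expect_equal(mm$end, 8)
  expect_equal(mm$matched, "AASTLLA")
  expect_equal(mm$flank_left, "A")   # truncated at the sequence start
  expect_equal(mm$flank_right, "")
  expect_equal(mm$group_start[[1]], 2:8)
  expect_equal(mm$group_end[[1]], 2:8)

  # empty dataset
  expect_equal(nrow(scan_motif(tiny_dataset("MMMM"), m)), 0)

  # overlap handling on "AA" x "AAAA"
  aa <- compile_motif("aa", "AA")
  d4 <- tiny_dataset("AAAA")
  expect_equal(scan_motif(d4, aa, overlapping = TRUE)$start, c(1, 2, 3))
  expect_equal(scan_motif(d4, aa, overlapping = FALSE)$start, c(1, 3))
})

test_that("matched strings and flank lengths satisfy their invariants", {
  set.seed(11)
  m <- compile_motif("v", "([ST])([ACDEG]{1,3})(L?)")
  for (rep in 1:10) {
    seqv <- random_aa_string(120)
    d <- tiny_dataset(seqv)
    mm <- scan_motif(d, m, flank_n = 4)
    if (nrow(mm) == 0) next
    expect_equal(mm$matched, substr(rep(seqv, nrow(mm)), mm$start, mm$end))
    expect_equal(nchar(mm$flank_left), pmin(4, mm$start - 1))
    expect_equal(nchar(mm$flank_right), pmin(4, nchar(seqv) - mm$end))
    for (i in seq_len(nrow(mm))) {
      gs <- mm$group_start[[i]]
      ge <- mm$group_end[[i]]
      ok <- is.na(gs) | (gs >= mm$start[i] & ge <= mm$end[i] & gs <= ge)
      expect_true(all(ok))
    }
  }
})

test_that("scan agrees with the anchored-at-every-position oracle", {
  set.seed(97)
  for (k in 1:12) {
    pat <- random_supported_pattern()
    m <- compile_motif("r", pat)
    for (j in 1:5) {
      seqv <- random_aa_string(sample(40:200, 1))
      d <- tiny_dataset(seqv)
      for (ov in c(TRUE, FALSE)) {
        got <- scan_motif(d, m, overlapping = ov)
        want <- oracle_scan(seqv, m, overlapping = ov)
        expect_equal(got$start, want$start, info = pat)
        expect_equal(got$end, want$end, info = pat)
      }
    }
  }
})

test_that("non-standard residues never match, including '.' and negated classes", {
  d <- tiny_dataset(c("AXA", "AUA", "ABA", "AZA", "AAA"))
  dot <- compile_motif("dot", "A.A")
  expect_equal(scan_motif(d, dot)$accession, "P00005")
  neg <- compile_motif("neg", "A[^C]A")
  expect_equal(scan_motif(d, neg)$accession, "P00005")
})

test_that("filter_identical keeps one highest-scoring representative per string", {
  d <- tiny_dataset(c("MKASTLLAK", "MKASTLLAW", "MWWSTLLWW"), c("A1", "B2", "C3"))
  m <- compile_motif("m7", pattern7)
  mm <- scan_motif(d, m)
  # A1 and B2 both contain "KASTLLA"
  expect_equal(sum(mm$matched == "KASTLLA"), 2)
  kept <- filter_identical(mm)
  expect_equal(sum(kept$matched == "KASTLLA"), 1)
  expect_equal(kept$accession[kept$matched == "KASTLLA"], "A1") # tie: scan order

  # with scores, the max survives regardless of order
  mm$score <- ifelse(mm$accession == "B2", 80, 60)
  kept <- filter_identical(mm)
  expect_equal(kept$accession[kept$matched == "KASTLLA"], "B2")

  # all distinct -> unchanged
  solo <- subset_distinct <- filter_identical(kept)
  expect_equal(nrow(solo), nrow(kept))
})

test_that("pattern probability follows the closed-form class product", {
  expect_equal(pattern_probability(compile_motif("x", "[ST]")), 2 / 20)
  expect_equal(pattern_probability(compile_motif("x", ".")), 1)
  # (16/20)(2/20)(7/20)(7/20): dots contribute 1, [ILMVFWY] has 7 members
  expect_equal(pattern_probability(compile_motif("x", pattern7)),
               (16 / 20) * (2 / 20) * (7 / 20) * (7 / 20))
  # bounded quantifier sums over expansions: p + p^2 for {1,2}
  p <- 2 / 20
  expect_equal(pattern_probability(compile_motif("x", "[ST]{1,2}")), p + p^2)
  # alternation adds branch probabilities
  expect_equal(pattern_probability(compile_motif("x", "A|C")), 2 / 20)
  # non-uniform background
  bg <- aa_background("swissprot")
  expect_equal(pattern_probability(compile_motif("x", "[ST]"), bg),
               unname(bg["S"] + bg["T"]))
  # expansion-count guard
  expect_error(pattern_probability(compile_motif("x", ".{0,99}.{0,99}.{0,99}"),
                                   max_expansions = 1e5),
               "simplify")
  # summing expansions can exceed 1, with a warning
  expect_warning(v <- pattern_probability(compile_motif("x", ".{1,3}")),
                 "exceed")
  expect_equal(v, 3)
})

test_that("empirical match frequency converges to the analytical probability", {
  set.seed(23)
  m <- compile_motif("m7", pattern7)
  p <- pattern_probability(m)
  n_pos <- 2e5
  seqv <- random_aa_string(n_pos + 6)
  cnt <- nrow(scan_motif(tiny_dataset(seqv), m))
  se <- sqrt(p * (1 - p) / n_pos)
  expect_lt(abs(cnt / n_pos - p), 5 * se)
})

test_that("motif tables round-trip patterns and attached PSSMs", {
  dir <- withr::local_tempdir()
  m <- compile_motif("m7", pattern7)
  pssm <- train_pssm(sample_motif_instances(m, 20), m)
  write_pssm(pssm, file.path(dir, "m7.pssm"))
  writeLines(c("name\tpattern\tpssm",
               paste("m7", pattern7, "m7.pssm", sep = "\t"),
               paste("st", "[ST]P", "", sep = "\t")),
             file.path(dir, "motifs.tsv"))
  motifs <- read_motif_table(file.path(dir, "motifs.tsv"))
  expect_equal(names(motifs), c("m7", "st"))
  expect_equal(motifs$m7$n_groups, 7)
  expect_false(is.null(motifs$m7$pssm))
  expect_null(motifs$st$pssm)
})
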