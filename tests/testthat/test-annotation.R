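write_psp_fixture <- function(path, rows) {
  writeLines(c("synthetic modification sites", "for testing", "",
               paste("GENE", "ACC_ID", "MOD_RSD", "ORGANISM", "Ambiguous_Site",
                     sep = "\t"),
               rows), path)
}

test_that("PSP tables decode MOD_RSD and drop ambiguous sites", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psp_fixture(f, c(
    "G1\tA1\tT5-p\tsyn\t0",
    "G1\tA1\tK9-ub\tsyn\t0",
    "G1\tA1\tS12-p\tsyn\t1",
    "G1\tA2\tS3-p\tsyn\t0",
    "G1\tA2\tbroken\tsyn\t0"
  ))
  expect_warning(sites <- load_ptm_psp(f), "skipped 1 rows")
  expect_equal(nrow(sites), 3) # ambiguous S12 dropped, broken skipped
  expect_equal(sites$position[1], 5)
  expect_equal(sites$residue[1], "T")
  expect_equal(sites$modification[1], "phosphorylation")
  expect_equal(sites$modification[2], "ubiquitination")
  expect_false(any(sites$position == 12))

  suppressWarnings({
    kept <- load_ptm_psp(f, drop_ambiguous = FALSE)
    expect_true(any(kept$position == 12 & kept$ambiguous))
    phos <- load_ptm_psp(f, modification_filter = "Phosphorylation")
    expect_true(all(phos$modification == "phosphorylation"))
  })

  writeLines(c("no", "header", "here"), f)
  expect_error(load_ptm_psp(f), "header")
})

test_that("dbPTM tables flag implausible acceptors and out-of-bounds positions", {
  d <- tiny_dataset("MSAYKT", "A1")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "A1_HUMAN\tA1\t2\tPhosphorylation\t12345",
    "A1_HUMAN\tA1\t3\tPhosphorylation\t12345",
    "A1_HUMAN\tA1\t5\tUbiquitination\t12345",
    "A1_HUMAN\tA1\t99\tPhosphorylation\t12345"
  ), f)
  sites <- load_ptm_dbptm(f, validate_residue = TRUE, proteome = d)
  expect_equal(nrow(sites), 4)
  expect_false(sites$implausible[1]) # S2 phospho plausible
  expect_true(sites$implausible[2])  # A3 phospho implausible
  expect_false(sites$implausible[3]) # K5 ubiquitin plausible
  expect_true(sites$out_of_bounds[4])

  strict <- load_ptm_dbptm(f, validate_residue = TRUE, proteome = d,
                           strict = TRUE)
  expect_equal(nrow(strict), 2)
})

test_that("PTM containment respects scope and 1-based inclusive boundaries", {
  d <- tiny_dataset("AAASTLLA", "A1")
  m <- compile_motif("m7", pattern7)
  mm <- scan_motif(d, m) # one match [2,8], group g spans [g+1, g+1]
  site_at <- function(pos) data.frame(
    accession = "A1", position = pos, residue = substr("AAASTLLA", pos, pos),
    modification = "phosphorylation", source = "psp", ambiguous = FALSE,
    stringsAsFactors = FALSE
  )
  expect_true(annotate_ptm(mm, site_at(5))$ptm_connected)
  expect_true(annotate_ptm(mm, site_at(2))$ptm_connected) # span start
  expect_true(annotate_ptm(mm, site_at(8))$ptm_connected) # span end
  expect_false(annotate_ptm(mm, site_at(1))$ptm_connected)

  # group scope: site 5 sits in group 4 ([5,5]) but not group 5 ([6,6])
  expect_true(annotate_ptm(mm, site_at(5), scope = 4)$ptm_connected)
  expect_false(annotate_ptm(mm, site_at(5), scope = 5)$ptm_connected)
  expect_error(annotate_ptm(mm, site_at(5), scope = 9), "out of range")

  # modification filter
  ub <- site_at(5)
  ub$modification <- "ubiquitination"
  expect_false(annotate_ptm(mm, ub,
                            modification_filter = "phosphorylation")$ptm_connected)
})

test_that("filter_without_connections keeps exactly the connected matches", {
  d <- tiny_dataset(c("MKASTLLAK", "MKASTILAK", "MKTSTLLAK"),
                    c("A1", "A2", "A3"))
  m <- compile_motif("m7", pattern7)
  mm <- scan_motif(d, m)
  expect_error(filter_without_connections(mm), "annotate_ptm")
  sites <- data.frame(accession = "A2", position = 4, residue = "S",
                      modification = "phosphorylation", source = "psp",
                      ambiguous = FALSE, stringsAsFactors = FALSE)
  ann <- annotate_ptm(mm, sites)
  kept <- filter_without_connections(ann)
  expect_true(all(kept$accession == "A2"))
  expect_equal(nrow(kept), sum(ann$ptm_connected))

  # brute-force join oracle on the same fixture
  brute <- vapply(seq_len(nrow(mm)), function(i) {
    any(sites$accession == mm$accession[i] &
          sites$position >= mm$start[i] & sites$position <= mm$end[i])
  }, logical(1))
  expect_equal(ann$ptm_connected, brute)

  all_sites <- data.frame(accession = c("A1", "A2", "A3"), position = 4,
                          residue = "S", modification = "phosphorylation",
                          source = "psp", ambiguous = FALSE,
                          stringsAsFactors = FALSE)
  expect_equal(nrow(filter_without_connections(annotate_ptm(mm, all_sites))),
               nrow(mm))
  none <- all_sites
  none$position <- 1
  expect_equal(nrow(filter_without_connections(annotate_ptm(mm, none))), 0)
})

test_that("IDR overlap percentages count covered positions inclusively", {
  d <- tiny_dataset(strrep("A", 30), "A1")
  mm <- scan_motif(d, compile_motif("m7", pattern7)) # no match; build by hand
  d2 <- tiny_dataset("AAASTLLAAAAAAAAAAAAAAAAAAAAAAA", "A1")
  m <- compile_motif("m7", pattern7)
  mm <- scan_motif(d2, m)
  mm <- subset_match_first(mm)
  feats <- data.frame(accession = "A1", start = 5, end = 20,
                      type = "Disordered", description = NA,
                      stringsAsFactors = FALSE)
  ann <- annotate_idr(mm, feats)
  expect_equal(ann$idr_overlap_percent, round(100 * 4 / 7, 1)) # 57.1

  inside <- data.frame(accession = "A1", start = 1, end = 30,
                       type = "Disordered", description = NA,
                       stringsAsFactors = FALSE)
  expect_equal(annotate_idr(mm, inside)$idr_overlap_percent, 100)
  other <- inside
  other$accession <- "ZZ"
  expect_equal(annotate_idr(mm, other)$idr_overlap_percent, 0)

  # merging overlapping intervals does not change the result
  split2 <- data.frame(accession = "A1", start = c(5, 6), end = c(10, 20),
                       type = "Disordered", description = NA,
                       stringsAsFactors = FALSE)
  expect_equal(annotate_idr(mm, split2)$idr_overlap_percent,
               ann$idr_overlap_percent)
})

test_that("feature intersection uses inclusive coordinates and sorted output", {
  d <- tiny_dataset("AAASTLLAAA", "A1")
  m <- compile_motif("m7", pattern7)
  mm <- scan_motif(d, m) # match [2,8]
  mm <- subset_match_first(mm)
  feats <- data.frame(
    accession = "A1",
    start = c(1, 8, 9, 3),
    end = c(1, 9, 10, 6),
    type = c("Domain", "Region", "Domain", "Binding site"),
    description = c("adjacent-left", "tail", "outside", "core"),
    stringsAsFactors = FALSE
  )
  ann <- annotate_features(mm, feats)
  hit <- ann$features[[1]]
  # [1,1] ends at start-1 -> excluded; [9,10] begins at end+1 -> excluded
  expect_equal(hit$description, c("core", "tail"))
  expect_equal(hit$start, c(3, 8))
})

test_that("auxiliary co-search marks proteins carrying a second motif", {
  seqs <- c("MKASTLLAKWWCWHWCY", "MKASTILAKAAAAAAAA")
  d <- tiny_dataset(seqs, c("A1", "A2"))
  prim <- compile_motif("m7", pattern7)
  aux <- compile_motif("aux", "WWCWHWCY")
  pm <- scan_motif(d, prim)
  ann <- annotate_auxiliary(pm, d, aux)
  expect_true(all(ann$aux_found[ann$accession == "A1"]))
  expect_false(any(ann$aux_found[ann$accession == "A2"]))
  expect_true(all(ann$aux_count[ann$accession == "A1"] == 1))

  filt <- annotate_auxiliary(pm, d, aux, filter = TRUE)
  expect_true(all(filt$accession == "A1"))

  # score threshold: of two auxiliary matches scoring differently, only the
  # one above threshold counts and sets aux_best_score
  set.seed(77)
  aux2 <- compile_motif("aux2", "([ST])([ILMV])([ACDE])")
  inst <- sample_motif_instances(aux2, 60,
                                 group_probs = list(c(S = 0.9, T = 0.1),
                                                    c(L = 0.8, I = 0.2),
                                                    c(A = 0.8, D = 0.2)))
  p2 <- train_pssm(inst, aux2)
  host <- tiny_dataset("MKASTLLAKWWWSLAWWWTVEWWW", "H1")
  aux_sc <- predict(p2, scan_motif(host, aux2))
  expect_equal(length(aux_sc), 2) # SLA and TVE
  thr <- mean(aux_sc)
  aux2$pssm <- p2
  pm2 <- scan_motif(host, prim)
  ann2 <- annotate_auxiliary(pm2, host, aux2, aux_threshold = thr)
  expect_true(all(ann2$aux_count == 1))
  expect_equal(unique(ann2$aux_best_score), max(aux_sc))

  expect_error(annotate_auxiliary(pm2, host, compile_motif("u", "[ST]LA"),
                                  aux_threshold = 50), "PSSM")
})
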