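test_that("iupac_match implements the degenerate code sets", {
  expect_true(iupac_match("A", "W"))
  expect_false(iupac_match("G", "Y"))
  expect_true(iupac_match("C", "n"))
  expect_true(all(iupac_match(c("A", "C", "G", "T"), "N")))
  expect_error(iupac_match("A", "Z"), "undefined")
})

test_that("a planted CTCF 19-mer is recovered as one exact width-19 hit", {
  withr::with_seed(11, {
    bg <- random_dna(40)
  })
  ctcf <- "TTACCTCTAGGTGCCAGCC"
  s <- paste0(substr(bg, 1, 10), ctcf, substr(bg, 30, 40))
  hits <- scan_motif(s, consensus_motif("CTCF-MGMT", ctcf), strands = "+")
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(11L, 29L))
  expect_equal(hits$end - hits$start + 1L, 19L)
  expect_equal(hits$mismatches, 0L)
})

test_that("the ARE core matches with internal wildcards and overlaps AP1", {
  are <- scan_motif("TGACTCAGC", consensus_motif("ARE", "TGACNNNGC"),
                    strands = "+")
  expect_equal(nrow(are), 1L)
  expect_equal(are$mismatches, 0L)
  ap1 <- scan_motif("TGACTCAGC", consensus_motif("AP1", "TGACTCA"),
                    strands = "+")
  expect_equal(ap1$start, 1L)  # AP1 site nested at the ARE 5' end
  expect_lte(ap1$end, are$end)
})

test_that("no E-box hits arise in poly-A sequence", {
  hits <- scan_motif(strrep("A", 60), consensus_motif("E-box", "CACGTG"))
  expect_equal(nrow(hits), 0L)
})

test_that("exclusion patterns veto windows that match the main pattern", {
  tata532 <- dplyr::filter(motif_catalog(), name == "TATA-532")
  blocked <- scan_motif("CATTTTAA", tata532, strands = "+")
  expect_equal(nrow(blocked), 0L)  # matches exclusion CAYTTTWR
  allowed <- scan_motif("TATAAAAA", tata532, strands = "+")
  expect_equal(nrow(allowed), 1L)
  # cross-check both decisions against the brute-force oracle
  for (s in c("CATTTTAA", "TATAAAAA")) {
    o <- oracle_scan(s, tata532$pattern, tata532$exclusions[[1]])
    got <- scan_motif(s, tata532, strands = "+")
    expect_equal(nrow(got), sum(o$strand == "+"))
  }
})

test_that("every unambiguous catalog motif planted in background is recovered", {
  cat0 <- dplyr::filter(motif_catalog(),
                        !grepl("[RYSWKMBDHVN]", pattern))
  withr::with_seed(23, {
    gap <- 25L
    pieces <- character()
    truth <- integer()
    pos <- 1L
    for (i in seq_len(nrow(cat0))) {
      bg <- random_dna(gap, gc = 0.2)
      pieces <- c(pieces, bg, cat0$pattern[i])
      truth <- c(truth, pos + gap)
      pos <- pos + gap + nchar(cat0$pattern[i])
    }
    s <- paste(c(pieces, random_dna(gap, gc = 0.2)), collapse = "")
  })
  hits <- scan_catalog(s, cat0)
  for (i in seq_len(nrow(cat0))) {
    hi <- dplyr::filter(hits, motif == cat0$name[i],
                        start == truth[i])
    expect_gte(nrow(hi), 1L)
  }
})

test_that("catalog scanning rejects duplicate motif names and empty input", {
  dup <- dplyr::bind_rows(consensus_motif("ARE", "TGACNNNGC"),
                          consensus_motif("ARE", "TGACTCA"))
  expect_error(scan_catalog("ACGT", dup), "duplicate")
  expect_equal(nrow(scan_catalog("", motif_catalog())), 0L)
})

test_that("distinct-site counting merges nested GAGA windows", {
  hits <- tibble::tibble(seqnames = "s", start = c(1L, 1L, 2L),
                         end = c(5L, 6L, 6L), strand = "+")
  expect_equal(count_distinct_sites(hits, "merge_overlapping"), 1L)
  expect_equal(count_distinct_sites(hits, "all"), 3L)
  disjoint <- tibble::tibble(seqnames = "s", start = c(1L, 10L),
                             end = c(5L, 14L), strand = "+")
  expect_equal(count_distinct_sites(disjoint, "all"), 2L)
  expect_equal(count_distinct_sites(disjoint, "merge_overlapping"), 2L)

  gaf <- scan_catalog("GAGAGAGA",
                      dplyr::filter(motif_catalog(), grepl("GAF", name)),
                      strands = "+")
  expect_gt(nrow(gaf), 1L)
  expect_equal(count_distinct_sites(gaf, "merge_overlapping"), 1L)
})

test_that("scanning agrees exactly with the brute-force oracle", {
  withr::with_seed(101, {
    s <- random_dna(2000, gc = 0.55)
  })
  for (mot in list(c("INR", "YYANWYY", 0), c("DTIE", "GBBRDNHGG", 1),
                   c("E-box", "CACGTG", 1))) {
    m <- consensus_motif(mot[1], mot[2], max_mismatches = as.integer(mot[3]))
    got <- scan_motif(s, m)
    want <- oracle_scan(s, mot[2], budget = as.integer(mot[3]))
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("strand symmetry: minus-strand scan equals scanning the revcomp pattern", {
  withr::with_seed(5, s <- random_dna(1500))
  m <- consensus_motif("DPE", "RGWCGTG")
  minus <- scan_motif(s, m, strands = "-")
  plus_rc <- scan_motif(s, consensus_motif("DPE-rc", reverse_complement("RGWCGTG")),
                        strands = "+")
  expect_equal(minus$start, plus_rc$start)
  expect_equal(minus$mismatches, plus_rc$mismatches)
})

test_that("hit sets are monotone in the mismatch budget and case-insensitive", {
  withr::with_seed(9, s <- random_dna(800))
  key <- function(h) paste(h$start, h$strand)
  prev <- character()
  for (k in 0:2) {
    hits <- scan_motif(s, consensus_motif("BRE", "SSRCGCC"), max_mismatches = k)
    expect_true(all(prev %in% key(hits)))
    prev <- key(hits)
  }
  expect_equal(scan_motif(tolower(s), consensus_motif("BRE", "SSRCGCC")),
               scan_motif(s, consensus_motif("BRE", "SSRCGCC")))
})

test_that("subject N never satisfies a non-N pattern position", {
  hits <- scan_motif("CACNTG", consensus_motif("E-box", "CACGTG"), strands = "+")
  expect_equal(nrow(hits), 0L)
  hits1 <- scan_motif("CACNTG", consensus_motif("E-box", "CACGTG"),
                      strands = "+", max_mismatches = 1)
  expect_equal(hits1$mismatches, 1L)
})

test_that("a catalog config file round-trips through the plain-text format", {
  cfg <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    name = c("TATA-532", "ARE"),
    pattern = c("HWHWWWWR", "TGACNNNGC"),
    exclusions = c("HTYTTTWR;CAYTTTWR;MAMAAAAR;CTYAAAAR", ""),
    max_mismatches = c(0L, 0L)), cfg)
  cat2 <- read_motif_catalog(cfg)
  expect_equal(nrow(cat2), 2L)
  expect_equal(cat2$exclusions[[1]],
               c("HTYTTTWR", "CAYTTTWR", "MAMAAAAR", "CTYAAAAR"))
  expect_equal(scan_motif("CATTTTAA", cat2[1, ], strands = "+") |> nrow(), 0L)
})
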