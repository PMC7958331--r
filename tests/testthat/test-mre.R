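test_that("hybridization closed forms hold", {
  model <- energy_model()
  h <- hybridize("AAAAAAA", "UUUUUUU", quiet = TRUE)
  expect_equal(h$mfe, 7 * model$au)
  expect_equal(nrow(h$structure), 7L)

  none <- hybridize("AAAA", "AAAA", quiet = TRUE)
  expect_equal(none$mfe, 0)
  expect_equal(nrow(none$structure), 0L)

  gc <- hybridize("GGGG", "CCCC", quiet = TRUE)
  expect_equal(gc$mfe, 4 * model$gc)
})

test_that("the DP equals exhaustive structure enumeration on small instances", {
  withr::with_seed(61, {
    for (r in 1:6) {
      mir <- random_rna(sample(6:8, 1))
      win <- random_rna(sample(10:12, 1))
      expect_equal(hybridize(mir, win, quiet = TRUE)$mfe,
                   oracle_duplex_mfe(mir, win),
                   info = paste(mir, win))
    }
  })
})

test_that("mfe decreases as pair energies strengthen", {
  withr::with_seed(67, {
    mir <- random_rna(12)
    win <- random_rna(30)
  })
  weak <- hybridize(mir, win, energy_model(gc = -1, au = -0.5, gu = -0.25),
                    quiet = TRUE)$mfe
  strong <- hybridize(mir, win, energy_model(gc = -4, au = -3, gu = -2),
                      quiet = TRUE)$mfe
  expect_lte(strong, weak)
})

test_that("duplexes never pair within one molecule and positions are monotone", {
  withr::with_seed(71, {
    mir <- random_rna(15)
    win <- random_rna(40)
  })
  h <- hybridize(mir, win, quiet = TRUE)
  st <- h$structure
  expect_true(all(diff(st$mir_pos) >= 1))
  expect_true(all(diff(st$target_pos) <= -1))  # antiparallel
  expect_true(all(st$mir_pos %in% seq_len(nchar(mir))))
  expect_true(all(st$target_pos %in% seq_len(nchar(win))))
})

test_that("seed matching finds perfect complements and nothing in poly-A", {
  # mir positions 2-8 are GAGGUAG; its reverse complement is CUACCUC
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  target <- paste0("AAAAACUACCUCAAAAA")
  hits <- seed_sites(mir, target)
  expect_true(6 %in% hits$position)
  expect_equal(hits$class[hits$position == 6], "7mer")
  expect_equal(nrow(seed_sites("AAAAAAAA", strrep("A", 30))), 0L)
})

test_that("seed matching agrees with a brute-force complement scan", {
  withr::with_seed(73, {
    mir <- random_rna(20)
    tgt <- random_rna(500)
  })
  seed <- substr(mir, 2, 8)
  rc <- reverse_complement(seed, rna = TRUE)
  brute <- which(vapply(1:(nchar(tgt) - 6), function(i)
    substr(tgt, i, i + 6) == rc, TRUE))
  got <- seed_sites(mir, tgt, classes = "7mer")
  expect_equal(got$position, brute)
})

test_that("planted complementary sites are recovered as ranked sites", {
  withr::with_seed(79, {
    mir <- mature_mirs()[8, ]  # 22-nt miR
    site <- chartr("U", "T", reverse_complement(mir$seq))
    tgt <- paste0(random_dna(150), site, random_dna(100), site, random_dna(150))
  })
  sites <- scan_transcript(mir, tgt, max_sites = 10)
  # both planted sites are reported, and they are the two strongest
  # (weaker incidental background sites may follow them)
  expect_true(all(c(151L, 273L) %in% sites$start))
  top2 <- sites$start[order(sites$mfe)][1:2]
  expect_setequal(top2, c(151L, 273L))
  # max_sites = 1 keeps the single best
  one <- scan_transcript(mir, tgt, max_sites = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mfe, min(sites$mfe))
})

test_that("site selection does not pad beyond genuine sites", {
  withr::with_seed(83, {
    mir <- seq_tbl(c(m = "ACGUACGUACGUACGUACGU"), alphabet = "RNA")
    site <- chartr("U", "T", reverse_complement(mir$seq))
    tgt <- paste0(strrep("A", 200), site, strrep("A", 200))
  })
  sites <- scan_transcript(mir, tgt, max_sites = 5, energy_cutoff = -30)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 201L)
})

test_that("selected sites are pairwise disjoint; dropping the best promotes the runner-up", {
  withr::with_seed(89, {
    mir <- mature_mirs()[7, ]
    site <- chartr("U", "T", reverse_complement(mir$seq))
    tgt <- paste0(random_dna(100), site, random_dna(80), site, random_dna(100))
  })
  sites <- scan_transcript(mir, tgt, max_sites = 10)
  if (nrow(sites) > 1) {
    for (i in 2:nrow(sites)) {
      expect_true(sites$end[i] < sites$start[i - 1] ||
                    sites$start[i] > sites$end[i - 1])
    }
  }
  # mask the best site and re-scan: previous second-best surfaces first
  best <- sites[which.min(sites$mfe), ]
  masked <- tgt
  substr(masked, best$start, best$end) <- strrep("A", best$end - best$start + 1)
  re <- scan_transcript(mir, masked, max_sites = 1)
  second <- sites[order(sites$mfe), ][2, ]
  expect_equal(re$start, second$start)
})

test_that("sites map to the features containing their leftmost position", {
  ann <- tibble::tibble(transcript_id = "tx",
                        label = c("5'UTR", "CDS", "3'UTR"),
                        start = c(1L, 27L, 708L), end = c(26L, 707L, 1200L))
  sites <- tibble::tibble(mir_id = "m", target_id = "tx",
                          start = c(908L, 1L, 30L), end = c(928L, 21L, 50L),
                          mfe = c(-20, -18, -15), n_pairs = 20L,
                          structure = list(NULL, NULL, NULL))
  mapped <- map_to_features(sites, ann)
  expect_equal(mapped$feature, c("3'UTR", "5'UTR", "CDS"))
  counts <- feature_counts(mapped)
  expect_equal(sum(counts$n_sites), 3L)
  # out-of-span position
  far <- dplyr::mutate(sites[1, ], start = 5000L)
  expect_warning(m2 <- map_to_features(far, ann), "outside")
  expect_equal(m2$feature, "unannotated")
})

test_that("per-feature counts conserve the total site count", {
  ann <- tibble::tibble(transcript_id = "tx",
                        label = c("5'UTR", "exon-2", "CDS", "3'UTR"),
                        start = c(1L, 101L, 201L, 501L),
                        end = c(100L, 200L, 500L, 900L))
  sites <- tibble::tibble(mir_id = "m", target_id = "tx",
                          start = c(10L, 120L, 250L, 350L, 600L),
                          end = start + 18L, mfe = -15, n_pairs = 15L,
                          structure = vector("list", 5))
  counts <- feature_counts(map_to_features(sites, ann))
  expect_equal(sum(counts$n_sites), 5L)
  expect_equal(sort(unique(counts$feature)),
               sort(c("5'UTR", "exon-2", "CDS", "3'UTR")))
})

test_that("Poisson multi-site tail matches its closed forms and series", {
  lam <- 0.7
  expect_equal(multi_site_pvalue(1, lam), 1 - exp(-lam))
  expect_equal(multi_site_pvalue(0, lam), 1.0)
  for (k in 0:20) {
    # tail series summed directly in log space (stable for large k, where
    # 1 - sum(head terms) would cancel catastrophically)
    i <- k:(k + 400)
    series <- sum(exp(i * log(lam) - lam - lgamma(i + 1)))
    expect_equal(multi_site_pvalue(k, lam), series, tolerance = 1e-12)
  }
})

test_that("DNA input is transcribed to RNA with a notice", {
  expect_message(h <- hybridize("AAAAAAA", "TTTTTTT"), "T -> U")
  expect_equal(h$mfe, 7 * energy_model()$au)
})
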