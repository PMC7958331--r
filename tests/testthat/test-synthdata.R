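test_that("identical specs produce byte-identical files", {
  plants <- tibble::tibble(type = "motif", name = "ctcf", position = 501L,
                           pattern = "TTACCTCTAGGTGCCAGCC", mismatches = 0L)
  spec <- simulation_spec(rng_seed = 424242L, length = 2000L,
                          gc_fraction = 0.45, plants = plants)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_simulation(simulate_sequence(spec), d1)
  f2 <- write_simulation(simulate_sequence(spec), d2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
})

test_that("background GC fraction is realised empirically", {
  withr::with_seed(131, s <- synth_background(100000, 0.6))
  ch <- strsplit(s, "")[[1]]
  gc <- mean(ch %in% c("C", "G"))
  expect_gt(gc, 0.59)
  expect_lt(gc, 0.61)
  expect_true(all(ch %in% c("A", "C", "G", "T")))
})

test_that("a planted motif appears verbatim at its truth coordinates", {
  plants <- tibble::tibble(type = "motif", name = "ctcf", position = 501L,
                           pattern = "TTACCTCTAGGTGCCAGCC", mismatches = 0L)
  sim <- simulate_sequence(simulation_spec(77L, 2000L, 0.5, plants))
  tr <- sim$truth
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$start, tr$end), c(501L, 519L))
  expect_equal(substr(sim$seq$seq, tr$start, tr$end), tr$planted)
  # and the scanner closes the loop at zero mismatches
  hits <- scan_motif(sim$seq, consensus_motif("CTCF", "TTACCTCTAGGTGCCAGCC"),
                     strands = "+")
  expect_true(any(hits$start == 501L & hits$mismatches == 0L))
})

test_that("mismatched instances violate the pattern at exactly k positions", {
  withr::with_seed(137, {
    for (k in 0:3) {
      inst <- plant_mismatched_instance("RRRCWWGYYY", k)
      mm <- sum(!iupac_match(strsplit(inst, "")[[1]],
                             strsplit("RRRCWWGYYY", "")[[1]]))
      expect_equal(mm, k)
    }
  })
})

test_that("a k=1 instance is missed at budget 0 but found at budget 1", {
  withr::with_seed(139, {
    inst <- plant_mismatched_instance("RRRCWWGYYY", 1L)
    s <- paste0(strrep("T", 30), inst, strrep("T", 30))
  })
  m0 <- consensus_motif("half", "RRRCWWGYYY", max_mismatches = 0L)
  m1 <- consensus_motif("half", "RRRCWWGYYY", max_mismatches = 1L)
  expect_false(any(scan_motif(s, m0, strands = "+")$start == 31L))
  found <- scan_motif(s, m1, strands = "+")
  expect_true(any(found$start == 31L & found$mismatches == 1L))
})

test_that("all-N patterns admit no mismatched positions", {
  expect_error(plant_mismatched_instance("NNNN", 1L), "at most 0")
  expect_error(plant_mismatched_instance("ACG", 4L), "exceed")
})

test_that("synthetic CpG blocks hit their composition targets", {
  withr::with_seed(149, {
    for (tgt in list(c(90, 1.8), c(65, 1.1), c(60, 0.7))) {
      b <- synth_cgi_block(400, tgt[1], tgt[2])
      st <- region_stats(b)
      expect_lte(abs(st$gc_percent - tgt[1]), 2)
      expect_lte(abs(st$obs_exp_cpg - tgt[2]), 0.06)
    }
  })
})

test_that("ill-fitting or overlapping plants are rejected before output", {
  p_off <- tibble::tibble(type = "motif", name = "m", position = 1995L,
                          pattern = "TTACCTCTAGGTGCCAGCC", mismatches = 0L)
  expect_error(simulate_sequence(simulation_spec(1L, 2000L, 0.5, p_off)),
               "fit")
  p_olap <- tibble::tibble(type = "motif", name = c("a", "b"),
                           position = c(100L, 110L),
                           pattern = "TTACCTCTAGGTGCCAGCC", mismatches = 0L)
  expect_error(simulate_sequence(simulation_spec(1L, 2000L, 0.5, p_olap)),
               "overlap")
})

test_that("dimer and cgi plants realise with the declared geometry", {
  plants <- tibble::tibble(
    type = c("dimer", "cgi"), name = c("p53", "island"),
    position = c(101L, 501L),
    pattern = c("RRRCWWGYYY", NA), mismatches = c(0L, NA),
    mismatches2 = c(0L, NA), spacer = c(5L, NA),
    length = c(NA, 400L), gc_percent = c(NA, 80), obs_exp = c(NA, 1.5))
  sim <- simulate_sequence(simulation_spec(211L, 1200L, 0.3, plants))
  tr <- sim$truth
  expect_equal(tr$end[tr$name == "p53"] - tr$start[tr$name == "p53"] + 1L, 25L)
  best <- best_dimer_match(sim$seq)
  expect_equal(best$mm_total, 0L)
  expect_equal(best$start, 101L)
  isl <- detect_cpg_islands(sim$seq)
  expect_gte(nrow(isl), 1L)
  top <- isl[which.max(isl$length), ]
  inter <- min(top$end, 900) - max(top$start, 501) + 1
  expect_gte(inter / 400, 0.9)
})
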