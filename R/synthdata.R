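# Seeded generator of synthetic sequences with planted regulatory structure
# and ground-truth records.  Background is i.i.d. with a chosen GC fraction;
# CpG-island-like blocks control the dinucleotide statistic directly via a
# composition-preserving swap search.  Every draw flows through the seed in
# the simulation specification, so identical specifications give
# byte-identical output.

#' Random background sequence
#'
#' @param length sequence length in bp.
#' @param gc_fraction probability of drawing C or G at each position.
#' @return a DNA string.
#' @export
synth_background <- function(length, gc_fraction = 0.5) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Concrete motif instance with a fixed mismatch count
#'
#' Draws a string matching an IUPAC pattern at exactly
#' `length(pattern) - k` positions: the `k` chosen positions receive a base
#' violating their code, all others a base satisfying it.  Deterministic
#' under the session RNG; wrap in `withr::with_seed()` for a fixed draw.
#'
#' @param pattern IUPAC string.
#' @param k number of mismatched positions.
#' @return instance string.
#' @export
plant_mismatched_instance <- function(pattern, k = 0L) {
  pm <- seq_to_masks(pattern, "pattern")
  L <- length(pm)
  if (k > L) abort("k cannot exceed the pattern length")
  bases <- c("A", "C", "G", "T")
  can_miss <- which(pm != 15L)  # an N position admits no mismatch
  if (k > length(can_miss)) {
    abort(sprintf("pattern admits at most %d mismatched position(s)",
                  length(can_miss)))
  }
  miss <- if (k > 0) sample(can_miss, k) else integer()
  vapply(seq_len(L), function(i) {
    allowed <- bases[bitwAnd(.iupac_masks[bases], pm[i]) == .iupac_masks[bases]]
    pool <- if (i %in% miss) setdiff(bases, allowed) else allowed
    pool[sample.int(length(pool), 1L)]
  }, character(1)) |> paste(collapse = "")
}

#' CpG-island-like block with controlled composition
#'
#' Builds a block whose base composition matches the target %G+C exactly
#' (up to rounding), then moves the CpG dinucleotide count toward the
#' target Obs/Exp ratio by a bounded local swap search; errors after
#' `max_iter` swaps rather than looping forever.  Works for enriched
#' (Obs/Exp up to the geometric maximum, 2.0 for a pure-CG block) and
#' depleted targets alike.
#'
#' @param length block length (bp).
#' @param gc_percent target %G+C.
#' @param obs_exp target Obs/Exp CpG ratio.
#' @param tol_gc,tol_oe acceptance tolerances.
#' @param max_iter swap-attempt cap.
#' @return a DNA string meeting the tolerances.
#' @export
synth_cgi_block <- function(length, gc_percent = 65, obs_exp = 1.0,
                            tol_gc = 2, tol_oe = 0.05, max_iter = 50000L) {
  nGC <- round(gc_percent / 100 * length)
  nC <- nGC %/% 2L; nG <- nGC - nC
  nA <- (length - nGC) %/% 2L; nT <- length - nGC - nA
  chars <- sample(c(rep("C", nC), rep("G", nG), rep("A", nA), rep("T", nT)))
  k_target <- round(obs_exp * nC * nG / length)
  cpg_count <- function(x) sum(x[-length(x)] == "C" & x[-1] == "G")
  # CpG starts touched by a change at position i
  local_cpg <- function(x, i) {
    idx <- unique(pmax(1L, pmin(length(x) - 1L, c(i - 1L, i))))
    sum(x[idx] == "C" & x[idx + 1L] == "G")
  }
  cc <- cpg_count(chars)
  ok <- function(cc) {
    oe <- if (nC * nG > 0) cc / ((nC * nG) / length) else 0
    abs(oe - obs_exp) <= tol_oe
  }
  iter <- 0L
  while (!ok(cc)) {
    iter <- iter + 1L
    if (iter > max_iter) {
      abort(sprintf(
        "could not reach %%GC = %.1f, Obs/Exp = %.2f within %d swap attempts",
        gc_percent, obs_exp, max_iter))
    }
    i <- sample.int(length, 1L); j <- sample.int(length, 1L)
    if (chars[i] == chars[j]) next
    before <- local_cpg(chars, i) + local_cpg(chars, j)
    tmp <- chars[i]; chars[i] <- chars[j]; chars[j] <- tmp
    after <- local_cpg(chars, i) + local_cpg(chars, j)
    cc_new <- cc + (after - before)
    # positions adjacent to both i and j are counted twice; recount if close
    if (abs(i - j) <= 2L) cc_new <- cpg_count(chars)
    if (abs(cc_new - k_target) <= abs(cc - k_target)) {
      cc <- cc_new
    } else {
      tmp <- chars[i]; chars[i] <- chars[j]; chars[j] <- tmp
    }
  }
  s <- paste(chars, collapse = "")
  st <- region_stats(s)
  if (abs(st$gc_percent - gc_percent) > tol_gc) {
    abort("rounded composition misses the %GC tolerance; use a longer block")
  }
  s
}

#' Simulation specification
#'
#' @param rng_seed integer seed; identical specs give identical output.
#' @param length total sequence length (bp).
#' @param gc_fraction background GC fraction.
#' @param plants tibble of plant directives with columns `type` (one of
#'   "motif", "dimer", "cgi", "mre"), `name`, `position` (1-based start)
#'   and type-specific columns: `pattern` + `mismatches` (motif; for
#'   "dimer" the half-site pattern with `spacer` and per-half mismatches
#'   `mismatches`/`mismatches2`), `length` + `gc_percent` + `obs_exp`
#'   (cgi), `mir` + `mismatches` (mre: the reverse complement of the miRNA
#'   is planted as DNA).
#' @return spec list of class `simulation_spec`.
#' @export
simulation_spec <- function(rng_seed, length, gc_fraction = 0.5,
                            plants = NULL) {
  stopifnot(length > 0, gc_fraction >= 0, gc_fraction <= 1)
  plants <- plants %||% tibble(type = character(), name = character(),
                               position = integer())
  structure(list(rng_seed = as.integer(rng_seed), length = as.integer(length),
                 gc_fraction = gc_fraction, plants = as_tibble(plants)),
            class = "simulation_spec")
}

# realise one plant directive as a concrete string
realise_plant <- function(p) {
  switch(p$type,
         motif = plant_mismatched_instance(p$pattern, p$mismatches %||% 0L),
         dimer = {
           sp <- p$spacer %||% 0L
           paste0(plant_mismatched_instance(p$pattern, p$mismatches %||% 0L),
                  plant_mismatched_instance(strrep("N", sp), 0L),
                  plant_mismatched_instance(p$pattern, p$mismatches2 %||% 0L))
         },
         cgi = synth_cgi_block(p$length, p$gc_percent %||% 65,
                               p$obs_exp %||% 1.0),
         mre = {
           site <- chartr("U", "T", reverse_complement(p$mir))
           plant_with_mm <- plant_mismatched_instance(site, p$mismatches %||% 0L)
           plant_with_mm
         },
         abort(sprintf("unknown plant type '%s'", p$type)))
}

#' Generate a synthetic sequence with planted regulatory structure
#'
#' Draws an i.i.d. background at the requested GC fraction, writes each plant
#' at its recorded position, and returns the sequence together with
#' ground-truth interval records.  Plants must fit inside the sequence and
#' not overlap one another; violations raise an error before any output.
#'
#' @param spec [simulation_spec()].
#' @return list with `seq` (one-row sequence tibble, id "synthetic") and
#'   `truth` (tibble: `name`, `type`, `seqnames`, `start`, `end`, `strand`,
#'   `planted`).
#' @export
simulate_sequence <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$rng_seed, {
    background <- synth_background(spec$length, spec$gc_fraction)
    plants <- spec$plants
    truth <- NULL
    s <- background
    if (nrow(plants) > 0) {
      instances <- map(seq_len(nrow(plants)),
                       function(i) realise_plant(as.list(plants[i, ])))
      starts <- plants$position
      ends <- starts + nchar(unlist(instances)) - 1L
      if (any(ends > spec$length) || any(starts < 1)) {
        abort("plant does not fit inside the sequence")
      }
      o <- order(starts)
      if (any(starts[o][-1] <= ends[o][-length(o)])) {
        abort("plants overlap; adjust positions")
      }
      for (i in seq_along(instances)) {
        substr(s, starts[i], ends[i]) <- instances[[i]]
      }
      truth <- tibble(name = plants$name, type = plants$type,
                      seqnames = "synthetic", start = as.integer(starts),
                      end = as.integer(ends), strand = "+",
                      planted = unlist(instances))
    }
    list(seq = seq_tbl(s, id = "synthetic"),
         truth = truth %||% tibble(name = character(), type = character(),
                                   seqnames = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   planted = character()))
  })
}

#' Write a simulation to disk
#'
#' Emits the FASTA, a BED6 truth file and a TSV manifest of the truth
#' records.
#'
#' @param sim result of [simulate_sequence()].
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  bed <- file.path(dir, paste0(stem, "_truth.bed"))
  tsv <- file.path(dir, paste0(stem, "_truth.tsv"))
  write_fasta(sim$seq, fa)
  if (nrow(sim$truth) > 0) write_bed(sim$truth, bed, name_col = "name")
  readr::write_tsv(sim$truth, tsv)
  invisible(c(fasta = fa, bed = bed, tsv = tsv))
}
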