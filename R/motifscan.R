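# Degenerate-consensus motif catalog and scanner.  Mismatch accounting:
# a window position is a mismatch iff the subject base fails iupac_match
# against the pattern code; ambiguity codes in the pattern are satisfied at
# zero cost; an N in the subject matches nothing but a pattern N.  Exclusion
# patterns are absolute -- tested at 0 mismatches regardless of the budget.

#' Define a degenerate consensus motif
#'
#' @param name motif name (unique within a catalog).
#' @param pattern IUPAC consensus string; lowercase "n" in printed patterns
#'   is the N wildcard.
#' @param exclusions character vector of IUPAC strings of the same length as
#'   `pattern`; a window matching any of them (exactly) is never reported.
#' @param max_mismatches mismatch budget for the main pattern (default 0).
#' @return one-row motif tibble with columns `name`, `pattern`, `exclusions`
#'   (list column), `max_mismatches`.
#' @examples
#' consensus_motif("ARE", "TGACNNNGC")
#' @export
consensus_motif <- function(name, pattern, exclusions = character(),
                            max_mismatches = 0L) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) abort("motif pattern must be non-empty")
  seq_to_masks(pattern, sprintf("pattern of motif '%s'", name))
  exclusions <- toupper(exclusions)
  for (ex in exclusions) {
    if (nchar(ex) != nchar(pattern)) {
      abort(sprintf("exclusion '%s' of motif '%s' must have the pattern length %d",
                    ex, name, nchar(pattern)))
    }
    seq_to_masks(ex, sprintf("exclusion of motif '%s'", name))
  }
  tibble(name = name, pattern = pattern,
         exclusions = list(exclusions),
         max_mismatches = as.integer(max_mismatches))
}

#' Built-in consensus motif catalog
#'
#' Core-promoter and response-element consensi used throughout the package:
#' TATA variants (the rare TATA-532 class carries four absolute exclusion
#' patterns), INR, DTIE, CCAAT and its inverted form, BRE, DPE, the
#' antioxidant response element (ARE), the MYC/MAX/MAD E-box, GAGA-factor
#' repeats, and the 19-nt CTCF recognition sequence of the MGMT promoter.
#' Elements whose consensus is not fixed in the literature source (SP1, AP1,
#' GRE, ERE) ship with documented canonical defaults and can be overridden
#' via [read_motif_catalog()].
#'
#' @return motif tibble, one row per motif (GAF contributes two patterns).
#' @export
motif_catalog <- function() {
  bind_rows(
    consensus_motif("TATA-8a", "TATAWA"),
    consensus_motif("TATA-8b", "TATAWAWR"),
    consensus_motif("TATA-532", "HWHWWWWR",
                    exclusions = c("HTYTTTWR", "CAYTTTWR", "MAMAAAAR", "CTYAAAAR")),
    consensus_motif("INR", "YYANWYY"),
    consensus_motif("DTIE", "GBBRDNHGG"),
    consensus_motif("CCAAT", "CCAAT"),
    consensus_motif("CCAAT-inverted", "TAACC"),
    consensus_motif("BRE", "SSRCGCC"),
    consensus_motif("DPE", "RGWCGTG"),
    consensus_motif("ARE", "TGACNNNGC"),
    consensus_motif("E-box", "CACGTG"),
    consensus_motif("GAF-5", "GAGAG"),
    consensus_motif("GAF-6", "GAGAGA"),
    consensus_motif("CTCF-MGMT", "TTACCTCTAGGTGCCAGCC"),
    consensus_motif("SP1", "GGGCGG"),
    consensus_motif("AP1", "TGACTCA"),
    consensus_motif("GRE", "AGAACANNNTGTTCT"),
    consensus_motif("ERE", "GGTCANNNTGACC")
  )
}

#' Read a motif catalog from a plain-text config
#'
#' Tab-separated columns: `name`, `pattern`, `exclusions` (";"-separated,
#' may be empty), `max_mismatches`.
#'
#' @param path TSV file.
#' @return motif tibble.
#' @export
read_motif_catalog <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("name", "pattern") %in% names(raw))) {
    abort("motif catalog needs at least columns 'name' and 'pattern'")
  }
  rows <- pmap(list(raw$name, raw$pattern,
                    raw$exclusions %||% rep("", nrow(raw)),
                    raw$max_mismatches %||% rep("0", nrow(raw))),
               function(nm, pat, ex, mm) {
                 ex <- if (is.na(ex) || !nzchar(ex)) character() else
                   strsplit(ex, ";", fixed = TRUE)[[1]]
                 mm <- if (is.na(mm)) 0L else as.integer(mm)
                 consensus_motif(nm, pat, ex, mm)
               })
  bind_rows(rows)
}

# scan one orientation of one motif over one subject mask vector
scan_one <- function(masks, pattern, exclusions, budget, strand, seqname, seq) {
  prof <- mismatch_profile(masks, pattern)
  if (length(prof) == 0) return(NULL)
  hit <- prof <= budget
  if (length(exclusions)) {
    for (ex in exclusions) {
      exprof <- mismatch_profile(masks, ex)
      hit <- hit & exprof > 0L
    }
  }
  idx <- which(hit)
  if (!length(idx)) return(NULL)
  L <- nchar(pattern)
  tibble(seqnames = seqname, start = idx, end = idx + L - 1L,
         strand = strand, matched = substring(seq, idx, idx + L - 1L),
         mismatches = prof[idx])
}

#' Scan sequences for a consensus motif
#'
#' Reports every window whose Hamming mismatch count against the pattern is
#' within the budget and which does not exactly match any exclusion pattern.
#' Minus-strand scanning matches the reverse-complemented pattern on the
#' forward strand, so coordinates are always forward-strand intervals and
#' `matched` is the forward-strand subsequence.  Overlapping hits are all
#' reported; results are sorted by (sequence, start, strand).
#'
#' @param seqs sequence tibble or character vector (see [seq_tbl()]).
#' @param motif one-row motif tibble from [consensus_motif()], or a bare
#'   IUPAC pattern string.
#' @param strands "both", "+" or "-".
#' @param max_mismatches optional override of the motif's budget.
#' @return hit tibble: `seqnames`, `start`, `end`, `strand`, `motif`,
#'   `matched`, `mismatches`.
#' @examples
#' scan_motif("TGACTCAGC", consensus_motif("ARE", "TGACNNNGC"))
#' @export
scan_motif <- function(seqs, motif, strands = c("both", "+", "-"),
                       max_mismatches = NULL) {
  strands <- match.arg(strands)
  seqs <- seq_tbl(seqs)
  if (is.character(motif)) motif <- consensus_motif(motif, motif)
  pattern <- motif$pattern[1]
  exclusions <- motif$exclusions[[1]]
  budget <- max_mismatches %||% motif$max_mismatches[1]
  out <- pmap(list(seqs$id, seqs$seq), function(id, s) {
    masks <- seq_to_masks(s, sprintf("sequence '%s'", id))
    res <- list()
    if (strands %in% c("both", "+")) {
      res$plus <- scan_one(masks, pattern, exclusions, budget, "+", id, s)
    }
    if (strands %in% c("both", "-")) {
      res$minus <- scan_one(masks, reverse_complement(pattern),
                            reverse_complement(exclusions), budget, "-", id, s)
    }
    bind_rows(res)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(seqnames = character(), start = integer(), end = integer(),
                  strand = character(), motif = character(),
                  matched = character(), mismatches = integer()))
  }
  out$motif <- motif$name[1]
  out <- select(out, "seqnames", "start", "end", "strand", "motif",
                "matched", "mismatches")
  arrange(out, .data$seqnames, .data$start, .data$strand)
}

#' Scan sequences against a motif catalog
#'
#' @inheritParams scan_motif
#' @param catalog motif tibble ([motif_catalog()] or [read_motif_catalog()]);
#'   motif names must be unique.
#' @return combined hit tibble, globally sorted by (sequence, start, strand,
#'   motif).
#' @export
scan_catalog <- function(seqs, catalog = motif_catalog(),
                         strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (nrow(catalog) == 0) abort("catalog must contain at least one motif")
  if (anyDuplicated(catalog$name)) {
    abort(sprintf("duplicate motif name in catalog: '%s'",
                  catalog$name[duplicated(catalog$name)][1]))
  }
  hits <- map(seq_len(nrow(catalog)),
              function(i) scan_motif(seqs, catalog[i, ], strands = strands))
  out <- bind_rows(hits)
  arrange(out, .data$seqnames, .data$start, .data$strand, .data$motif)
}

#' Count distinct motif sites
#'
#' With `mode = "all"` returns the raw hit count.  With
#' `mode = "merge_overlapping"` counts maximal clusters of mutually
#' overlapping same-strand hits, so a GAGAGA window and the GAGAG windows
#' nested in it count once.
#'
#' @param hits hit tibble from [scan_motif()] / [scan_catalog()], all on one
#'   sequence.
#' @param mode "all" or "merge_overlapping".
#' @return non-negative integer.
#' @export
count_distinct_sites <- function(hits, mode = c("all", "merge_overlapping")) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0) return(0L)
  if (length(unique(hits$seqnames)) > 1) {
    abort("count_distinct_sites expects hits from a single sequence")
  }
  if (mode == "all") return(nrow(hits))
  clusters <- hits |>
    group_by(.data$strand) |>
    summarise(k = length(IRanges::reduce(
      IRanges::IRanges(.data$start, .data$end), min.gapwidth = 0L)),
      .groups = "drop")
  sum(clusters$k)
}
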