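# Spaced-dimer response-element search: two degenerate decamer half-sites
# (default RRRCWWGYYY) separated by a 0-13 nt spacer, with per-half mismatch
# accounting.  The default half-site class is reverse-complement symmetric,
# so minimum mismatch counts are strand-invariant.  When a sequence is too
# short for the requested spacer range the range is clipped to what the
# length permits, so a printed element can be scored as the full string.

#' Spaced-dimer consensus definition
#'
#' @param half_pattern IUPAC half-site (default the p53 decamer RRRCWWGYYY).
#' @param spacer_min,spacer_max allowed spacer lengths in nt.
#' @param max_total_mismatches mismatch budget summed over both halves.
#' @return parameter list of class `dimer_consensus`.
#' @export
dimer_consensus <- function(half_pattern = "RRRCWWGYYY",
                            spacer_min = 0L, spacer_max = 13L,
                            max_total_mismatches = 0L) {
  half_pattern <- toupper(half_pattern)
  seq_to_masks(half_pattern, "half pattern")
  stopifnot(spacer_min >= 0, spacer_min <= spacer_max,
            max_total_mismatches >= 0)
  structure(list(half_pattern = half_pattern,
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max),
                 max_total_mismatches = as.integer(max_total_mismatches)),
            class = "dimer_consensus")
}

# all placements on one strand of one sequence; half1/half2 are the two
# half-site patterns as they read on the forward strand, 5'->3' order of
# the element on `strand`
dimer_placements <- function(masks, consensus, strand, seqname, s) {
  L <- nchar(consensus$half_pattern)
  n <- length(masks)
  half_fwd <- if (strand == "+") consensus$half_pattern else
    reverse_complement(consensus$half_pattern)
  prof <- mismatch_profile(masks, half_fwd)
  out <- list()
  smax <- min(consensus$spacer_max, n - 2L * L)
  if (smax < consensus$spacer_min) return(NULL)
  for (sp in consensus$spacer_min:smax) {
    span <- 2L * L + sp
    imax <- n - span + 1L
    if (imax < 1) next
    i <- seq_len(imax)
    mA <- prof[i]            # left half on forward coordinates
    mB <- prof[i + L + sp]   # right half
    # element half1 is the 5' half on its own strand
    m1 <- if (strand == "+") mA else mB
    m2 <- if (strand == "+") mB else mA
    out[[length(out) + 1L]] <- tibble(
      seqnames = seqname, start = i, end = i + span - 1L, strand = strand,
      spacer = sp, mm_half1 = m1, mm_half2 = m2, mm_total = m1 + m2,
      matched = substring(s, i, i + span - 1L))
  }
  bind_rows(out)
}

#' Find spaced-dimer response-element sites
#'
#' Exhaustively enumerates every (offset, spacer) placement on the requested
#' strands and reports all placements within the total mismatch budget.
#' Minus-strand placements are mapped to forward-strand coordinates;
#' `mm_half1` always refers to the 5' half-site on the element's own strand.
#'
#' @param seqs sequence tibble or character vector.
#' @param consensus [dimer_consensus()].
#' @param strands "both", "+" or "-".
#' @return hit tibble sorted by (total mismatches, start, spacer):
#'   `seqnames`, `start`, `end`, `strand`, `spacer`, `mm_half1`, `mm_half2`,
#'   `mm_total`, `matched`.
#' @export
find_dimer_sites <- function(seqs, consensus = dimer_consensus(),
                             strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  seqs <- seq_tbl(seqs)
  use <- if (strands == "both") c("+", "-") else strands
  out <- pmap(list(seqs$id, seqs$seq), function(id, s) {
    masks <- seq_to_masks(s, sprintf("sequence '%s'", id))
    bind_rows(map(use, function(st)
      dimer_placements(masks, consensus, st, id, s)))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(seqnames = character(), start = integer(), end = integer(),
                  strand = character(), spacer = integer(),
                  mm_half1 = integer(), mm_half2 = integer(),
                  mm_total = integer(), matched = character()))
  }
  out <- filter(out, .data$mm_total <= consensus$max_total_mismatches)
  arrange(out, .data$seqnames, .data$mm_total, .data$start, .data$spacer)
}

#' Best spaced-dimer placement in a sequence
#'
#' Returns the placement minimising the total mismatch count over both
#' strands and all permitted (offset, spacer) placements, the spacer range
#' clipped to what the sequence length allows.  Ties break deterministically
#' by smaller spacer, then smaller start, then "+" strand.
#'
#' @param seq single sequence (string or one-row sequence tibble).
#' @param consensus [dimer_consensus()]; the budget is ignored here.
#' @return one-row hit tibble (columns as in [find_dimer_sites()]).
#' @examples
#' best_dimer_match("AGGCAAGCCCACACCCAGGCTAGCAC")$mm_total  # 1
#' @export
best_dimer_match <- function(seq, consensus = dimer_consensus()) {
  seqs <- seq_tbl(seq)
  L <- nchar(consensus$half_pattern)
  if (nchar(seqs$seq[1]) < 2L * L + consensus$spacer_min) {
    abort(sprintf(
      "sequence of length %d cannot hold two %d-nt half-sites with spacer >= %d",
      nchar(seqs$seq[1]), L, consensus$spacer_min))
  }
  relaxed <- consensus
  relaxed$max_total_mismatches <- 2L * L
  hits <- find_dimer_sites(seqs, relaxed, strands = "both")
  hits <- arrange(hits, .data$mm_total, .data$spacer, .data$start,
                  dplyr::desc(.data$strand == "+"))
  hits[1, ]
}
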