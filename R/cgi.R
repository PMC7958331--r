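# CpG-island statistics and sliding-window island detection.
#
# Obs/Exp CpG follows the classical enrichment statistic:
#   #CpG / ((#C * #G) / N)
# with N the region length and #CpG counting overlapping CG dinucleotides.
# Ambiguity codes (including N) count as non-C/non-G and break dinucleotides.
# Threshold comparisons are strict (>).  Detection merges maximal runs of
# passing windows rather than replicating the EMBOSS CPGplot per-position
# averaging; the thresholds are the interface, the smoothing is not.

#' CpG-island detection parameters
#'
#' Defaults are the widely used thresholds: Obs/Exp CpG > 0.60,
#' %G+C > 55.0, length > 200 bp, over 100-bp windows slid by 1 bp.
#'
#' @param min_obs_exp Obs/Exp CpG threshold (strict).
#' @param min_gc_percent %G+C threshold (strict).
#' @param min_length minimum island length in bp (strict).
#' @param window sliding window size in bp.
#' @param step window step in bp.
#' @return parameter list of class `cgi_params`.
#' @export
cgi_params <- function(min_obs_exp = 0.60, min_gc_percent = 55.0,
                       min_length = 200L, window = 100L, step = 1L) {
  stopifnot(min_obs_exp > 0, min_gc_percent > 0, min_length > 0,
            window > 0, step > 0, min_length >= window)
  structure(list(min_obs_exp = min_obs_exp, min_gc_percent = min_gc_percent,
                 min_length = as.integer(min_length), window = as.integer(window),
                 step = as.integer(step)),
            class = "cgi_params")
}

# indicator vectors for C, G and CG-dinucleotide starts (U counted as T,
# i.e. never C/G); works on a single uppercase string
.base_indicators <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  isC <- chars == "C"
  isG <- chars == "G"
  n <- length(chars)
  isCG <- if (n >= 2) isC[-n] & isG[-1] else logical(0)
  list(C = isC, G = isG, CG = isCG, n = n)
}

#' CpG statistics of sequence regions
#'
#' Computes %G+C and the Obs/Exp CpG ratio for one or more regions of a
#' sequence.  With no `start`/`end` the whole sequence is measured.
#' The ratio is defined as 0 when the region contains no C or no G.
#'
#' @param seq single sequence: a string or a one-row sequence tibble.
#' @param start,end 1-based inclusive region bounds (vectorised).
#' @return tibble with `start`, `end`, `length`, `gc_percent`, `obs_exp_cpg`.
#' @examples
#' region_stats(strrep("CG", 100))
#' @export
region_stats <- function(seq, start = 1L, end = NULL) {
  seq <- seq_tbl(seq)
  s <- seq$seq[1]
  ind <- .base_indicators(s)
  if (is.null(end)) end <- ind$n
  if (any(start < 1 | end > ind$n | start > end)) {
    abort(sprintf("region out of bounds for sequence of length %d", ind$n))
  }
  cC <- cumsum(ind$C); cG <- cumsum(ind$G); cCG <- cumsum(c(ind$CG, FALSE))
  at0 <- function(cs, i) ifelse(i >= 1, cs[pmax(i, 1)], 0)
  nC <- at0(cC, end) - at0(cC, start - 1)
  nG <- at0(cG, end) - at0(cG, start - 1)
  # CG dinucleotide must start within [start, end-1]
  nCG <- at0(cCG, pmax(end - 1, start - 1)) - at0(cCG, start - 1)
  len <- end - start + 1
  gc <- 100 * (nC + nG) / len
  oe <- ifelse(nC * nG > 0, nCG / ((nC * nG) / len), 0)
  tibble(start = as.integer(start), end = as.integer(end),
         length = as.integer(len), gc_percent = gc, obs_exp_cpg = oe)
}

# windowed statistics at every step position; internal engine for
# detect_cpg_islands() and plot_cgi_profile()
window_stats <- function(s, window, step) {
  ind <- .base_indicators(s)
  if (ind$n < window) {
    return(tibble(start = integer(), end = integer(),
                  gc_percent = numeric(), obs_exp_cpg = numeric()))
  }
  starts <- seq.int(1L, ind$n - window + 1L, by = step)
  region_stats(s, start = starts, end = starts + window - 1L) |>
    select("start", "end", "gc_percent", "obs_exp_cpg")
}

#' Detect CpG islands by sliding-window thresholding
#'
#' A window passes when its %G+C and Obs/Exp CpG both strictly exceed the
#' thresholds; maximal runs of passing windows are merged into candidate
#' islands spanning the first window's start to the last window's end, and
#' candidates not exceeding `min_length` are discarded.  Each island is
#' reported with whole-island [region_stats()].
#'
#' @param seq single sequence (string or one-row sequence tibble).
#' @param params [cgi_params()].
#' @return tibble of islands: `seqnames`, `start`, `end`, `length`,
#'   `gc_percent`, `obs_exp_cpg`.
#' @export
detect_cpg_islands <- function(seq, params = cgi_params()) {
  seq <- seq_tbl(seq)
  s <- seq$seq[1]
  empty <- tibble(seqnames = character(), start = integer(), end = integer(),
                  length = integer(), gc_percent = numeric(),
                  obs_exp_cpg = numeric())
  ws <- window_stats(s, params$window, params$step)
  if (nrow(ws) == 0) return(empty)
  pass <- ws$gc_percent > params$min_gc_percent &
    ws$obs_exp_cpg > params$min_obs_exp
  if (!any(pass)) return(empty)
  r <- rle(pass)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- which(r$values)
  cand <- tibble(start = ws$start[starts_i[keep]], end = ws$end[ends_i[keep]])
  cand <- filter(cand, .data$end - .data$start + 1 > params$min_length)
  if (nrow(cand) == 0) return(empty)
  stats <- region_stats(s, cand$start, cand$end)
  mutate(stats, seqnames = seq$id[1], .before = 1)
}

#' Windowed CpG profile plot
#'
#' Plots the sliding-window %G+C and Obs/Exp CpG tracks with the detection
#' thresholds, the visual counterpart of [detect_cpg_islands()].
#'
#' @inheritParams detect_cpg_islands
#' @return a ggplot object.
#' @export
plot_cgi_profile <- function(seq, params = cgi_params()) {
  seq <- seq_tbl(seq)
  ws <- window_stats(seq$seq[1], params$window, params$step)
  long <- tidyr::pivot_longer(ws, c("gc_percent", "obs_exp_cpg"),
                              names_to = "metric", values_to = "value")
  thr <- tibble(metric = c("gc_percent", "obs_exp_cpg"),
                value = c(params$min_gc_percent, params$min_obs_exp))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = thr, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "window start (bp)", y = NULL,
                  title = sprintf("CpG profile (%d-bp windows)", params$window)) +
    ggplot2::theme_minimal()
}
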