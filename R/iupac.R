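# IUPAC nucleotide codes as 4-bit masks: A=1, C=2, G=4, T/U=8.
# A base b satisfies a code c iff set(b) is a subset of set(c); a masked
# base (N) in the subject therefore matches only a pattern N, never a
# narrower code -- conservative behaviour for masked input.

.iupac_masks <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# 256-slot lookup from uppercase char codes to masks (0 = undefined)
.mask_table <- local({
  tb <- integer(256)
  tb[utf8ToInt(paste(names(.iupac_masks), collapse = ""))] <- unname(.iupac_masks)
  tb
})

#' Convert a nucleotide string to IUPAC bitmasks
#'
#' @param x single character string (case-insensitive).
#' @param what label used in error messages.
#' @return integer vector of 4-bit masks, one per residue.
#' @keywords internal
#' @noRd
seq_to_masks <- function(x, what = "sequence") {
  ints <- utf8ToInt(toupper(x))
  masks <- .mask_table[ints]
  if (any(masks == 0L)) {
    bad <- which(masks == 0L)[1]
    abort(sprintf("illegal character '%s' at position %d of %s",
                  substr(toupper(x), bad, bad), bad, what))
  }
  masks
}

#' Test whether bases satisfy IUPAC consensus codes
#'
#' Vectorised membership test: a base matches a degenerate code when it is
#' one of the bases the code denotes (`W` = A or T, `Y` = C or T, `N` = any).
#' Comparison is case-insensitive; `U` is treated as `T`.
#'
#' @param base character vector of single bases (may themselves be ambiguity
#'   codes; an ambiguous base matches only codes covering its whole set).
#' @param code character vector of IUPAC codes, recycled against `base`.
#' @return logical vector.
#' @examples
#' iupac_match("A", "W")
#' iupac_match(c("G", "C"), "Y")
#' @export
iupac_match <- function(base, code) {
  bm <- .mask_table[utf8ToInt(paste(toupper(base), collapse = ""))]
  cm <- .mask_table[utf8ToInt(paste(toupper(code), collapse = ""))]
  if (any(bm == 0L)) abort("undefined nucleotide character in `base`")
  if (any(cm == 0L)) abort("undefined IUPAC code in `code`")
  n <- max(length(bm), length(cm))
  bm <- rep_len(bm, n); cm <- rep_len(cm, n)
  bitwAnd(bm, cm) == bm
}

#' Reverse-complement a nucleotide string
#'
#' Complements all IUPAC codes (R<->Y, K<->M, B<->V, D<->H; W, S, N are
#' self-complementary) and reverses.  For RNA input (or `rna = TRUE`) the
#' complement of A is written U.
#'
#' @param x character vector of sequences.
#' @param rna logical; emit U instead of T in the complement.
#' @return character vector of reverse-complemented sequences (uppercase).
#' @examples
#' reverse_complement("GAGAG")
#' @export
reverse_complement <- function(x, rna = FALSE) {
  vapply(x, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    if (length(chars) == 0) return("")
    comp <- .iupac_complement[chars]
    if (anyNA(comp)) {
      abort(sprintf("illegal character '%s' in sequence",
                    chars[which(is.na(comp))[1]]))
    }
    if (rna) comp[comp == "T"] <- "U"
    paste(rev(unname(comp)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# per-window mismatch counts of `pattern` (IUPAC) along a subject mask vector
mismatch_profile <- function(subject_masks, pattern) {
  pm <- seq_to_masks(pattern, "pattern")
  L <- length(pm)
  n <- length(subject_masks)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  acc <- integer(nw)
  for (j in seq_len(L)) {
    sm <- subject_masks[j:(j + nw - 1L)]
    acc <- acc + as.integer(bitwAnd(sm, pm[j]) != sm)
  }
  acc
}
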