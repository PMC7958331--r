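# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementations.

.oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# character-by-character mismatch count of a window against a pattern;
# subject ambiguity codes other than exact bases never match a narrower code
oracle_mismatches <- function(window, pattern) {
  w <- strsplit(toupper(window), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  sum(mapply(function(b, c) {
    bs <- .oracle_sets[[b]]
    !(length(bs) == 1 && bs %in% .oracle_sets[[c]]) &&
      !all(bs %in% .oracle_sets[[c]])
  }, w, p))
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# all forward+reverse hits of a pattern with a mismatch budget and
# 0-mismatch exclusions, as (start, end, strand, mismatches)
oracle_scan <- function(seq, pattern, exclusions = character(), budget = 0) {
  seq <- toupper(seq)
  L <- nchar(pattern)
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pattern else oracle_revcomp(pattern)
    exc <- if (strand == "+") exclusions else
      vapply(exclusions, oracle_revcomp, "")
    if (nchar(seq) < L) next
    for (i in seq_len(nchar(seq) - L + 1)) {
      win <- substr(seq, i, i + L - 1)
      mm <- oracle_mismatches(win, pat)
      if (mm > budget) next
      if (length(exc) && any(vapply(exc, function(e)
        oracle_mismatches(win, e) == 0, TRUE))) next
      out <- rbind(out, data.frame(start = i, end = i + L - 1,
                                   strand = strand, mismatches = mm))
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive spaced-dimer enumeration on both strands
oracle_dimer <- function(seq, half = "RRRCWWGYYY", smin = 0, smax = 13) {
  seq <- toupper(seq)
  n <- nchar(seq); L <- nchar(half)
  out <- NULL
  for (strand in c("+", "-")) {
    s2 <- if (strand == "+") seq else oracle_revcomp(seq)
    for (sp in smin:min(smax, n - 2 * L)) {
      if (sp < smin) next
      span <- 2 * L + sp
      if (n < span) next
      for (i in seq_len(n - span + 1)) {
        m1 <- oracle_mismatches(substr(s2, i, i + L - 1), half)
        m2 <- oracle_mismatches(substr(s2, i + L + sp, i + span - 1), half)
        fs <- if (strand == "+") i else n - (i + span - 1) + 1
        out <- rbind(out, data.frame(start = fs, end = fs + span - 1,
                                     strand = strand, spacer = sp,
                                     mm1 = m1, mm2 = m2, total = m1 + m2))
      }
    }
  }
  out
}

# direct character counting for CpG statistics
oracle_region_stats <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  nC <- sum(ch == "C"); nG <- sum(ch == "G")
  nCG <- sum(ch[-n] == "C" & ch[-1] == "G")
  list(gc = 100 * (nC + nG) / n,
       oe = if (nC * nG > 0) nCG / ((nC * nG) / n) else 0)
}

# exhaustive duplex enumeration: minimum energy over every legal set of
# antiparallel intermolecular pairs under the affine loop model
oracle_duplex_mfe <- function(mir, target, model = cisreg::energy_model()) {
  code <- c(A = 1, C = 2, G = 3, U = 4)
  mi <- code[strsplit(gsub("T", "U", toupper(mir)), "")[[1]]]
  ti <- rev(code[strsplit(gsub("T", "U", toupper(target)), "")[[1]]])
  pe <- function(x, y) {
    if ((x == 3 && y == 2) || (x == 2 && y == 3)) return(model$gc)
    if ((x == 1 && y == 4) || (x == 4 && y == 1)) return(model$au)
    if ((x == 3 && y == 4) || (x == 4 && y == 3)) return(model$gu)
    NA_real_
  }
  gap <- function(a, b) {
    if (a > model$max_bulge || b > model$max_bulge) return(NA_real_)
    if (a == 0 && b == 0) return(0)
    if (a == 0) return(model$bulge_open + model$bulge_ext * (b - 1))
    if (b == 0) return(model$bulge_open + model$bulge_ext * (a - 1))
    model$il_open + model$il_ext * (a + b - 2)
  }
  m <- length(mi); n <- length(ti)
  best <- 0
  rec <- function(i, j, acc) {
    # choose the next pair at (ii, jj) with ii > i, jj > j
    for (ii in (i + 1):m) {
      if (ii > m) break
      for (jj in (j + 1):n) {
        if (jj > n) break
        p <- pe(mi[ii], ti[jj])
        if (is.na(p)) next
        g <- if (i == 0) 0 else gap(ii - i - 1, jj - j - 1)
        if (is.na(g)) next
        e <- acc + g + p
        if (e < best) best <<- e
        rec(ii, jj, e)
      }
    }
  }
  rec(0, 0, 0)
  best
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
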