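# miRNA recognition-element prediction: seed matching, intermolecular
# minimum-free-energy hybridization (dynamic program, no intramolecular
# pairs), greedy suboptimal non-overlapping site selection, and mapping of
# sites onto transcript feature annotations.

.rna_code <- c(A = 0L, C = 1L, G = 2L, U = 3L)

# uppercase RNA string -> integer codes; DNA is transcribed T->U with a note
rna_to_int <- function(x, what = "sequence", quiet = FALSE) {
  s <- toupper(x)
  if (grepl("T", s, fixed = TRUE)) {
    if (!quiet) inform(sprintf("transcribing %s: T -> U", what))
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- .rna_code[chars]
  if (anyNA(code)) {
    abort(sprintf("non-RNA character '%s' in %s (ambiguity codes are not
allowed in hybridization input)", chars[which(is.na(code))[1]], what))
  }
  unname(code)
}

#' Duplex energy model
#'
#' A deliberately simple nearest-neighbour-flavoured model: each base pair
#' contributes a fixed stacking-free pair energy, and unpaired stretches
#' between consecutive pairs are charged affine bulge or internal-loop
#' penalties.  Dangling ends are free.  All values are user-overridable.
#'
#' @param gc,au,gu pair energies in kcal/mol (must be negative).
#' @param bulge_open,bulge_ext penalty for a bulge of length L:
#'   `bulge_open + bulge_ext * (L - 1)`.
#' @param il_open,il_ext penalty for an internal loop with a + b unpaired
#'   bases: `il_open + il_ext * (a + b - 2)`.
#' @param max_bulge maximum unpaired stretch on either strand.
#' @return parameter list of class `energy_model`.
#' @export
energy_model <- function(gc = -3.0, au = -2.0, gu = -1.0,
                         bulge_open = 3.0, bulge_ext = 0.5,
                         il_open = 2.0, il_ext = 0.5, max_bulge = 15L) {
  stopifnot(gc < 0, au < 0, gu < 0, bulge_open > 0, bulge_ext > 0,
            il_open > 0, il_ext > 0, max_bulge >= 1)
  structure(list(gc = gc, au = au, gu = gu,
                 bulge_open = bulge_open, bulge_ext = bulge_ext,
                 il_open = il_open, il_ext = il_ext,
                 max_bulge = as.integer(max_bulge)),
            class = "energy_model")
}

#' Minimum-free-energy intermolecular hybridization
#'
#' Dynamic program over (miRNA position, target position) returning the
#' lowest-energy antiparallel duplex between the full miRNA and a target
#' window.  Only intermolecular pairs are formed; bulges and internal loops
#' are charged per [energy_model()]; dangling ends are free.  If no pairing
#' is favourable the MFE is 0 with an empty structure.
#'
#' @param mir miRNA sequence 5'->3' (RNA; DNA is transcribed with a notice).
#' @param target_window target subsequence 5'->3' (kept short, typically
#'   under ~80 nt, as the DP is quadratic with a bounded loop span).
#' @param model [energy_model()].
#' @param quiet suppress the DNA-transcription notice.
#' @return list with `mfe` (kcal/mol) and `structure`, a tibble of paired
#'   positions (`mir_pos`, `target_pos`), both 1-based 5'->3'.
#' @examples
#' hybridize("AAAAAAA", "UUUUUUU")$mfe  # 7 * au
#' @export
hybridize <- function(mir, target_window, model = energy_model(),
                      quiet = FALSE) {
  mi <- rna_to_int(mir, "miRNA", quiet = quiet)
  ti <- rna_to_int(target_window, "target window", quiet = quiet)
  res <- hybrid_dp_cpp(mi, ti, model$gc, model$au, model$gu,
                       model$bulge_open, model$bulge_ext,
                       model$il_open, model$il_ext, model$max_bulge)
  list(mfe = res$mfe,
       structure = tibble(mir_pos = res$mir_pos, target_pos = res$target_pos))
}

#' Seed-complementarity candidate sites
#'
#' Scans a target for matches to the reverse complement of the miRNA seed
#' (positions `seed_start`..`seed_end`, default 2-8).  Site classes:
#' `7mer` = perfect complement of the full seed span; `6mer` = perfect
#' complement of the span minus its last position; `GU` = full-span
#' complement tolerating G:U wobble pairs.  Positions are 1-based target
#' positions of the leftmost matched base; a position is reported once with
#' its strongest class (7mer > 6mer > GU).
#'
#' @param mir miRNA sequence 5'->3'.
#' @param target target sequence 5'->3' (RNA or DNA).
#' @param seed_start,seed_end seed span within the miRNA.
#' @param classes subset of `c("7mer", "6mer", "GU")`.
#' @return tibble with `position` (ascending) and `class`.
#' @export
seed_sites <- function(mir, target, seed_start = 2L, seed_end = 8L,
                       classes = c("7mer", "6mer", "GU")) {
  classes <- match.arg(classes, several.ok = TRUE)
  mir <- gsub("T", "U", toupper(mir), fixed = TRUE)
  target <- gsub("T", "U", toupper(target), fixed = TRUE)
  if (seed_start < 1 || seed_end > nchar(mir) || seed_start >= seed_end) {
    abort("seed span must lie within the miRNA")
  }
  seed <- substr(mir, seed_start, seed_end)
  # reverse complement of the seed, as it appears in the target 5'->3'
  rc <- reverse_complement(seed, rna = TRUE)
  tl <- strsplit(target, "", fixed = TRUE)[[1]]
  find_exact <- function(pat) {
    L <- nchar(pat)
    if (length(tl) < L) return(integer())
    pc <- strsplit(pat, "", fixed = TRUE)[[1]]
    n <- length(tl) - L + 1L
    ok <- rep(TRUE, n)
    for (j in seq_len(L)) ok <- ok & tl[j:(j + n - 1L)] == pc[j]
    which(ok)
  }
  # GU-tolerant: seed base G may face U, seed base U may face G
  find_gu <- function(seedchars) {
    L <- length(seedchars)
    if (length(tl) < L) return(integer())
    # target reads the complement reversed: target pos p+j-1 faces seed
    # position (L - j + 1)
    n <- length(tl) - L + 1L
    ok <- rep(TRUE, n)
    for (j in seq_len(L)) {
      sb <- seedchars[L - j + 1L]
      allowed <- switch(sb,
                        A = "U", C = "G",
                        G = c("C", "U"), U = c("A", "G"), character())
      ok <- ok & tl[j:(j + n - 1L)] %in% allowed
    }
    which(ok)
  }
  res <- list()
  if ("7mer" %in% classes) {
    res$`7mer` <- tibble(position = find_exact(rc), class = "7mer")
  }
  if ("6mer" %in% classes) {
    six <- substr(mir, seed_start, seed_end - 1L)
    res$`6mer` <- tibble(position = find_exact(reverse_complement(six, rna = TRUE)),
                         class = "6mer")
  }
  if ("GU" %in% classes) {
    res$GU <- tibble(position = find_gu(strsplit(seed, "", fixed = TRUE)[[1]]),
                     class = "GU")
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) return(tibble(position = integer(), class = character()))
  out |>
    mutate(rank = match(.data$class, c("7mer", "6mer", "GU"))) |>
    group_by(.data$position) |>
    slice(which.min(.data$rank)) |>
    ungroup() |>
    select("position", "class") |>
    arrange(.data$position)
}

# candidate window starts for scan_transcript
candidate_windows <- function(n, m, seeds, window, step, exhaustive) {
  if (!exhaustive && length(seeds) > 0) {
    # the mir 3' end pairs upstream of the seed match on the target, so the
    # window reaches m + slack to the left of the seed and a little right
    starts <- unique(pmax(1L, pmin(seeds - m - 5L, n - window + 1L)))
  } else {
    starts <- seq.int(1L, max(1L, n - window + 1L), by = step)
  }
  sort(unique(pmax(1L, pmin(starts, max(1L, n - window + 1L)))))
}

#' Predict hybridization sites on a transcript
#'
#' Computes the duplex MFE in candidate windows (anchored at seed matches,
#' falling back to exhaustive stepped windows when no seed exists or
#' `exhaustive = TRUE`), then greedily selects sites by ascending MFE
#' subject to non-overlap of their paired target spans, stopping at
#' `max_sites`.  Sites with `mfe > energy_cutoff` (or with no pairs) are
#' suppressed.
#'
#' @param mir named miRNA: a one-row sequence tibble or a (optionally
#'   named) string.
#' @param transcript target transcript: one-row sequence tibble or string.
#' @param model [energy_model()].
#' @param max_sites maximum number of reported non-overlapping sites.
#' @param energy_cutoff report only sites with MFE <= this value (kcal/mol).
#' @param window,step candidate window size and step for the exhaustive
#'   fallback; `window` defaults to miRNA length + 15.
#' @param exhaustive force exhaustive windows regardless of seed matches.
#' @return tibble of sites: `mir_id`, `target_id`, `start`, `end` (paired
#'   target span, 1-based 5'->3'; `start` is the leftmost paired position),
#'   `mfe`, `n_pairs`, `structure` (list column of pair tibbles).
#' @export
scan_transcript <- function(mir, transcript, model = energy_model(),
                            max_sites = 10L, energy_cutoff = 0,
                            window = NULL, step = NULL, exhaustive = FALSE) {
  mir <- seq_tbl(mir, alphabet = "RNA")
  transcript <- seq_tbl(transcript)
  ms <- gsub("T", "U", mir$seq[1], fixed = TRUE)
  ts <- gsub("T", "U", transcript$seq[1], fixed = TRUE)
  m <- nchar(ms); n <- nchar(ts)
  if (n < m) abort("transcript shorter than the miRNA")
  window <- as.integer(window %||% min(n, m + 15L))
  step <- as.integer(step %||% max(1L, window %/% 3L))
  sd <- seed_sites(ms, ts)
  starts <- candidate_windows(n, m, sd$position, window, step, exhaustive)
  cand <- map(starts, function(st) {
    en <- min(n, st + window - 1L)
    h <- hybridize(ms, substr(ts, st, en), model, quiet = TRUE)
    if (nrow(h$structure) == 0 || h$mfe >= 0) return(NULL)
    tibble(start = st + min(h$structure$target_pos) - 1L,
           end = st + max(h$structure$target_pos) - 1L,
           mfe = h$mfe, n_pairs = nrow(h$structure),
           structure = list(mutate(h$structure,
                                   target_pos = .data$target_pos + st - 1L)))
  })
  cand <- bind_rows(cand)
  empty <- tibble(mir_id = character(), target_id = character(),
                  start = integer(), end = integer(), mfe = numeric(),
                  n_pairs = integer(), structure = list())
  if (nrow(cand) == 0) return(empty)
  cand <- cand |>
    filter(.data$mfe <= energy_cutoff) |>
    arrange(.data$mfe, .data$start) |>
    distinct(.data$start, .data$end, .keep_all = TRUE)
  # greedy non-overlapping selection by ascending mfe
  chosen <- integer()
  for (i in seq_len(nrow(cand))) {
    if (length(chosen) >= max_sites) break
    ok <- all(cand$end[i] < cand$start[chosen] |
                cand$start[i] > cand$end[chosen])
    if (ok) chosen <- c(chosen, i)
  }
  if (!length(chosen)) return(empty)
  out <- cand[chosen, ]
  mutate(out, mir_id = mir$id[1], target_id = transcript$id[1], .before = 1)
}

#' Map hybridization sites onto transcript features
#'
#' Labels each site by the annotation feature containing its leftmost
#' position (ties, from overlapping features, go to the more upstream
#' feature).  Positions beyond the annotation span are labelled
#' "unannotated" with a warning.
#'
#' @param sites site tibble from [scan_transcript()].
#' @param annotation tibble with `transcript_id`, `label`, `start`, `end`
#'   in transcript-local coordinates (see [read_feature_annotation()]).
#' @return `sites` with a `feature` column added.
#' @export
map_to_features <- function(sites, annotation) {
  if (nrow(sites) == 0) return(mutate(sites, feature = character()))
  ann <- arrange(annotation, .data$start)
  lab <- map_chr(sites$start, function(p) {
    inside <- ann$start <= p & p <= ann$end
    if (!any(inside)) return("unannotated")
    ann$label[which(inside)[1]]
  })
  if (any(lab == "unannotated")) {
    warn("some site positions fall outside the annotation span")
  }
  mutate(sites, feature = lab)
}

#' Per-feature site counts
#'
#' Summarises mapped sites the way target tables report them: one row per
#' (miRNA, transcript, feature) with the site count and leftmost positions.
#'
#' @param sites output of [map_to_features()].
#' @return summary tibble with `mir_id`, `target_id`, `feature`, `n_sites`,
#'   `leftmost_positions` (comma-separated, ascending).
#' @export
feature_counts <- function(sites) {
  sites |>
    group_by(.data$mir_id, .data$target_id, .data$feature) |>
    summarise(n_sites = n(),
              leftmost_positions = paste(sort(.data$start), collapse = ", "),
              .groups = "drop")
}

#' Read a transcript feature annotation table
#'
#' Tab-separated columns `transcript_id`, `label`, `start`, `end`
#' (transcript-local, 1-based inclusive).
#'
#' @param path TSV file.
#' @return annotation tibble.
#' @export
read_feature_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = "c", label = "c", start = "i", end = "i"))
}

#' Bundled mature miRNA sequences
#'
#' Mature miRNA sequences (RNA alphabet) of the regulatory-RNA candidates
#' analysed around the MGMT/EBF3 locus, for examples and tests.
#'
#' @return sequence tibble (RNA).
#' @export
mature_mirs <- function() {
  read_fasta(system.file("extdata", "mature_mirs.fasta", package = "cisreg"),
             alphabet = "RNA")
}

#' Render a duplex as two-line text
#'
#' @param mir,target the hybridized sequences (5'->3').
#' @param structure pair tibble from [hybridize()] (`target_pos` local to
#'   `target`).
#' @return character vector of display lines.
#' @export
format_duplex <- function(mir, target, structure) {
  mir <- gsub("T", "U", toupper(mir), fixed = TRUE)
  target <- gsub("T", "U", toupper(target), fixed = TRUE)
  if (nrow(structure) == 0) return(c("(no pairs)"))
  marks_m <- rep(" ", nchar(mir))
  marks_m[structure$mir_pos] <- "|"
  c(paste0("miR    5' ", mir, " 3'"),
    paste0("          ", paste(marks_m, collapse = "")),
    paste0("target 3' ", paste(rev(strsplit(target, "")[[1]]), collapse = ""),
           " 5'  (positions ", min(structure$target_pos), "-",
           max(structure$target_pos), ")"))
}
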