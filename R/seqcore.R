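# Sequence and coordinate foundation.  Sequences travel as tibbles with
# columns (id, seq, alphabet); genomic intervals as tibbles with columns
# (seqnames, start, end, strand), 1-based inclusive throughout.  BED export
# converts to 0-based half-open at the boundary; GFF3 stays 1-based.

.dna_chars <- "ACGTRYSWKMBDHVN"
.rna_chars <- "ACGURYSWKMBDHVN"

#' Build a sequence tibble
#'
#' Normalises input to the tabular sequence representation used across the
#' package: one row per record with columns `id`, `seq` (uppercased) and
#' `alphabet` ("DNA" or "RNA").  A plain (optionally named) character vector
#' is accepted anywhere a sequence table is expected.
#'
#' @param x character vector of sequences, or an existing sequence tibble.
#' @param id identifiers; defaults to names of `x` or "seq1", "seq2", ...
#' @param alphabet "DNA", "RNA" or "auto" (RNA iff the sequence contains U
#'   and no T).
#' @return tibble with columns `id`, `seq`, `alphabet`.
#' @examples
#' seq_tbl(c(promoter = "ACGTACGT"))
#' @export
seq_tbl <- function(x, id = NULL, alphabet = "auto") {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    out <- as_tibble(x)
    if (!"alphabet" %in% names(out)) out$alphabet <- alphabet
    x <- out$seq
    id <- out$id
    alphabet <- out$alphabet
  }
  sq <- toupper(as.character(x))
  if (is.null(id)) id <- names(x) %||% paste0("seq", seq_along(sq))
  alphabet <- rep_len(alphabet, length(sq))
  auto <- alphabet == "auto"
  if (any(auto)) {
    has_u <- grepl("U", sq[auto], fixed = TRUE)
    has_t <- grepl("T", sq[auto], fixed = TRUE)
    alphabet[auto] <- ifelse(has_u & !has_t, "RNA", "DNA")
  }
  ok <- map2(sq, alphabet, function(s, a) {
    allowed <- if (a == "RNA") .rna_chars else .dna_chars
    bad <- gsub(sprintf("[%s]", allowed), "", s)
    if (nzchar(bad)) substr(bad, 1, 1) else NA_character_
  })
  bad <- which(!is.na(unlist(ok)))
  if (length(bad)) {
    abort(sprintf("record '%s' contains character '%s' outside the %s alphabet",
                  id[bad[1]], unlist(ok)[bad[1]], alphabet[bad[1]]))
  }
  tibble(id = as.character(id), seq = sq, alphabet = alphabet)
}

#' Read a FASTA file into a sequence tibble
#'
#' Records are uppercased at ingest; blank lines are ignored.  Residues
#' outside the declared alphabet raise a parse error naming the offending
#' line of the file.
#'
#' @param path FASTA file.
#' @param alphabet "DNA", "RNA" or "auto".
#' @return tibble with columns `id`, `seq`, `alphabet`.
#' @export
read_fasta <- function(path, alphabet = "auto") {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  sq <- toupper(as.character(set))
  res <- tryCatch(
    seq_tbl(sq, id = ids, alphabet = alphabet),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    # locate the offending line for a useful parse error
    lines <- toupper(readLines(path))
    allowed <- sprintf("[%s%s \t]", .dna_chars, "U")
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (startsWith(ln, ">") || !nzchar(ln)) next
      bad <- gsub(allowed, "", ln)
      if (nzchar(bad)) {
        abort(sprintf("FASTA parse error at line %d of '%s': illegal character '%s'",
                      i, path, substr(bad, 1, 1)))
      }
    }
    stop(res)
  }
  res
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs sequence tibble (or character vector; see [seq_tbl()]).
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- seq_tbl(seqs)
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Build a genomic interval tibble
#'
#' Coordinates are 1-based inclusive.  Descending pairs (start > end), as
#' printed for minus-strand elements, are normalised to (min, max) with
#' strand "-".
#'
#' @param seqnames sequence names.
#' @param start,end 1-based inclusive coordinates.
#' @param strand "+", "-" or "*" (unstranded); recycled.
#' @return tibble with columns `seqnames`, `start`, `end`, `strand`.
#' @examples
#' interval_tbl("chr10", 129466183, 129468201)
#' interval_tbl("p", 617, 595)  # descending: minus strand
#' @export
interval_tbl <- function(seqnames, start, end, strand = "*") {
  n <- max(length(seqnames), length(start), length(end))
  seqnames <- rep_len(as.character(seqnames), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  desc <- start > end
  strand[desc] <- "-"
  tmp <- start[desc]; start[desc] <- end[desc]; end[desc] <- tmp
  if (any(start < 1)) abort("interval coordinates must be positive (1-based)")
  tibble(seqnames = seqnames, start = start, end = end, strand = strand)
}

#' Inclusive interval length
#'
#' @param ivs interval tibble, or a numeric start when `end` is given.
#' @param end optional numeric end positions.
#' @return numeric vector of lengths `end - start + 1`.
#' @examples
#' interval_length(interval_tbl("chr10", 129466183, 129468201))  # 2019
#' interval_length(129835232, 129964281)                          # 129050
#' @export
interval_length <- function(ivs, end = NULL) {
  if (is.data.frame(ivs)) return(ivs$end - ivs$start + 1)
  end - ivs + 1
}

#' Union of genomic intervals
#'
#' Merges overlapping and touching (`end + 1 == next start`) intervals on a
#' single sequence into the minimal sorted set of maximal intervals.  Strand
#' is ignored for the union; the result is unstranded.
#'
#' @param ivs interval tibble; all rows must share one `seqnames`.
#' @return interval tibble of merged intervals, sorted by start.
#' @export
interval_union <- function(ivs) {
  if (nrow(ivs) == 0) return(ivs)
  if (length(unique(ivs$seqnames)) > 1) {
    abort("interval_union requires all intervals on one sequence")
  }
  merged <- IRanges::reduce(IRanges::IRanges(ivs$start, ivs$end),
                            min.gapwidth = 1L)
  interval_tbl(ivs$seqnames[1], IRanges::start(merged), IRanges::end(merged))
}

#' Map local positions to genomic coordinates
#'
#' Local coordinates are 1-based from the anchor's start on the plus strand,
#' so local position 1 is the anchor start.
#'
#' @param anchor one-row interval tibble (or its numeric start).
#' @param local_pos vector of 1-based local positions.
#' @return numeric vector of genomic positions.
#' @examples
#' local_to_genome(interval_tbl("chr10", 129466183, 129468201), 241)
#' @export
local_to_genome <- function(anchor, local_pos) {
  if (is.data.frame(anchor)) {
    len <- interval_length(anchor)[1]
    if (any(local_pos < 1 | local_pos > len)) {
      abort(sprintf("local position out of range [1, %d]", len))
    }
    anchor <- anchor$start[1]
  }
  if (any(local_pos < 1)) abort("local positions are 1-based")
  anchor + local_pos - 1
}

#' Map genomic positions to anchor-local coordinates
#'
#' Inverse of [local_to_genome()].
#'
#' @inheritParams local_to_genome
#' @param genome_pos vector of genomic positions.
#' @return numeric vector of 1-based local positions.
#' @export
genome_to_local <- function(anchor, genome_pos) {
  if (is.data.frame(anchor)) {
    if (any(genome_pos < anchor$start[1] | genome_pos > anchor$end[1])) {
      abort("genomic position outside the anchor interval")
    }
    anchor <- anchor$start[1]
  }
  genome_pos - anchor + 1
}

# hits/intervals tibble -> GRanges (for the rtracklayer writers)
hits_to_granges <- function(df, score_col = NULL, name_col = NULL) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = ifelse(strand %in% c("+", "-"), strand, "*")
  )
  if (!is.null(name_col) && name_col %in% names(df)) {
    gr$name <- as.character(df[[name_col]])
  }
  if (!is.null(score_col) && score_col %in% names(df)) {
    gr$score <- as.numeric(df[[score_col]])
  }
  gr
}

#' Write intervals or hits as BED6
#'
#' Output is 0-based half-open, sorted by (sequence, start, name) so files
#' are deterministic.
#'
#' @param df tibble with `seqnames`, `start`, `end` (+ optional `strand`).
#' @param path output file.
#' @param score_col,name_col columns to place in the BED score/name fields.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, score_col = NULL, name_col = NULL) {
  df <- arrange(df, .data$seqnames, .data$start)
  gr <- hits_to_granges(df, score_col = score_col, name_col = name_col)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write intervals or hits as GFF3
#'
#' Stays 1-based inclusive, matching the internal convention.
#'
#' @inheritParams write_bed
#' @param type feature type string for column 3.
#' @param source source string for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(df, path, type = "nucleotide_motif",
                       source = "cisreg", score_col = NULL, name_col = NULL) {
  df <- arrange(df, .data$seqnames, .data$start)
  gr <- hits_to_granges(df, score_col = score_col, name_col = name_col)
  gr$type <- type
  gr$source <- source
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
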