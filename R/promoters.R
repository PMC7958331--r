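# Alternative-promoter bookkeeping: ingest promoter records, build the
# union ("revised") promoter envelope, verify printed spans, and map
# promoter-local annotations to genomic coordinates.

#' Read promoter records from a TSV table
#'
#' Expected columns: `source`, `promoter_id`, `chrom`, `start`, `end`,
#' `declared_span` (optional).
#'
#' @param path TSV file.
#' @return tibble of promoter records with interval columns normalised.
#' @export
read_promoter_records <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    source = "c", promoter_id = "c", chrom = "c",
    start = "d", end = "d", .default = "d"))
  need <- c("source", "promoter_id", "chrom", "start", "end")
  if (!all(need %in% names(raw))) {
    abort(sprintf("promoter table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  iv <- interval_tbl(raw$chrom, raw$start, raw$end, "+")
  tibble(source = raw$source, promoter_id = raw$promoter_id,
         seqnames = iv$seqnames, start = iv$start, end = iv$end,
         strand = iv$strand,
         declared_span = raw$declared_span %||% NA_real_)
}

#' Alternative and revised MGMT exon-1 promoter records
#'
#' The bundled table of alternative promoter intervals at the 5' side of
#' human MGMT exon-1 (hg38 chr10 coordinates), the union ("revised")
#' promoter derived from them, and the predicted exon-2 promoter-like
#' record.  Subsets are selected with `which`.
#'
#' @param which "exon1" for the five alternative exon-1 promoters, "all"
#'   for every record (including the revised union and the exon-2 record),
#'   "revised" for the union record alone.
#' @return tibble of promoter records.
#' @examples
#' mgmt_promoters()
#' @export
mgmt_promoters <- function(which = c("exon1", "all", "revised")) {
  which <- match.arg(which)
  recs <- read_promoter_records(
    system.file("extdata", "mgmt_promoters.tsv", package = "cisreg"))
  switch(which,
         exon1 = filter(recs, !.data$promoter_id %in% c("MGMT-P1", "TRED-5071")),
         revised = filter(recs, .data$promoter_id == "MGMT-P1"),
         all = recs)
}

#' Bundled promoter-local CpG-island annotations
#'
#' Local coordinates (1-based from the revised promoter's 5' end) and the
#' published whole-region CpG statistics of the promoter CGI annotations.
#'
#' @return tibble with `annotation`, `local_start`, `local_end`,
#'   `gc_percent`, `obs_exp_cpg`.
#' @export
mgmt_cgi_annotations <- function() {
  readr::read_tsv(
    system.file("extdata", "mgmt_cgi_annotations.tsv", package = "cisreg"),
    col_types = readr::cols(annotation = "c", .default = "d"))
}

#' Build the revised (union) promoter from overlapping records
#'
#' All records must lie on one chromosome and form a single connected block
#' under overlap-or-touch; a disconnected record (for example an exon-2
#' promoter offered to an exon-1 union) raises an error naming the
#' offenders.  The envelope is `(min start, max end)`.
#'
#' @param records promoter record tibble (see [read_promoter_records()]).
#' @return object of class `revised_promoter`: a list with `interval`
#'   (one-row interval tibble), `members` (records sorted by start) and
#'   `local_annotations` (tibble, initially empty).
#' @examples
#' rp <- build_revised_promoter(mgmt_promoters("exon1"))
#' glance(rp)
#' @export
build_revised_promoter <- function(records) {
  if (nrow(records) == 0) abort("at least one promoter record is required")
  if (length(unique(records$seqnames)) > 1) {
    abort("promoter records span multiple chromosomes")
  }
  members <- arrange(records, .data$start, .data$end)
  if (nrow(members) > 1) {
    run_end <- cummax(members$end)
    gap <- members$start[-1] > run_end[-nrow(members)] + 1
    if (any(gap)) {
      bad <- members$promoter_id[which(gap) + 1]
      abort(sprintf("disconnected promoter record(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  env <- interval_union(select(members, "seqnames", "start", "end", "strand"))
  structure(list(interval = env, members = members,
                 local_annotations = tibble(label = character(),
                                            local_start = integer(),
                                            local_end = integer())),
            class = "revised_promoter")
}

#' @export
print.revised_promoter <- function(x, ...) {
  cat(sprintf("<revised promoter> %s:%s-%s (%s bp), %d member record(s)\n",
              x$interval$seqnames, format(x$interval$start, big.mark = ","),
              format(x$interval$end, big.mark = ","),
              format(interval_length(x$interval), big.mark = ","),
              nrow(x$members)))
  invisible(x)
}

#' Verify declared promoter spans against computed lengths
#'
#' @param records promoter record tibble with a `declared_span` column.
#' @return tibble with `promoter_id`, `computed_span`, `declared_span`,
#'   `agree`; declared spans are reported, never silently fixed.
#' @export
verify_spans <- function(records) {
  tibble(promoter_id = records$promoter_id,
         computed_span = interval_length(records),
         declared_span = records$declared_span,
         agree = !is.na(records$declared_span) &
           interval_length(records) == records$declared_span)
}

#' Map a promoter-local annotation to genomic coordinates
#'
#' @param rp `revised_promoter` object.
#' @param label annotation label.
#' @param local_start,local_end 1-based local interval within the promoter.
#' @return one-row tibble with `label`, `seqnames`, `start`, `end`.
#' @examples
#' rp <- build_revised_promoter(mgmt_promoters("exon1"))
#' annotate_local(rp, "US-CGI", 241, 720)
#' @export
annotate_local <- function(rp, label, local_start, local_end) {
  stopifnot(inherits(rp, "revised_promoter"))
  len <- interval_length(rp$interval)
  if (any(c(local_start, local_end) < 1) || any(c(local_start, local_end) > len)) {
    abort(sprintf("local interval outside [1, %d]", len))
  }
  tibble(label = label,
         seqnames = rp$interval$seqnames,
         start = local_to_genome(rp$interval, local_start),
         end = local_to_genome(rp$interval, local_end))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the member records of a revised promoter
#'
#' @param x `revised_promoter` object.
#' @param ... unused.
#' @return the member record tibble with computed spans.
#' @export
tidy.revised_promoter <- function(x, ...) {
  mutate(x$members, computed_span = interval_length(x$members))
}

#' One-row summary of a revised promoter
#'
#' @param x `revised_promoter` object.
#' @param ... unused.
#' @return tibble with envelope coordinates, length and member count.
#' @export
glance.revised_promoter <- function(x, ...) {
  tibble(seqnames = x$interval$seqnames,
         start = x$interval$start, end = x$interval$end,
         length = interval_length(x$interval),
         n_members = nrow(x$members))
}
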