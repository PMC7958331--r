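# Unified run front end: a plain config (list or YAML file) selects a task,
# inputs and parameters; outputs are deterministic for a fixed seed and are
# accompanied by a manifest (parameters, package version, seed, input
# checksums) so every file is reproducible from its manifest alone.
# A thin command-line wrapper lives at inst/scripts/cisreg-cli.R.

.run_tasks <- c("scan-motifs", "find-cgi", "find-p53re", "merge-promoters",
                "predict-mre", "simulate")

#' Assemble a run configuration
#'
#' @param task one of `scan-motifs`, `find-cgi`, `find-p53re`,
#'   `merge-promoters`, `predict-mre`, `simulate`.
#' @param inputs named list of input file paths (task-dependent: `fasta`,
#'   `catalog`, `table`, `mir`, `transcript`, `annotation`).
#' @param params named list of parameter overrides.
#' @param rng_seed integer seed for any randomness in the run.
#' @param out_dir output directory.
#' @return config list of class `run_config`.
#' @export
run_config <- function(task, inputs = list(), params = list(),
                       rng_seed = 1L, out_dir = tempfile("cisreg_run_")) {
  if (!task %in% .run_tasks) {
    abort(sprintf("unknown task '%s'; expected one of: %s",
                  task, paste(.run_tasks, collapse = ", ")))
  }
  structure(list(task = task, inputs = inputs, params = params,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys `task`, `inputs`, `params`, `rng_seed`,
#'   `out_dir`.
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(task = y$task, inputs = y$inputs %||% list(),
             params = y$params %||% list(),
             rng_seed = y$rng_seed %||% 1L,
             out_dir = y$out_dir %||% tempfile("cisreg_run_"))
}

.need_input <- function(config, key) {
  p <- config$inputs[[key]]
  if (is.null(p)) abort(sprintf("task '%s' requires input '%s'",
                                config$task, key))
  if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  p
}

write_manifest <- function(config, outputs) {
  checksums <- map_chr(config$inputs, function(p)
    unname(tools::md5sum(p)))
  manifest <- list(task = config$task,
                   package = "cisreg",
                   version = as.character(utils::packageVersion("cisreg")),
                   rng_seed = config$rng_seed,
                   params = config$params,
                   inputs = as.list(checksums),
                   outputs = as.list(outputs))
  path <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  path
}

#' Execute a configured run
#'
#' Delegates to the owning module, writes the task's result tables (TSV,
#' plus BED6 where the result is positional) under `out_dir`, and writes a
#' `manifest.yaml` recording parameters, seed and input checksums.
#'
#' @param config [run_config()] object or path to a YAML config.
#' @return the primary result (tibble or object), invisibly; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  out <- list()
  result <- switch(
    config$task,
    "scan-motifs" = {
      seqs <- read_fasta(.need_input(config, "fasta"))
      catalog <- if (!is.null(config$inputs$catalog)) {
        read_motif_catalog(config$inputs$catalog)
      } else motif_catalog()
      hits <- scan_catalog(seqs, catalog, strands = p$strands %||% "both")
      readr::write_tsv(hits, out$tsv <- file.path(config$out_dir, "motif_hits.tsv"))
      if (nrow(hits)) {
        write_bed(hits, out$bed <- file.path(config$out_dir, "motif_hits.bed"),
                  score_col = "mismatches", name_col = "motif")
      }
      hits
    },
    "find-cgi" = {
      seqs <- read_fasta(.need_input(config, "fasta"))
      params <- cgi_params(
        min_obs_exp = p$min_obs_exp %||% 0.60,
        min_gc_percent = p$min_gc_percent %||% 55.0,
        min_length = p$min_length %||% 200L,
        window = p$window %||% 100L, step = p$step %||% 1L)
      islands <- bind_rows(map(seq_len(nrow(seqs)), function(i)
        detect_cpg_islands(seqs[i, ], params)))
      readr::write_tsv(islands, out$tsv <- file.path(config$out_dir, "islands.tsv"))
      if (nrow(islands)) {
        islands$score <- round(100 * islands$obs_exp_cpg)
        write_bed(islands, out$bed <- file.path(config$out_dir, "islands.bed"),
                  score_col = "score")
      }
      islands
    },
    "find-p53re" = {
      seqs <- read_fasta(.need_input(config, "fasta"))
      consensus <- dimer_consensus(
        half_pattern = p$half_pattern %||% "RRRCWWGYYY",
        spacer_min = p$spacer_min %||% 0L,
        spacer_max = p$spacer_max %||% 13L,
        max_total_mismatches = p$max_mismatches %||% 3L)
      hits <- bind_rows(map(seq_len(nrow(seqs)), function(i)
        find_dimer_sites(seqs[i, ], consensus,
                         strands = p$strands %||% "both")))
      readr::write_tsv(hits, out$tsv <- file.path(config$out_dir, "p53re_hits.tsv"))
      if (nrow(hits)) {
        write_bed(hits, out$bed <- file.path(config$out_dir, "p53re_hits.bed"),
                  score_col = "mm_total")
      }
      hits
    },
    "merge-promoters" = {
      records <- read_promoter_records(.need_input(config, "table"))
      rp <- build_revised_promoter(records)
      readr::write_tsv(verify_spans(records),
                       out$spans <- file.path(config$out_dir, "span_check.tsv"))
      write_gff3(rp$interval,
                 out$gff3 <- file.path(config$out_dir, "revised_promoter.gff3"),
                 type = "promoter")
      rp
    },
    "predict-mre" = {
      mirs <- read_fasta(.need_input(config, "mir"), alphabet = "RNA")
      transcripts <- read_fasta(.need_input(config, "transcript"))
      ann <- if (!is.null(config$inputs$annotation)) {
        read_feature_annotation(config$inputs$annotation)
      } else NULL
      model <- energy_model()
      sites <- bind_rows(map(seq_len(nrow(mirs)), function(i) {
        bind_rows(map(seq_len(nrow(transcripts)), function(j) {
          st <- scan_transcript(mirs[i, ], transcripts[j, ], model = model,
                                max_sites = p$max_sites %||% 10L)
          if (nrow(st) > 0 && (p$calibrate %||% TRUE)) {
            cal <- calibrate_evd(mirs[i, ], transcripts[j, ], model = model,
                                 shuffle_count = p$shuffle_count %||% 100L,
                                 rng_seed = config$rng_seed)
            st <- site_pvalue(st, cal)
          }
          if (!is.null(ann)) {
            st <- map_to_features(
              st, filter(ann, .data$transcript_id == transcripts$id[j]))
          }
          st
        }))
      }))
      flat <- select(sites, -dplyr::any_of("structure"))
      readr::write_tsv(flat, out$tsv <- file.path(config$out_dir, "mre_sites.tsv"))
      if (nrow(sites) > 0 && "feature" %in% names(sites)) {
        readr::write_tsv(feature_counts(sites),
                         out$counts <- file.path(config$out_dir,
                                                 "mre_feature_counts.tsv"))
      }
      sites
    },
    "simulate" = {
      plants <- if (!is.null(config$inputs$plants)) {
        readr::read_tsv(config$inputs$plants, col_types = readr::cols())
      } else NULL
      spec <- simulation_spec(rng_seed = config$rng_seed,
                              length = p$length %||% 10000L,
                              gc_fraction = p$gc_fraction %||% 0.5,
                              plants = plants)
      sim <- simulate_sequence(spec)
      out <- as.list(write_simulation(sim, config$out_dir))
      sim
    })
  write_manifest(config, map_chr(out, identity))
  invisible(result)
}

#' Motif element map plot
#'
#' Draws motif/element hits as strand-coloured segments along a sequence,
#' one track per motif name -- the package's rendering of an annotated
#' promoter element map.
#'
#' @param hits hit tibble ([scan_catalog()], [find_dimer_sites()], or any
#'   tibble with `start`, `end`, `strand` and a `motif` column).
#' @param sequence_length optional x-axis limit.
#' @return a ggplot object.
#' @export
plot_element_map <- function(hits, sequence_length = NULL) {
  if (!"motif" %in% names(hits)) hits$motif <- "element"
  gg <- ggplot2::ggplot(hits) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$motif, yend = .data$motif,
                   colour = .data$strand),
      linewidth = 3) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "strand") +
    ggplot2::theme_minimal()
  if (!is.null(sequence_length)) {
    gg <- gg + ggplot2::xlim(1, sequence_length)
  }
  gg
}
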