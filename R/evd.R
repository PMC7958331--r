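# Significance statistics for hybridization sites: a dinucleotide-preserving
# shuffle defines the null, best-site length-normalised energies are fitted
# to a Gumbel (extreme-value) distribution, and multiple binding sites are
# assessed with a Poisson tail.

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: the returned sequence has exactly the
#' dinucleotide (and hence mononucleotide) counts of the input.  The null
#' preserves CpG/stacking composition, which dominates hybridization
#' energies.
#'
#' @param x single sequence string.
#' @param n number of shuffles.
#' @return character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(x, n = 1L) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 3) return(rep(paste(chars, collapse = ""), n))
  first <- chars[1]; last <- chars[L]
  verts <- unique(chars)
  edges <- split(chars[-1], chars[-L])  # adjacency lists of the edge multigraph
  shuffle_once <- function() {
    # choose a random last-edge per vertex (except `last`) until the
    # chosen edges form paths into `last` (guarantees an Eulerian walk)
    others <- setdiff(verts, last)
    repeat {
      last_edge <- vapply(others, function(u) {
        e <- edges[[u]]
        e[sample.int(length(e), 1L)]
      }, character(1))
      ok <- all(vapply(others, function(u) {
        seen <- character()
        while (u != last) {
          if (u %in% seen || !(u %in% names(last_edge))) return(FALSE)
          seen <- c(seen, u)
          u <- last_edge[[u]]
        }
        TRUE
      }, logical(1)))
      if (ok) break
    }
    walk_edges <- lapply(setNames(verts, verts), function(u) {
      e <- edges[[u]]
      if (is.null(e)) return(character())
      if (u %in% names(last_edge)) {
        # remove one instance of the reserved last edge, shuffle, re-append
        i <- match(last_edge[[u]], e)
        rest <- e[-i]
        c(rest[sample.int(length(rest))], last_edge[[u]])
      } else {
        e[sample.int(length(e))]
      }
    })
    used <- setNames(integer(length(verts)), verts)
    out <- character(L)
    out[1] <- first
    u <- first
    for (i in 2:L) {
      used[u] <- used[u] + 1L
      v <- walk_edges[[u]][used[u]]
      out[i] <- v
      u <- v
    }
    paste(out, collapse = "")
  }
  vapply(seq_len(n), function(i) shuffle_once(), character(1))
}

#' Calibrate the extreme-value null for hybridization energies
#'
#' Scans `shuffle_count` dinucleotide-shuffled copies of the target for
#' their best hybridization site, converts each best MFE to the
#' length-normalised score `x = -mfe / ln(m * n)` (m = miRNA length,
#' n = target length), and fits Gumbel location/scale by the method of
#' moments.  Deterministic given `rng_seed`.
#'
#' @param mir miRNA (string or one-row sequence tibble).
#' @param target target sequence providing the null composition.
#' @param model [energy_model()].
#' @param shuffle_count number of shuffled targets (>= 100 recommended;
#'   smaller values are allowed for quick checks).
#' @param rng_seed integer seed controlling the shuffles.
#' @param exhaustive scan every window of each shuffled target (default).
#'   The fitted statistic is the best score over the whole transcript;
#'   seed-anchored candidate windows would score a random number of
#'   windows per shuffle and distort the null.
#' @param ... passed to [scan_transcript()] (e.g. `window`, `step`).
#' @return object of class `evd_calibration` with fields `location`,
#'   `scale`, `normalization`, `mir_length`, `target_length`,
#'   `shuffle_count`, `rng_seed`, `scores`.
#' @export
calibrate_evd <- function(mir, target, model = energy_model(),
                          shuffle_count = 100L, rng_seed = 1L,
                          exhaustive = TRUE, ...) {
  mir <- seq_tbl(mir, alphabet = "RNA")
  target <- seq_tbl(target)
  ts <- target$seq[1]
  m <- nchar(mir$seq[1]); n <- nchar(ts)
  shuffled <- withr::with_seed(rng_seed, dinucleotide_shuffle(ts, shuffle_count))
  best_mfe <- map_dbl(shuffled, function(s) {
    sites <- scan_transcript(mir, s, model = model, max_sites = 1L,
                             exhaustive = exhaustive, ...)
    if (nrow(sites) == 0) 0 else sites$mfe[1]
  })
  x <- -best_mfe / log(m * n)
  if (sd(x) == 0) {
    abort("degenerate background: best-site scores have zero variance")
  }
  scale <- sd(x) * sqrt(6) / pi
  location <- mean(x) - 0.5772156649 * scale
  structure(list(location = location, scale = scale,
                 normalization = "length-normalized MFE: x = -mfe / ln(m*n)",
                 mir_length = m, target_length = n,
                 shuffle_count = as.integer(shuffle_count),
                 rng_seed = as.integer(rng_seed), scores = x),
            class = "evd_calibration")
}

#' @export
print.evd_calibration <- function(x, ...) {
  cat(sprintf(paste0("<EVD calibration> Gumbel(location = %.4f, scale = %.4f), ",
                     "%d shuffles, seed %d\n  %s\n"),
              x$location, x$scale, x$shuffle_count, x$rng_seed,
              x$normalization))
  invisible(x)
}

#' Gumbel p-value of hybridization sites
#'
#' `p = 1 - exp(-exp(-(x - location) / scale))` with `x` the
#' length-normalised score of the site's MFE under the calibration's
#' normalisation; strictly decreasing in `-mfe`.
#'
#' @param sites site tibble from [scan_transcript()], or a numeric vector
#'   of MFE values.
#' @param cal [calibrate_evd()] result.
#' @return for a tibble input, the tibble with a `p_value` column; for a
#'   numeric input, the numeric p-values.
#' @export
site_pvalue <- function(sites, cal) {
  stopifnot(inherits(cal, "evd_calibration"))
  pv <- function(mfe) {
    x <- -mfe / log(cal$mir_length * cal$target_length)
    1 - exp(-exp(-(x - cal$location) / cal$scale))
  }
  if (is.data.frame(sites)) return(mutate(sites, p_value = pv(.data$mfe)))
  pv(sites)
}

#' Poisson tail probability for multiple binding sites
#'
#' `P(K >= site_count)` under `K ~ Poisson(expected_rate)`, the standard
#' approximation for the significance of observing several sites on one
#' transcript.
#'
#' @param site_count observed number of sites (>= 0).
#' @param expected_rate expected site count under the null (> 0).
#' @return probability.
#' @examples
#' multi_site_pvalue(1, 0.5)  # 1 - exp(-0.5)
#' @export
multi_site_pvalue <- function(site_count, expected_rate) {
  stopifnot(all(expected_rate > 0), all(site_count >= 0))
  ppois(site_count - 1, expected_rate, lower.tail = FALSE)
}

#' Tidy a fitted EVD calibration
#'
#' @param x `evd_calibration` object.
#' @param ... unused.
#' @return tibble with one row per Gumbel parameter.
#' @export
tidy.evd_calibration <- function(x, ...) {
  tibble(term = c("location", "scale"), estimate = c(x$location, x$scale))
}

#' One-row summary of an EVD calibration
#'
#' @param x `evd_calibration` object.
#' @param ... unused.
#' @return tibble with fit parameters and provenance.
#' @export
glance.evd_calibration <- function(x, ...) {
  tibble(location = x$location, scale = x$scale,
         shuffle_count = x$shuffle_count, rng_seed = x$rng_seed,
         mir_length = x$mir_length, target_length = x$target_length)
}

#' Plot an EVD calibration
#'
#' Histogram of the null best-site scores with the fitted Gumbel density.
#'
#' @param object `evd_calibration` object.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.evd_calibration <- function(object, ...) {
  df <- tibble(x = object$scores)
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = 200))
  z <- (grid$x - object$location) / object$scale
  grid$density <- exp(-z - exp(-z)) / object$scale
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$density),
                       colour = "red") +
    ggplot2::labs(x = "length-normalised best-site score",
                  y = "density", title = "Null score distribution and Gumbel fit") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
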