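---
title: "Models and methods behind cisreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cisreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisreg)
```

This vignette records the statistical and algorithmic models the package
implements, the assumptions behind them, and the reasoning for every
default parameter. The running example is the regulatory landscape of the
human *MGMT*–*EBF3* genomic space (chromosome 10q26): the revised
exon-1 promoter assembled from five overlapping database promoters, its
two CpG islands, the CTCF recognition sequence, the two p53 response
elements in intron 1, and miRNA recognition elements on the *MGMT*
transcript.

## 1. Degenerate consensus motif scanning

A motif is an IUPAC consensus string; each code denotes a set of bases
(`R` = {A,G}, `N` = {A,C,G,T}, …). Internally every code is a 4-bit mask
and a subject base `b` satisfies a pattern code `c` iff
`mask(b) & mask(c) == mask(b)` — the subset rule. Two consequences worth
stating:

* A subject `N` (unknown base) never satisfies a narrower pattern code:
  an unknown base is not evidence of a match.
* Matching is case-insensitive, and `U` is treated as `T`.

`scan_motif()` counts, for every window and both strands, the number of
positions violating their code ("mismatches") and reports windows within
the motif's mismatch budget. Minus-strand hits are found by scanning the
reverse-complemented pattern on the forward sequence, so all coordinates
are forward-strand and 1-based inclusive.

**Exclusion patterns.** Some catalog consensi are deliberately broad and
carry exclusion patterns: a window matching the main pattern is vetoed if
it also matches any exclusion at zero mismatches. The bundled TATA-532
entry is the worked example: `HWHWWWWR` with four exclusions that remove
poly-A-like and CA-initiated windows.

**Defaults.** `max_mismatches = 0`: a degenerate consensus already
encodes its tolerated variation, so additional mismatches are opt-in per
motif. `strands = "both"`: regulatory elements are strand-agnostic until
proven otherwise. Overlap handling is explicit: `count_distinct_sites()`
clusters only hits that genuinely overlap (touching hits stay separate),
because runs such as `GAGAGAGA` produce nested windows that are one
biological site.

## 2. CpG-island statistics and detection

For a region of length $N$ with $n_C$ cytosines, $n_G$ guanines and
$n_{CG}$ CpG dinucleotides:

$$\%GC = 100\,\frac{n_C + n_G}{N}, \qquad
\mathrm{Obs/Exp}\ \mathrm{CpG} = \frac{n_{CG}}{n_C\,n_G / N}.$$

Obs/Exp is defined as 0 when $n_C n_G = 0$. These are the classical
island statistics; `region_stats()` evaluates them for any sub-interval
in O(1) from cumulative counts.

`detect_cpg_islands()` slides a 100-bp window at 1-bp steps, marks
windows that *strictly* exceed both thresholds (Obs/Exp > 0.60,
%GC > 55.0), merges maximal runs of passing windows into candidate
islands, and keeps those strictly longer than 200 bp. The defaults are
the Gardiner-Garden–Frommer criteria. The run-merge step is a documented
simplification relative to EMBOSS CPGplot (which smooths the per-window
profile before thresholding); boundaries can therefore differ from
CPGplot by roughly a window width at island edges, since a passing
window extends the island up to 99 bp into a flank. Reported islands
are re-scored as whole intervals, so every reported island satisfies the
thresholds as a region.

## 3. Spaced-dimer (p53 response element) search

A p53 response element is two `RRRCWWGYYY` decamer half-sites separated
by a spacer of 0–13 bp. `find_dimer_sites()` enumerates every
(position, spacer) placement on both strands and reports the per-half
and total mismatch counts within a budget; `best_dimer_match()` returns
the global optimum with deterministic tie-breaking (fewest total
mismatches, then smallest spacer, then leftmost start, then forward
strand). Because the half-site consensus is its own reverse complement,
minimum mismatch counts are invariant under reverse complement of the
subject — a property the test suite checks.

When the subject is shorter than two half-sites plus the requested
spacer, larger spacers are simply not enumerable; the search optimises
over the spacers that fit. On the two *MGMT* intron-1 elements bundled
with the package this yields minima of 1 and 3 total mismatches at
spacers 6 and 7.

## 4. Promoter interval union and coordinate mapping

Genomic intervals are 1-based inclusive throughout; `interval_union()`
merges overlapping *or touching* intervals (two abutting promoter
records describe contiguous sequence). `build_revised_promoter()`
additionally requires the member records to be pairwise connected and
names the offending record otherwise — silently unioning a disjoint
record would fabricate sequence. The bundled records reproduce the
2019-bp revised exon-1 promoter envelope
(chr10:129,466,183–129,468,201) from its five overlapping members, and
`local_to_genome()` / `genome_to_local()` interconvert envelope-local
and genomic positions (`genome = local + start − 1`). BED export is
0-based half-open and delegated to `rtracklayer`.

## 5. Hybridization energy model

`hybridize()` computes the minimum-free-energy intermolecular duplex
between a short RNA and a target window: intramolecular pairs are
disallowed, the strands pair antiparallel, and the structure is a
monotone chain of pairs separated by bulges and internal loops. The
dynamic program is exact for the model below and is verified against
exhaustive structure enumeration in the tests.

The energy model is deliberately simple — single-pair energies plus
affine loop penalties:

| term | default | rationale |
|---|---|---|
| GC pair | −3.0 | strongest pair, 3 H-bonds |
| AU pair | −2.0 | 2 H-bonds |
| GU wobble | −1.0 | weak but allowed |
| bulge open / extend | +3.0 / +0.5 per extra base | affine gap |
| internal loop open / extend | +2.0 / +0.5 per extra base | affine gap |
| max bulge/loop side | 15 | caps loop sizes |

This is not a nearest-neighbour thermodynamic parameter set; it is a
transparent scoring model whose optimum is reproducible and testable.
Absolute energies are therefore not comparable to laboratory ΔG values —
only rankings and calibrated p-values (below) are meaningful. Dangling
ends are free and the MFE is capped at 0 (no forced pairing).

**Site discovery.** `scan_transcript()` anchors candidate windows at
seed matches (perfect complementarity to miRNA positions 2–8, with 6mer
and GU-tolerant classes available) and falls back to exhaustive stepped
windows when no seed match exists; `exhaustive = TRUE` forces the
stepped scan. Sites are selected greedily by ascending MFE subject to
non-overlap, mirroring the optimal-plus-suboptimal-sites convention of
hybridization search tools. The window default (miRNA length + 15)
leaves room for target-side bulges; the step default (window/3)
guarantees every position is covered by at least two windows.

## 6. Significance statistics

**Null model.** Dinucleotide-preserving (Altschul–Erikson) shuffles of
the target: hybridization energy is dominated by stacking/composition at
the dinucleotide level, so a mononucleotide shuffle would be too easy to
beat. The shuffle is exact — every shuffled sequence has precisely the
original dinucleotide counts.

**Extreme-value fit.** For each shuffle the best whole-transcript site
MFE is converted to the length-normalised score

$$x = \frac{-\mathrm{mfe}}{\ln(m\,n)}$$

($m$ = miRNA length, $n$ = target length), and a Gumbel distribution is
fitted by the method of moments. `site_pvalue()` then reports
$p = 1 - \exp(-\exp(-(x-\mu)/\beta))$. The $\ln(mn)$ normalisation is
the standard correction for the search-space size of an
alignment-like optimum, making calibrations comparable across lengths.

Three practical caveats, each of which shaped the defaults:

1. *Calibration scans exhaustively.* The fitted statistic is the best
   score over the whole transcript. The seed-anchored heuristic scores a
   random number of windows per shuffle (one or two when a seed matches,
   the full transcript when none does), which yields a mixture rather
   than a clean maximum; `calibrate_evd()` therefore forces the
   exhaustive scan by default, and the heuristic remains a discovery
   accelerator only.
2. *Scores are lattice-valued.* Every energy parameter is a multiple of
   0.5, so best-site MFEs live on a 0.5-wide lattice and the fitted
   continuous CDF can never match the atomic empirical CDF below the
   atom mass. Distributional checks should use a lattice-aware statistic
   (the test suite jitters scores uniformly within one half-unit cell — a
   randomized probability integral transform — before testing
   uniformity).
3. *Extreme-value asymptotics need length.* The Gumbel family fits the
   null well only when the maximum is taken over enough effectively
   independent windows; targets of several hundred bp or less are below
   that regime and their calibrations should be treated as rough.

`shuffle_count` trades calibration quality for time: 100 shuffles
(the default floor) estimate location/scale to roughly ±10%; the
package's own distributional test uses 300. Calibration is deterministic
given `rng_seed`.

**Multiple sites.** `multi_site_pvalue(k, λ)` is the Poisson tail
$P(K \ge k)$ — the standard approximation for observing $k$ sites on one
transcript when $λ$ are expected under the null.

## 7. Synthetic data with planted truth

`simulation_spec()` + `simulate_sequence()` generate seeded synthetic
sequences with planted structure and exact ground-truth records, so
every scanner can be benchmarked without downloads:

* background: i.i.d. bases at a chosen GC fraction;
* `plant_mismatched_instance()`: a concrete instance violating an IUPAC
  pattern at *exactly* k positions (an `N` position admits no violation);
* `synth_cgi_block()`: exact base composition for the target %GC, then a
  bounded local swap search moves the CpG count to the target Obs/Exp —
  this reaches depleted (Obs/Exp < 1) and strongly enriched targets
  alike, which rejection sampling from an i.i.d. model cannot;
* dimer and MRE plants compose the primitives above.

Plants must fit and be pairwise disjoint; violations raise errors before
any output. Identical specs produce byte-identical FASTA/BED/TSV output.
The realism limit is explicit: i.i.d. backgrounds have no repeats,
isochores or composition gradients, so false-positive rates measured on
them are optimistic lower bounds for genomic sequence.

## 8. Problem sizes

Benchmarks and tests in this package run on sequences of 200 bp to
100 kb, calibrations of 100–400 shuffles, and exhaustive oracles up to
10 kb (scan), 200 bp (dimer enumeration) and 8 × 12 nt (duplex
enumeration). These sizes are the package's own choices, selected so
that every exact cross-check completes in minutes on one CPU while still
exercising the asymptotic regimes the statistics assume.

## 9. Resolved ambiguities

Decisions where the domain literature is loose, recorded so users know
what the package does:

* **ERE/GRE half-sites:** the catalog stores the full palindromic
  consensus (`GGTCANNNTGACC`, `AGAACANNNTGTTCT`); half-site searches are
  expressed as their own catalog entries rather than a special mode.
* **ARE annotation extents:** published ARE annotations often quote
  longer flanking extents; the catalog stores the functional core
  `TGACNNNGC`, and flanks are recoverable from hit coordinates.
* **p53 spacer reports:** published spacer values for specific elements
  sometimes exceed what the printed sequence can contain; the search
  optimises over spacers that geometrically fit and reports the
  achieved optimum, which reproduces published mismatch counts.
* **Island boundaries:** run-merge boundaries (not CPGplot-smoothed);
  see section 2.

## 10. Reproducibility surface

Every stochastic entry point takes an explicit seed (`simulation_spec`,
`calibrate_evd`), every pipeline run writes a manifest (parameters,
package version, seed, input checksums), and `scripts/acceptance.R` in
the source repository recomputes the headline quantities from scratch:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
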