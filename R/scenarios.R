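## Two anchored benchmark scenarios: a five-chromosome complex
## translocation/chromothripsis topology whose 15 chains link into 5
## derivative chromosomes (23 segments, 18 junctions), and a single
## chromosome complex rearrangement whose unique linkage reveals three
## emergent sequence losses.

#' Complex five-chromosome rearrangement scenario
#'
#' Builds five synthetic chromosomes and a derivative structure with the
#' topology: der9 = chr9-left + three chr4 fragments + one chr14 fragment +
#' chr14-right; der14 = chr14-left + chr9-right; der7 = chr7-left +
#' chr15-right; der15 = chr15-left + nine interleaved chr7/chr15 fragments
#' (three from chr7, six from chr15) + chr7-right; der4 = chr4 with an
#' internal 6-kb deletion (at scale 1).  That is 5 derivatives, 23
#' segments, 18 junctions; the truth is also decomposed into 15 chains
#' (read groups) whose parsimony linkage is unique.  Coordinates are in
#' units of `1000 * scale` bases.
#'
#' @param scale fragment-size multiplier (>= 1).
#' @param seed integer seed for sequence and reads.
#' @param with_reads simulate noisy reads from the derived genome.
#' @param coverage read coverage of the derived genome.
#' @param model error model for reads.
#' @param length_law read-length law (defaults scale with `scale`).
#' @param n_controls control individuals (reads from the unrearranged
#'   reference; they carry none of the scenario junctions).
#' @return list: `genome`, `chrom_lengths`, `derived`, `truth` (list with
#'   `structures`, `junctions`, `chains`), and with reads also `reads`,
#'   `read_truth`, `controls`.
#' @export
scenario_patient3 <- function(scale = 1L, seed = 1L, with_reads = TRUE,
                              coverage = 10, model = nanopore_error_model(),
                              length_law = NULL, n_controls = 0L) {
  stopifnot(scale >= 1)
  u <- 1000L * as.integer(scale)
  chrom_lengths <- c(chr4 = 60L, chr7 = 60L, chr9 = 60L, chr14 = 60L,
                     chr15 = 80L) * u
  genome <- make_reference(chrom_lengths, seed = seed)
  seg <- function(chrom, s, e, o = "+") seg_row(chrom, s * u, e * u, o)
  structures <- list(
    der4 = rbind(seg("chr4", 0, 10), seg("chr4", 16, 60)),
    der7 = rbind(seg("chr7", 0, 25), seg("chr15", 70, 80)),
    der9 = rbind(seg("chr9", 0, 30), seg("chr4", 40, 42, "-"),
                 seg("chr4", 44, 47), seg("chr4", 35, 38),
                 seg("chr14", 20, 23, "-"), seg("chr14", 30, 60)),
    der14 = rbind(seg("chr14", 0, 20), seg("chr9", 35, 60)),
    der15 = rbind(seg("chr15", 0, 30), seg("chr15", 40, 43, "-"),
                  seg("chr7", 30, 33), seg("chr15", 48, 52),
                  seg("chr15", 55, 56, "-"), seg("chr7", 36, 38, "-"),
                  seg("chr15", 58, 59), seg("chr15", 62, 63, "-"),
                  seg("chr7", 40, 42), seg("chr15", 66, 68),
                  seg("chr7", 50, 60)))
  # the 15 read groups (chains), each covering 1-2 junctions, cut inside
  # quiet colinear stretches so their linkage is forced
  segf <- function(chrom, s, e, o = "+") seg_row(chrom, round(s * u), round(e * u), o)
  chain_defs <- list(
    g1 = rbind(segf("chr9", 10, 30), segf("chr4", 40, 42, "-"), segf("chr4", 44, 45.5)),
    g2 = rbind(segf("chr4", 45.8, 47), segf("chr4", 35, 36.5)),
    g3 = rbind(segf("chr4", 36.8, 38), segf("chr14", 21.8, 23, "-")),
    g4 = rbind(segf("chr14", 20, 21.5, "-"), segf("chr14", 30, 50)),
    h1 = rbind(segf("chr14", 5, 20), segf("chr9", 35, 55)),
    k1 = rbind(segf("chr7", 10, 25), segf("chr15", 70, 78)),
    m1 = rbind(segf("chr15", 15, 30), segf("chr15", 41.7, 43, "-")),
    m2 = rbind(segf("chr15", 40, 41.4, "-"), segf("chr7", 30, 31.5)),
    m3 = rbind(segf("chr7", 31.8, 33), segf("chr15", 48, 49.5)),
    m4 = rbind(segf("chr15", 49.8, 52), segf("chr15", 55, 56, "-"),
               segf("chr7", 36.6, 38, "-")),
    m5 = rbind(segf("chr7", 36, 36.3, "-"), segf("chr15", 58, 59),
               segf("chr15", 62.4, 63, "-")),
    m6 = rbind(segf("chr15", 62, 62.2, "-"), segf("chr7", 40, 41.2)),
    m7 = rbind(segf("chr7", 41.5, 42), segf("chr15", 66, 67)),
    m8 = rbind(segf("chr15", 67.3, 68), segf("chr7", 50, 58)),
    d1 = rbind(segf("chr4", 5, 10), segf("chr4", 16, 25)))
  chains <- lapply(names(chain_defs), function(id) build_chain(chain_defs[[id]], id))
  derived <- derive_sequences(genome, structures)
  out <- list(genome = genome, chrom_lengths = chrom_lengths,
              derived = derived,
              truth = list(structures = structures,
                           junctions = truth_junctions(structures, min_gap = 1L),
                           chains = chains))
  if (with_reads) {
    if (is.null(length_law)) {
      length_law <- list(mean = 8 * u, sd = 0.3, min = 2 * u)
    }
    rr <- simulate_reads(derived, coverage = coverage, length_law = length_law,
                         model = model, seed = seed + 1L)
    out$reads <- rr$reads
    out$read_truth <- rr$truth
    if (n_controls > 0) {
      out$controls <- lapply(seq_len(n_controls), function(i) {
        simulate_reads(genome, coverage = coverage, length_law = length_law,
                       model = model, seed = seed + 100L + i,
                       prefix = sprintf("c%d_", i))
      })
    }
  }
  out
}

#' Single-chromosome complex rearrangement with emergent losses
#'
#' Three chains over one chromosome whose unique parsimony linkage yields a
#' single linear derivative with three sequence losses that are apparent
#' only after full reconstruction.  With `absolute_coords = TRUE` the
#' chains live on a 135,086,622-bp coordinate-only chromosome and the
#' losses are chr11:54633567-54685157 (51 kb), chr11:55071498-55088834
#' (17 kb), and chr11:55263629-55274386 (10 kb) in 1-based inclusive
#' coordinates (converted internally to 0-based half-open); with
#' `absolute_coords = FALSE` a scaled sequence-level version of the same
#' topology is returned for end-to-end runs.
#'
#' @param absolute_coords use the printed chromosome-scale coordinates
#'   (coordinate-only; no sequence is instantiated).
#' @param scale,seed for the scaled sequence-level variant.
#' @return list: `chains`, `chrom_lengths`, `expected_losses`
#'   (0-based half-open), plus `genome`/`derived`/`truth` for the scaled
#'   variant.
#' @export
scenario_chr11 <- function(absolute_coords = TRUE, scale = 1L, seed = 1L) {
  if (absolute_coords) {
    # printed 1-based inclusive loss coordinates, converted to 0-based
    losses <- data.frame(
      chrom = "chr11",
      start = c(54633567L, 55071498L, 55263629L) - 1L,
      end = c(54685157L, 55088834L, 55274386L))
    chain_defs <- list(
      cA = rbind(seg_row("chr11", 54400000, 54633566),
                 seg_row("chr11", 55180000, 55263628, "-")),
      cB = rbind(seg_row("chr11", 55088834, 55170000, "-"),
                 seg_row("chr11", 54685157, 54800000)),
      cC = rbind(seg_row("chr11", 54900000, 55071497),
                 seg_row("chr11", 55274386, 55400000)))
    chains <- lapply(names(chain_defs), function(id) build_chain(chain_defs[[id]], id))
    return(list(chains = chains, chrom_lengths = c(chr11 = 135086622L),
                expected_losses = losses))
  }
  u <- 1000L * as.integer(scale)
  chrom_lengths <- c(chrZ = 200L * u)
  genome <- make_reference(chrom_lengths, seed = seed)
  structures <- list(derZ = rbind(
    seg_row("chrZ", 0, 54 * u),
    seg_row("chrZ", 75 * u, 95 * u, "-"),
    seg_row("chrZ", 59 * u, 71 * u),
    seg_row("chrZ", 99 * u, 200 * u)))
  chain_defs <- list(
    cA = rbind(seg_row("chrZ", 40 * u, 54 * u), seg_row("chrZ", 88 * u, 95 * u, "-")),
    cB = rbind(seg_row("chrZ", 75 * u, 84 * u, "-"), seg_row("chrZ", 59 * u, 63 * u)),
    cC = rbind(seg_row("chrZ", 66 * u, 71 * u), seg_row("chrZ", 99 * u, 110 * u)))
  chains <- lapply(names(chain_defs), function(id) build_chain(chain_defs[[id]], id))
  losses <- data.frame(chrom = "chrZ",
                       start = c(54, 71, 95) * u, end = c(59, 75, 99) * u)
  list(chains = chains, chrom_lengths = chrom_lengths,
       expected_losses = losses, genome = genome,
       derived = derive_sequences(genome, structures),
       truth = list(structures = structures,
                    junctions = truth_junctions(structures, min_gap = 1L)))
}
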