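## End-to-end convenience: reads -> split alignment -> junctions ->
## control subtraction -> corroboration -> groups -> consensus -> chains ->
## parsimony linking -> loss/gain report.

#' Run the full rearrangement-detection pipeline
#'
#' @param reads named [Biostrings::DNAStringSet] of case reads.
#' @param genome named [Biostrings::DNAStringSet] reference, or a
#'   [genome_index()].
#' @param controls list of control junction tables (or segment tables from
#'   [align_reads()], or DNAStringSets of control reads, which are aligned).
#' @param model error model used for scoring and consensus weighting.
#' @param min_gap forward-gap threshold for junction extraction.
#' @param tol breakend tolerance.
#' @param min_support,min_group corroboration / grouping thresholds.
#' @param max_mismap mismap filter for junction extraction.
#' @param link also link consensus chains and report losses/gains.
#' @param consensus compute per-group consensus sequences.
#' @param refine_breakpoints compute consensus-refined breakend positions
#'   per junction cluster ([call_junctions()]).
#' @param ... passed to [align_reads()].
#' @return list with `segments`, `junctions`, `filtered`, `groups`,
#'   `consensus` (per group, with `chain_alignment` and `junctions`),
#'   `junction_calls` (consensus-refined breakend positions per junction
#'   cluster), and optionally `reconstruction` + `loss_gain`.
#' @export
run_pipeline <- function(reads, genome, controls = list(),
                         model = nanopore_error_model(),
                         min_gap = 10000L, tol = 2000L, min_support = 2L,
                         min_group = 3L, max_mismap = 0.5, link = TRUE,
                         consensus = TRUE, refine_breakpoints = TRUE, ...) {
  scheme <- log_odds_scores(add_pseudo(model))
  index <- if (inherits(genome, "genome_index")) genome else genome_index(genome)
  segments <- align_reads(reads, index, scheme, ...)
  junctions <- extract_all_junctions(segments, min_gap, max_mismap)
  ctrl_tabs <- lapply(controls, function(ct) {
    if (is.data.frame(ct) && all(c("chrom1", "pos1") %in% names(ct))) return(ct)
    if (is.data.frame(ct)) return(extract_all_junctions(ct, min_gap, max_mismap))
    extract_all_junctions(align_reads(ct, index, scheme, ...), min_gap, max_mismap)
  })
  filtered <- subtract_controls(junctions, ctrl_tabs, tol)
  filtered <- require_corroboration(filtered, tol, min_support)
  groups <- group_reads(filtered, tol, min_group)
  out <- list(segments = segments, junctions = junctions, filtered = filtered,
              groups = groups, scheme = scheme, index = index)
  if (length(groups) == 0) return(out)
  if (refine_breakpoints) {
    out$junction_calls <- call_junctions(groups, reads, segments, filtered,
                                         index, scheme, model,
                                         min_gap = min_gap, tol = tol,
                                         max_mismap = max_mismap)
  }
  if (!consensus) return(out)
  cons <- lapply(groups, function(g) {
    cc <- merge_group(g, reads, model, scheme, junctions = filtered,
                      segments = segments)
    consensus_chain(cc, index, scheme, min_gap = min_gap,
                    max_mismap = max_mismap)
  })
  out$consensus <- cons
  if (link) {
    chains <- lapply(cons, build_chain)
    chains <- chains[vapply(chains, function(ch) nrow(ch$segments) >= 1, TRUE)]
    lens <- stats::setNames(Biostrings::width(genomify(index)), index$chroms)
    out$reconstruction <- link_chains(chains, lens)
    out$loss_gain <- report_loss_gain(out$reconstruction, lens)
  }
  out
}

genomify <- function(index) {
  Biostrings::DNAStringSet(stats::setNames(
    substring(index$concat, index$offsets + 1L, index$offsets + index$lengths),
    index$chroms))
}

#' Consensus-refined breakend positions per junction cluster
#'
#' For every junction cluster of every group, the reads supporting the
#' cluster are merged into a local consensus (star alignment around the
#' longest supporting read), the consensus is re-aligned, and the matching
#' consensus junction provides the refined breakend positions.  Falls back
#' to the cluster median if the consensus does not reproduce the junction.
#'
#' @inheritParams run_pipeline
#' @param segments,junctions tables from the pipeline.
#' @param index,scheme alignment machinery.
#' @return data.frame: group, cluster columns (`chrom1,pos1,dir1,...`),
#'   refined `pos1`/`pos2`, `source` ("consensus" or "cluster_median").
#' @export
call_junctions <- function(groups, reads, segments, junctions, index, scheme,
                           model = nanopore_error_model(), min_gap = 10000L,
                           tol = 2000L, max_mismap = 0.5) {
  rows <- list()
  for (g in groups) {
    cl <- g$junction_clusters
    for (i in seq_len(nrow(cl))) {
      cluster <- cl[i, , drop = FALSE]
      jj <- junctions[junctions$read_id %in% g$read_ids, , drop = FALSE]
      m <- junctions_match_table(jj, cluster, tol)
      support_ids <- unique(jj$read_id[m])
      if (length(support_ids) == 0) next
      sub <- list(id = sprintf("%s_j%d", g$id, i), read_ids = support_ids,
                  junction_clusters = cluster)
      cc <- merge_group(sub, reads, model, scheme,
                        junctions = jj[m, , drop = FALSE], segments = segments,
                        max_reads = 8L)
      cc <- consensus_chain(cc, index, scheme, min_gap = min_gap,
                            max_mismap = max_mismap)
      cj <- cc$junctions
      refined <- NULL
      if (nrow(cj)) {
        cand <- which(junctions_match_table(cj, cluster, tol * 2))
        if (length(cand)) {
          d <- abs(cj$pos1[cand] - cluster$pos1) + abs(cj$pos2[cand] - cluster$pos2)
          refined <- cj[cand[which.min(d)], , drop = FALSE]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g$id, chrom1 = cluster$chrom1, dir1 = cluster$dir1,
        chrom2 = cluster$chrom2, dir2 = cluster$dir2,
        pos1 = if (is.null(refined)) cluster$pos1 else refined$pos1,
        pos2 = if (is.null(refined)) cluster$pos2 else refined$pos2,
        n_reads = length(support_ids),
        source = if (is.null(refined)) "cluster_median" else "consensus",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), chrom1 = character(),
                      dir1 = character(), chrom2 = character(),
                      dir2 = character(), pos1 = integer(), pos2 = integer(),
                      n_reads = integer(), source = character())
  }
  out
}

# vectorized: does each row of A match the single junction `b`?
junctions_match_table <- function(A, b, tol) {
  if (nrow(A) == 0) return(logical(0))
  direct <- A$chrom1 == b$chrom1 & A$dir1 == b$dir1 & abs(A$pos1 - b$pos1) <= tol &
    A$chrom2 == b$chrom2 & A$dir2 == b$dir2 & abs(A$pos2 - b$pos2) <= tol
  swapped <- A$chrom1 == b$chrom2 & A$dir1 == b$dir2 & abs(A$pos1 - b$pos2) <= tol &
    A$chrom2 == b$chrom1 & A$dir2 == b$dir1 & abs(A$pos2 - b$pos1) <= tol
  direct | swapped
}

#' Compare called junctions with truth junctions
#'
#' Matches each called junction to the nearest truth junction with the same
#' breakend signature and reports the per-breakend absolute offsets.
#'
#' @param calls data.frame from [call_junctions()].
#' @param truth truth junction table ([truth_junctions()]).
#' @param tol maximum matching distance.
#' @return data.frame with one row per matched call: `offset1`, `offset2`,
#'   and `offset` (mean of the two).
#' @export
junction_offsets <- function(calls, truth, tol = 2000L) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    b <- calls[i, , drop = FALSE]
    m <- which(junctions_match_table(truth, b, tol))
    if (length(m) == 0) next
    d1 <- abs(truth$pos1[m] - b$pos1); d2 <- abs(truth$pos2[m] - b$pos2)
    # handle swapped orientation
    s1 <- abs(truth$pos1[m] - b$pos2); s2 <- abs(truth$pos2[m] - b$pos1)
    use_swap <- (s1 + s2) < (d1 + d2) &
      truth$chrom1[m] == b$chrom2 & truth$dir1[m] == b$dir2
    o1 <- ifelse(use_swap, s1, d1); o2 <- ifelse(use_swap, s2, d2)
    k <- which.min(o1 + o2)
    rows[[length(rows) + 1L]] <- data.frame(
      group = b$group, truth_index = m[k], offset1 = o1[k], offset2 = o2[k],
      offset = (o1[k] + o2[k]) / 2)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(group = character(), truth_index = integer(),
                                      offset1 = numeric(), offset2 = numeric(),
                                      offset = numeric())
  out
}
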