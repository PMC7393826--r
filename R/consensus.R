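## Group consensus: star alignment of each read to a backbone read with
## model-weighted plurality calling, then re-alignment of the consensus to
## the reference to tighten breakpoints.

#' Pick the backbone read of a group
#'
#' The read maximizing, in order: number of the group's junction clusters
#' it covers, total aligned length, then lexicographically smallest id.
#'
#' @param group a group from [group_reads()].
#' @param junctions junction data.frame of the group's reads.
#' @param segments segment data.frame of the group's reads.
#' @param tol breakend tolerance used for cluster coverage.
#' @return the backbone read id.
#' @export
pick_backbone <- function(group, junctions, segments, tol = 2000L) {
  ids <- group$read_ids
  stopifnot(length(ids) >= 1)
  clusters <- group$junction_clusters
  n_cov <- vapply(ids, function(id) {
    jj <- junctions[junctions$read_id == id, , drop = FALSE]
    if (nrow(jj) == 0 || nrow(clusters) == 0) return(0L)
    sum(junction_has_match(clusters, jj, tol))
  }, 0L)
  alen <- vapply(ids, function(id) {
    ss <- segments[segments$read_id == id, , drop = FALSE]
    sum(ss$read_end - ss$read_start)
  }, 0)
  ids[order(-n_cov, -alen, ids)][1]
}

# orient a read against the backbone by shared-seed voting; the band is set
# from the dominant diagonal stripe (read parts aligning elsewhere are
# clipped by the overlap alignment, not chased with a huge band).
orient_to_backbone <- function(read, backbone, k = 13L, max_per = 16L,
                               stripe_gap = 200L) {
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp_chr(read)
    h <- cpp_seed_hits(backbone, q, k, max_per)
    n <- length(h$ref_pos)
    if (n == 0) next
    if (is.null(best) || n > best$n) {
      d <- sort(h$ref_pos - h$query_pos)
      stripe <- cumsum(c(1L, diff(d) > stripe_gap))
      top <- which.max(tabulate(stripe))
      dd <- d[stripe == top]
      best <- list(strand = strand, n = n,
                   diag_lo = dd[1], diag_hi = dd[length(dd)])
    }
  }
  best
}

#' Merge a read group into a consensus sequence
#'
#' Each non-backbone read is aligned to the backbone by banded overlap
#' alignment (orientation chosen by shared-seed voting; the band doubles on
#' band-edge hits up to `band_max`).  Consensus is per-column weighted
#' plurality over the aligned reads, weights `1 - p_err` with `p_err` the
#' model's expected per-base error; columns where a gap wins are deleted,
#' ties keep the backbone base, and insertions relative to the backbone are
#' included when more than half of the covering reads agree on them.
#'
#' @param group a group from [group_reads()].
#' @param reads named [Biostrings::DNAStringSet] holding the group's reads.
#' @param model an `error_model` (weighting); default nanopore-like.
#' @param scheme score scheme for the read-to-backbone alignments; default
#'   derived from `model`.
#' @param band initial alignment band half-width (>= 20); `band_max` cap.
#' @param junctions,segments,tol passed to [pick_backbone()]; if omitted
#'   the longest read is the backbone.
#' @param max_reads depth cap: only the longest `max_reads` reads (plus the
#'   backbone) enter the merge; consensus accuracy saturates well below it.
#' @param rounds consensus refinement rounds: after the first star call the
#'   reads are re-aligned to the draft consensus, which repairs deletions
#'   and indel-placement artifacts inherited from the backbone read
#'   (default 2).
#' @return a `group_consensus` object: `group_id`, `sequence`, `support`
#'   (per-position read depth), `reads_used`, `backbone`.
#' @export
merge_group <- function(group, reads, model = nanopore_error_model(),
                        scheme = NULL, band = 100L, band_max = 1600L,
                        junctions = NULL, segments = NULL, tol = 2000L,
                        max_reads = 15L, rounds = 2L) {
  stopifnot(band >= 20)
  if (is.null(scheme)) scheme <- log_odds_scores(add_pseudo(model))
  ids <- group$read_ids
  seqs <- toupper(as.character(reads[ids]))
  backbone_id <- if (!is.null(junctions) && !is.null(segments)) {
    pick_backbone(group, junctions, segments, tol)
  } else ids[order(-nchar(seqs), ids)][1]
  if (length(ids) > max_reads) { # deepest groups: longest reads suffice
    keep <- ids[order(-nchar(seqs), ids)][seq_len(max_reads)]
    ids <- union(backbone_id, keep)[seq_len(max_reads)]
    seqs <- seqs[ids]
  }
  scaffold <- seqs[[backbone_id]]
  used <- character(0)
  for (round in seq_len(rounds)) {
    res <- star_call(scaffold, seqs, model, scheme, band, band_max,
                     self_id = if (round == 1) backbone_id else NULL)
    scaffold <- res$sequence
    used <- res$used
    if (length(used) <= 1) break
  }
  structure(list(group_id = group$id, sequence = res$sequence,
                 support = res$support, reads_used = used,
                 backbone = backbone_id),
            class = "group_consensus")
}

# one round of star consensus: align every read to the scaffold by banded
# overlap alignment and take the weighted plurality per column
star_call <- function(scaffold, seqs, model, scheme, band, band_max,
                      self_id = NULL) {
  bb <- scaffold
  Lb <- nchar(bb)
  ids <- names(seqs)
  p_err <- expected_error_rate(model)
  w <- 1 - p_err
  # votes: 5 x Lb (A,C,G,T,gap); insertions keyed by backbone position
  votes <- matrix(0, 5, Lb)
  depth <- numeric(Lb)
  ins_tab <- list()
  used <- character(0)
  for (id in ids) {
    s <- seqs[[id]]
    if (!is.null(self_id) && id == self_id) {
      aln <- list(cigar = sprintf("%d=", Lb), query_start = 0L, ref_start = 0L)
      q <- s
    } else {
      ori <- orient_to_backbone(s, bb)
      if (is.null(ori)) { warning("read ", id, " shares no seeds with backbone; excluded"); next }
      q <- if (ori$strand == "+") s else revcomp_chr(s)
      b <- band
      repeat {
        aln <- cpp_band_align(bb, q, as.integer(t(scheme$subs)),
                              scheme$del_open, scheme$del_ext,
                              scheme$ins_open, scheme$ins_ext,
                              as.integer(ori$diag_lo - b), as.integer(ori$diag_hi + b), 1L)
        if (!isTRUE(aln$edge) || b >= band_max) break
        b <- b * 2L
      }
      if (!isTRUE(aln$ok) || aln$score <= 0) {
        warning("read ", id, " failed to align to backbone; excluded"); next
      }
    }
    used <- c(used, id)
    cg <- parse_cigar(aln$cigar)
    qp <- aln$query_start; rp <- aln$ref_start
    for (j in seq_along(cg$op)) {
      len <- cg$len[j]
      op <- cg$op[j]
      if (op == "=" || op == "X") {
        pos <- (rp + 1L):(rp + len)
        base_idx <- match(strsplit(substr(q, qp + 1L, qp + len), "")[[1]],
                          c("A", "C", "G", "T"))
        okb <- !is.na(base_idx)
        if (any(okb)) {
          idx <- cbind(base_idx[okb], pos[okb]) # positions unique within a run
          votes[idx] <- votes[idx] + w
        }
        depth[pos] <- depth[pos] + 1
        qp <- qp + len; rp <- rp + len
      } else if (op == "D") {
        pos <- (rp + 1L):(rp + len)
        votes[5, pos] <- votes[5, pos] + w
        depth[pos] <- depth[pos] + 1
        rp <- rp + len
      } else { # I
        key <- as.character(rp)   # insertion before backbone position rp (0-based)
        insseq <- substr(q, qp + 1L, qp + len)
        ins_tab[[key]] <- c(ins_tab[[key]], insseq)
        qp <- qp + len
      }
    }
  }
  # plurality call per backbone column
  bbv <- strsplit(bb, "")[[1]]
  bb_idx <- match(bbv, c("A", "C", "G", "T"))
  mx <- pmax(votes[1, ], votes[2, ], votes[3, ], votes[4, ], votes[5, ])
  call_idx <- max.col(t(votes), ties.method = "first")
  idx_ok <- which(!is.na(bb_idx))
  tie <- votes[cbind(bb_idx[idx_ok], idx_ok)] == mx[idx_ok]
  call_idx[idx_ok[tie]] <- bb_idx[idx_ok[tie]]
  # assemble: plurality bases, then splice in majority insertions
  alphabet <- c("A", "C", "G", "T")
  base_keep <- which(call_idx != 5L)
  seq_v <- alphabet[call_idx[base_keep]]
  supp_v <- as.integer(round(depth[base_keep]))
  acc <- list()
  for (key in names(ins_tab)) {
    strs <- ins_tab[[key]]
    pos0 <- as.integer(key)
    cov <- if (pos0 >= 1 && pos0 <= Lb) depth[pos0] else length(used)
    tab <- table(strs)
    top <- names(tab)[which.max(tab)]
    if (tab[[top]] > cov / 2) {
      acc[[length(acc) + 1L]] <- list(pos0 = pos0, seq = top, n = tab[[top]])
    }
  }
  if (length(acc)) {
    acc <- acc[order(vapply(acc, `[[`, 0L, "pos0"))]
    offset <- 0L
    for (a in acc) {
      at <- findInterval(a$pos0, base_keep) + offset
      seq_v <- append(seq_v, strsplit(a$seq, "")[[1]], after = at)
      supp_v <- append(supp_v, rep(as.integer(a$n), nchar(a$seq)), after = at)
      offset <- offset + nchar(a$seq)
    }
  }
  list(sequence = paste(seq_v, collapse = ""), support = supp_v, used = used)
}

expected_error_rate <- function(model) {
  subs <- 1 - mean(diag(model$p_sub))
  gl <- function(open, ext) if (open <= 0) 0 else open / (1 - ext)
  min(0.75, subs + gl(model$p_del_open, model$p_del_extend) +
        gl(model$p_ins_open, model$p_ins_extend))
}

# a copy of the model guaranteed free of exact zeros (for scoring)
add_pseudo <- function(model, eps = 1e-4) {
  p <- model$p_sub + eps
  p <- p / rowSums(p)
  new_error_model(p, max(model$p_del_open, eps), max(model$p_del_extend, eps),
                  max(model$p_ins_open, eps), max(model$p_ins_extend, eps),
                  model$background)
}

#' @export
print.group_consensus <- function(x, ...) {
  cat(sprintf("Consensus of %s: %d bp from %d reads (backbone %s), median depth %g\n",
              x$group_id, nchar(x$sequence), length(x$reads_used), x$backbone,
              stats::median(x$support)))
  invisible(x)
}

#' Re-align a group consensus to the reference
#'
#' Runs split alignment of the consensus sequence and recomputes its
#' junctions; in practice this rarely changes the picture relative to the
#' raw-read junction clusters, but it tightens breakpoint positions to
#' around a base.
#'
#' @param consensus a `group_consensus`.
#' @param index a [genome_index()].
#' @param scheme score scheme.
#' @param min_gap,max_mismap junction extraction parameters.
#' @param ... passed to [align_read()].
#' @return the consensus with `chain_alignment` (segment data.frame) and
#'   `junctions` filled in.
#' @export
consensus_chain <- function(consensus, index, scheme, min_gap = 10000L,
                            max_mismap = 0.5, ...) {
  stopifnot(nchar(consensus$sequence) >= 1)
  aln <- align_read(consensus$sequence, index, scheme,
                    read_id = consensus$group_id, ...)
  aln$profile <- NULL
  consensus$chain_alignment <- aln
  consensus$junctions <- extract_junctions(aln, min_gap, max_mismap)
  consensus
}
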