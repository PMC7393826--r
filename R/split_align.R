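## Seed-and-extend split alignment with mismap probabilities.
##
## A didactic self-contained aligner: exact-seed lookup on both strands,
## banded affine local extension around each seed cluster, a dynamic
## program choosing the most-likely division of the read among candidate
## alignments, and a softmax mismap probability per chosen segment.
## Externally produced alignments (LAST-dialect MAF) can be substituted at
## any point via read_maf().

#' Build a seed index over a reference genome
#'
#' Chromosomes are concatenated with `N` spacers (seeds never cross
#' chromosome boundaries) and indexed by exact k-mer.
#'
#' @param genome named [Biostrings::DNAStringSet] (or named character).
#' @param min_seed exact seed length (k), at least 8.
#' @param max_per ignore seeds occurring more than this many times.
#' @return a `genome_index` object.
#' @export
genome_index <- function(genome, min_seed = 13L, max_per = 64L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(length(genome) >= 1, !is.null(names(genome)), min_seed >= 8)
  seqs <- toupper(as.character(genome))
  if (any(nchar(seqs) < 1)) stop("empty chromosome in genome")
  spacer <- strrep("N", min_seed)
  concat <- paste(seqs, collapse = spacer)
  lens <- nchar(seqs)
  offsets <- cumsum(c(0L, utils::head(lens + min_seed, -1L)))
  structure(list(
    concat = concat, chroms = names(genome),
    lengths = stats::setNames(lens, names(genome)),
    offsets = stats::setNames(offsets, names(genome)),
    k = as.integer(min_seed), max_per = as.integer(max_per),
    ptr = cpp_seed_index(concat, as.integer(min_seed))),
    class = "genome_index")
}

# XPtr survives neither serialization nor (in some cases) package reload;
# rebuild lazily.
index_ptr <- function(index) {
  p <- index$ptr
  if (is.null(p) || isTRUE(tryCatch({cpp_seed_query(p, "", 1L); FALSE},
                                     error = function(e) TRUE))) {
    p <- cpp_seed_index(index$concat, index$k)
  }
  p
}

concat_to_chrom <- function(index, pos) {
  i <- findInterval(pos, index$offsets)
  list(chrom = index$chroms[i], pos = pos - index$offsets[i])
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

empty_segments <- function() {
  data.frame(read_id = character(), read_start = integer(), read_end = integer(),
             read_len = integer(), chrom = character(), ref_start = integer(),
             ref_end = integer(), strand = character(), score = numeric(),
             mismap = numeric(), cigar = character(), stringsAsFactors = FALSE)
}

#' Find candidate local alignments of one read
#'
#' Every locus attracting an exact seed of length `min_seed` (on either
#' strand) is extended by banded affine local alignment under the score
#' scheme; candidates scoring below `min_score` are discarded, duplicates
#' (same read and reference interval) removed.  Candidates may overlap each
#' other on the read; [split_read()] resolves the competition.
#'
#' @param read a character string (or `DNAString`) of length >= 1.
#' @param index a [genome_index()].
#' @param scheme a `score_scheme` ([log_odds_scores()]).
#' @param min_score minimum candidate score.
#' @param read_id id recorded in the output.
#' @param pad bases of context added around each seed cluster before
#'   extension; `band_pad` extra diagonal slack.
#' @return data.frame of candidate segments (0-based half-open read and
#'   reference intervals, forward-read coordinates); the `profile` column
#'   (list of per-read-position score increments) drives [split_read()].
#' @export
find_candidate_alignments <- function(read, index, scheme, min_score = 150,
                                      read_id = "read", pad = 350L,
                                      band_pad = 60L, max_candidates = 24L) {
  read <- toupper(as.character(read))
  if (nchar(read) < 1) stop("empty read")
  L <- nchar(read)
  ptr <- index_ptr(index)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else revcomp_chr(read)
    hits <- cpp_seed_query(ptr, q, index$max_per)
    if (length(hits$ref_pos) == 0) next
    cl <- cluster_hits(hits$ref_pos, hits$query_pos)
    for (ci in setdiff(unique(cl), 0L)) {
      sel <- cl == ci
      r <- hits$ref_pos[sel]; qq <- hits$query_pos[sel]
      loc <- concat_to_chrom(index, min(r))
      chrom <- loc$chrom
      off <- index$offsets[[chrom]]
      clen <- index$lengths[[chrom]]
      r0 <- max(0L, min(r) - off - pad); r1 <- min(clen, max(r) - off + index$k + pad)
      q0 <- max(0L, min(qq) - pad); q1 <- min(L, max(qq) + index$k + pad)
      dw <- (r - off - r0) - (qq - q0)
      aln <- cpp_band_align(
        substr(index$concat, off + r0 + 1L, off + r1), substr(q, q0 + 1L, q1),
        as.integer(t(scheme$subs)),
        scheme$del_open, scheme$del_ext, scheme$ins_open, scheme$ins_ext,
        min(dw) - band_pad, max(dw) + band_pad, 0L)
      if (!isTRUE(aln$ok) || aln$score < min_score) next
      qs <- q0 + aln$query_start; qe <- q0 + aln$query_end
      seg <- data.frame(
        read_id = read_id,
        read_start = if (strand == "+") qs else L - qe,
        read_end = if (strand == "+") qe else L - qs,
        read_len = L, chrom = chrom,
        ref_start = r0 + aln$ref_start, ref_end = r0 + aln$ref_end,
        strand = strand, score = aln$score, mismap = NA_real_,
        cigar = aln$cigar, stringsAsFactors = FALSE)
      prof <- aln$profile
      if (strand == "-") prof <- rev(prof)
      seg$profile <- list(prof)
      out[[length(out) + 1L]] <- seg
    }
  }
  if (length(out) == 0) { z <- empty_segments(); z$profile <- list(); return(z) }
  segs <- do.call(rbind, out)
  dup <- duplicated(segs[, c("read_start", "read_end", "chrom", "ref_start",
                             "ref_end", "strand")])
  segs <- segs[!dup, , drop = FALSE]
  if (nrow(segs) > max_candidates) {
    segs <- segs[order(-segs$score), , drop = FALSE][seq_len(max_candidates), ]
  }
  rownames(segs) <- NULL
  segs
}

# stripe seed hits by diagonal, then by query gaps; clusters with fewer
# than min_hits seeds (mostly chance k-mer matches) are dropped (cluster 0)
cluster_hits <- function(ref_pos, query_pos, max_diag_gap = 100L,
                         max_query_gap = 1500L, min_hits = 2L) {
  d <- ref_pos - query_pos
  o <- order(d, query_pos)
  stripe <- cumsum(c(1L, diff(d[o]) > max_diag_gap))
  cl <- integer(length(d))
  nxt <- 0L
  for (s in unique(stripe)) {
    idx <- o[stripe == s]
    idx <- idx[order(query_pos[idx])]
    sub <- cumsum(c(1L, diff(query_pos[idx]) > max_query_gap))
    cl[idx] <- nxt + sub
    nxt <- nxt + max(sub)
  }
  keep <- tabulate(cl)[cl] >= min_hits
  cl[!keep] <- 0L
  cl
}

#' Choose the most-likely division of a read among candidate alignments
#'
#' Dynamic program over read positions maximizing the sum of per-position
#' alignment scores of the chosen (possibly trimmed) candidates minus
#' `jump_penalty` per additional segment.  Chosen segments are trimmed so
#' read intervals are disjoint; all split points inside an overlap are
#' considered and each side pays its own per-base score loss.  Ties prefer
#' fewer segments, then the lexicographically smallest (chrom, ref_start)
#' candidate sequence.
#'
#' @param candidates data.frame from [find_candidate_alignments()] (one read).
#' @param jump_penalty score cost of introducing an additional segment.
#' @return data.frame of the chosen, trimmed segments ordered by
#'   `read_start` (a read alignment); zero rows if no division scores > 0.
#' @export
split_read <- function(candidates, jump_penalty = 30) {
  if (nrow(candidates) == 0) return(candidates)
  L <- candidates$read_len[1]
  stopifnot(all(candidates$read_len == L))
  ord <- order(candidates$chrom, candidates$ref_start, candidates$strand)
  cand <- candidates[ord, , drop = FALSE]
  res <- cpp_split_dp(L, cand$read_start, cand$read_end, cand$profile,
                      jump_penalty)
  if (length(res$cand) == 0) {
    z <- cand[0, , drop = FALSE]
    return(z)
  }
  segs <- vector("list", length(res$cand))
  for (i in seq_along(res$cand)) {
    seg <- cand[res$cand[i] + 1L, , drop = FALSE]
    segs[[i]] <- trim_segment(seg, res$seg_start[i], res$seg_end[i] )
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$read_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1]]
  list(op = ops, len = lens)
}

unparse_cigar <- function(op, len) {
  keep <- len > 0
  op <- op[keep]; len <- len[keep]
  if (length(op) > 1) { # merge equal neighbours
    grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
    len <- as.integer(tapply(len, grp, sum))
    op <- op[!duplicated(grp)]
  }
  paste0(len, op, collapse = "")
}

# Restrict a candidate segment to forward-read interval [a, b).
trim_segment <- function(seg, a, b) {
  stopifnot(nrow(seg) == 1, a >= seg$read_start, b <= seg$read_end, a < b)
  if (a == seg$read_start && b == seg$read_end) return(seg)
  L <- seg$read_len
  # query-orientation interval (query = read or its reverse complement)
  if (seg$strand == "+") { qa <- a - seg$read_start; qb <- b - seg$read_start
  } else { qa <- (L - b) - (L - seg$read_end); qb <- (L - a) - (L - seg$read_end) }
  cg <- parse_cigar(seg$cigar)
  qc <- ifelse(cg$op == "D", 0L, cg$len)            # query consumed per run
  rc <- ifelse(cg$op == "I", 0L, cg$len)            # ref consumed per run
  qb0 <- cumsum(qc) - qc                            # query pos before run
  rb0 <- cumsum(rc) - rc                            # ref pos before run
  lo <- pmax(qb0, qa); hi <- pmin(qb0 + qc, qb)
  keepq <- which(qc > 0L & hi > lo)
  stopifnot(length(keepq) > 0)
  i1 <- keepq[1]; i2 <- keepq[length(keepq)]
  sel <- i1:i2                                      # D runs in between stay
  ops_out <- cg$op[sel]
  len_out <- ifelse(qc[sel] > 0L, hi[sel] - lo[sel], cg$len[sel])
  r_lo <- rb0[i1] + if (rc[i1] > 0L) lo[i1] - qb0[i1] else 0L
  r_hi <- rb0[i2] + if (rc[i2] > 0L) hi[i2] - qb0[i2] else 0L
  prof <- seg$profile[[1]]
  new_prof <- prof[(a - seg$read_start + 1L):(b - seg$read_start)]
  seg$read_start <- a; seg$read_end <- b
  seg$ref_start <- seg$ref_start + r_lo
  seg$ref_end <- seg$ref_start + (r_hi - r_lo)
  seg$cigar <- unparse_cigar(ops_out, len_out)
  seg$score <- sum(new_prof)
  seg$profile <- list(new_prof)
  seg
}

#' Mismap probability of a chosen alignment segment
#'
#' The probability that the segment is aligned to the wrong locus: one
#' minus the softmax weight `exp(score / temperature)` of the chosen
#' candidate among all candidates whose read interval overlaps at least
#' half of the chosen segment's read interval.  It is near 0 for a unique
#' alignment and approaches `1 - 1/n` for `n` equally good loci.
#'
#' @param candidates all candidates for the read ([find_candidate_alignments()]).
#' @param chosen single-row data.frame, the chosen segment.
#' @param temperature softmax temperature in score units; the natural value
#'   for a log-odds scheme is `1 / (scale * ln 2)` (see [log_odds_scores()]).
#' @return probability in `[0, 1]`.
#' @export
estimate_mismap <- function(candidates, chosen, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  stopifnot(nrow(chosen) == 1)
  span <- chosen$read_end - chosen$read_start
  ov <- pmin(candidates$read_end, chosen$read_end) -
    pmax(candidates$read_start, chosen$read_start)
  sel <- which(ov >= span / 2)
  if (length(sel) <= 1) return(0)
  # identify the chosen segment's source candidate (it may have been trimmed)
  same <- candidates$chrom[sel] == chosen$chrom &
    candidates$strand[sel] == chosen$strand &
    candidates$ref_start[sel] <= chosen$ref_start + span / 2 &
    candidates$ref_end[sel] >= chosen$ref_end - span / 2
  self <- if (any(same)) sel[same][which.max(candidates$score[sel][same])]
          else sel[which.max(ov[sel])]
  sc <- candidates$score[sel]
  w <- exp((sc - max(sc)) / temperature)
  unname(1 - w[match(self, sel)] / sum(w))
}

#' Align one read: candidates, division, mismap
#'
#' @inheritParams find_candidate_alignments
#' @inheritParams split_read
#' @param mismap_temperature see [estimate_mismap()]; default derived from
#'   the score scheme scale.
#' @return read alignment data.frame with `mismap` filled in.
#' @export
align_read <- function(read, index, scheme, read_id = "read",
                       min_score = 150, jump_penalty = 30,
                       mismap_temperature = NULL) {
  if (is.null(mismap_temperature)) mismap_temperature <- 1 / (scheme$scale * log(2))
  cand <- find_candidate_alignments(read, index, scheme, min_score = min_score,
                                    read_id = read_id)
  aln <- split_read(cand, jump_penalty)
  if (nrow(aln) == 0) return(aln)
  for (i in seq_len(nrow(aln))) {
    aln$mismap[i] <- estimate_mismap(cand, aln[i, , drop = FALSE],
                                     mismap_temperature)
  }
  aln
}

#' Split-align a set of reads to a genome
#'
#' @param reads named [Biostrings::DNAStringSet] or named character vector.
#' @param genome named [Biostrings::DNAStringSet], or a prebuilt
#'   [genome_index()].
#' @param scheme score scheme; default: nanopore-like model.
#' @param ... passed to [align_read()].
#' @return one data.frame of aligned segments for all reads (the `profile`
#'   column is dropped).
#' @export
align_reads <- function(reads, genome, scheme = NULL, ...) {
  if (is.null(scheme)) scheme <- log_odds_scores(nanopore_error_model())
  index <- if (inherits(genome, "genome_index")) genome else genome_index(genome)
  reads_chr <- toupper(as.character(reads))
  ids <- names(reads_chr)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads_chr))
  out <- vector("list", length(reads_chr))
  for (i in seq_along(reads_chr)) {
    out[[i]] <- align_read(reads_chr[[i]], index, scheme, read_id = ids[i], ...)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_segments()
  res$profile <- NULL
  rownames(res) <- NULL
  res
}

#' Convert aligned segments to MAF blocks
#'
#' Reconstructs gapped alignment text from the stored edit paths; the read
#' row follows the MAF strand convention (for `-` segments, coordinates
#' count from the start of the reverse-complemented read) and the `p` line
#' encodes the segment mismap probability per column.
#'
#' @param segments segment data.frame.
#' @param genome named DNAStringSet (reference).
#' @param reads named DNAStringSet of reads.
#' @export
segments_to_maf <- function(segments, genome, reads) {
  genome <- toupper(as.character(genome))
  reads <- toupper(as.character(reads))
  blocks <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    rseq <- reads[[s$read_id]]
    q <- if (s$strand == "+") rseq else revcomp_chr(rseq)
    qa <- if (s$strand == "+") s$read_start else s$read_len - s$read_end
    g <- substr(genome[[s$chrom]], s$ref_start + 1L, s$ref_end)
    qs <- substr(q, qa + 1L, qa + (s$read_end - s$read_start))
    cg <- parse_cigar(s$cigar)
    gt <- character(0); qt <- character(0)
    gp <- 1L; qp <- 1L
    for (j in seq_along(cg$op)) {
      len <- cg$len[j]
      switch(cg$op[j],
        "=" = , "X" = {
          gt <- c(gt, substr(g, gp, gp + len - 1L))
          qt <- c(qt, substr(qs, qp, qp + len - 1L))
          gp <- gp + len; qp <- qp + len
        },
        "D" = {
          gt <- c(gt, substr(g, gp, gp + len - 1L))
          qt <- c(qt, strrep("-", len)); gp <- gp + len
        },
        "I" = {
          gt <- c(gt, strrep("-", len))
          qt <- c(qt, substr(qs, qp, qp + len - 1L)); qp <- qp + len
        })
    }
    gtext <- paste(gt, collapse = ""); qtext <- paste(qt, collapse = "")
    probs <- if (is.na(s$mismap)) NA_character_ else
      encode_prob_symbols(rep(max(s$mismap, 1e-9), nchar(qtext)))
    blocks[[i]] <- list(
      score = s$score,
      rows = data.frame(
        seq_name = c(s$chrom, s$read_id),
        start = c(s$ref_start, qa),
        aln_size = c(s$ref_end - s$ref_start, s$read_end - s$read_start),
        strand = c("+", s$strand),
        src_size = c(nchar(genome[[s$chrom]]), s$read_len),
        text = c(gtext, qtext), stringsAsFactors = FALSE),
      probs = probs)
  }
  blocks
}

#' Convert MAF blocks to a segment table
#'
#' The inverse view of [segments_to_maf()] for externally produced
#' alignments: genome row first, read row second.  Mismap is taken as the
#' maximum decoded `p`-line probability (1 if symbols are unknown, 0 if no
#' `p` line).
#'
#' @param blocks list of MAF blocks.
#' @export
maf_to_segments <- function(blocks) {
  rows <- lapply(blocks, function(b) {
    g <- b$rows[1, ]; r <- b$rows[2, ]
    gt <- strsplit(b$rows$text[1], "")[[1]]
    rt <- strsplit(b$rows$text[2], "")[[1]]
    op <- ifelse(gt == "-", "I", ifelse(rt == "-", "D", ifelse(gt == rt, "=", "X")))
    rl <- rle(op)
    rs <- if (r$strand == "+") r$start else r$src_size - (r$start + r$aln_size)
    mm <- if (is.na(b$probs)) 0 else max(decode_prob_symbols(b$probs))
    data.frame(read_id = r$seq_name, read_start = rs, read_end = rs + r$aln_size,
               read_len = r$src_size, chrom = g$seq_name,
               ref_start = g$start, ref_end = g$start + g$aln_size,
               strand = r$strand, score = b$score, mismap = mm,
               cigar = unparse_cigar(rl$values, rl$lengths),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_segments()
  out
}
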