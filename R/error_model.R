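BASES <- c("A", "C", "G", "T")

#' Tally substitution and gap events from alignments
#'
#' Scans MAF blocks column by column and counts, per genome base, how often
#' each read base was observed, plus affine gap events: a run of gap columns
#' counts one open and `len - 1` extends on the appropriate side (gap in the
#' read row = deletion, gap in the genome row = insertion).  Columns in which
#' either base is not A/C/G/T are excluded from the substitution tally and
#' from the `aligned_columns` denominator: an N is absence of information,
#' not an event.
#'
#' @param blocks list of MAF blocks ([read_maf()]); genome row first.
#' @return an `event_counts` object: list with `subs` (4x4 genome x read
#'   count matrix), `gap_open_del`, `gap_extend_del`, `gap_open_ins`,
#'   `gap_extend_ins`, `aligned_columns`.
#' @export
count_alignment_events <- function(blocks) {
  subs <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  god <- ged <- goi <- gei <- cols <- 0
  for (b in blocks) {
    g <- strsplit(toupper(b$rows$text[1]), "")[[1]]
    r <- strsplit(toupper(b$rows$text[2]), "")[[1]]
    gi <- match(g, BASES)   # NA for gap or ambiguity code
    ri <- match(r, BASES)
    is_del <- r == "-"
    is_ins <- g == "-"
    both <- !is.na(gi) & !is.na(ri)
    if (any(both)) {
      subs <- subs + table(factor(gi[both], 1:4), factor(ri[both], 1:4))
      cols <- cols + sum(both)
    }
    runs <- function(mask) {
      if (!any(mask)) return(c(0, 0))
      rl <- rle(mask)
      n_open <- sum(rl$values)
      c(n_open, sum(rl$lengths[rl$values]) - n_open)
    }
    d <- runs(is_del); god <- god + d[1]; ged <- ged + d[2]
    i <- runs(is_ins); goi <- goi + i[1]; gei <- gei + i[2]
  }
  structure(list(subs = unclass(subs), gap_open_del = god, gap_extend_del = ged,
                 gap_open_ins = goi, gap_extend_ins = gei,
                 aligned_columns = cols),
            class = "event_counts")
}

new_error_model <- function(p_sub, p_del_open, p_del_extend,
                            p_ins_open, p_ins_extend, background) {
  stopifnot(all(dim(p_sub) == c(4, 4)),
            all(abs(rowSums(p_sub) - 1) < 1e-9),
            abs(sum(background) - 1) < 1e-9, all(background > 0))
  dimnames(p_sub) <- list(BASES, BASES)
  structure(list(p_sub = p_sub,
                 p_del_open = p_del_open, p_del_extend = p_del_extend,
                 p_ins_open = p_ins_open, p_ins_extend = p_ins_extend,
                 background = stats::setNames(as.numeric(background), BASES)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Read-vs-genome error model\n  substitution matrix (genome rows, read columns):\n")
  print(round(x$p_sub, 4))
  cat(sprintf("  deletion:  open %.4g, extend %.4g\n", x$p_del_open, x$p_del_extend))
  cat(sprintf("  insertion: open %.4g, extend %.4g\n", x$p_ins_open, x$p_ins_extend))
  invisible(x)
}

#' Estimate substitution and gap probabilities from event counts
#'
#' Normalizes [count_alignment_events()] tallies into probabilities with an
#' additive pseudocount (default 0.5, Jeffreys-style): each row of the
#' substitution matrix is normalized to 1; gap-open probabilities use the
#' aligned-column denominator and gap-extend probabilities the gap-column
#' denominator; the background read-base distribution is the column sum of
#' the substitution matrix weighted by genome-base frequencies.
#'
#' @param counts an `event_counts` object.
#' @param pseudocount non-negative smoothing count added to every cell.
#' @return an `error_model` object.
#' @export
estimate_error_model <- function(counts, pseudocount = 0.5) {
  stopifnot(pseudocount >= 0)
  if (counts$aligned_columns == 0 && pseudocount == 0) {
    stop("cannot estimate an error model from zero aligned columns with pseudocount 0")
  }
  s <- counts$subs + pseudocount
  p_sub <- s / rowSums(s)
  gp <- function(open, denom) {
    if (denom + 2 * pseudocount == 0) return(0)
    (open + pseudocount) / (denom + 2 * pseudocount)
  }
  p_del_open <- gp(counts$gap_open_del, counts$aligned_columns)
  p_ins_open <- gp(counts$gap_open_ins, counts$aligned_columns)
  p_del_extend <- gp(counts$gap_extend_del, counts$gap_open_del + counts$gap_extend_del)
  p_ins_extend <- gp(counts$gap_extend_ins, counts$gap_open_ins + counts$gap_extend_ins)
  w <- rowSums(s) / sum(s)
  background <- as.numeric(w %*% p_sub)
  background <- background / sum(background)
  new_error_model(p_sub, p_del_open, p_del_extend, p_ins_open, p_ins_extend,
                  background)
}

#' Convert an error model to integer log-odds alignment scores
#'
#' `score(a, b) = round(log2(p_sub[a, b] / background[b]) / scale)` with
#' `scale` in bits per score unit; affine gap penalties come from the
#' matching log-odds of opening/extending versus staying aligned.  The
#' scheme is validated to give negative expected score on random sequence
#' (a requirement for local alignment to be meaningful).
#'
#' @param model an `error_model`.
#' @param scale bits per score unit; the default picks a scale giving a
#'   maximum substitution score of about +6.
#' @return a `score_scheme` object: integer `subs` matrix (genome rows,
#'   read columns), penalties `del_open`, `del_ext`, `ins_open`, `ins_ext`
#'   (all `>= 0`), and `scale`.
#' @export
log_odds_scores <- function(model, scale = NULL) {
  lo <- log2(sweep(model$p_sub, 2, model$background, "/"))
  if (!all(is.finite(lo))) {
    stop("error model contains a zero probability; re-estimate with a pseudocount > 0")
  }
  if (is.null(scale)) scale <- if (max(lo) > 0) max(lo) / 6 else 1
  stopifnot(scale > 0)
  subs <- round(lo / scale)
  gap_pen <- function(p) max(0L, -as.integer(round(log2(p / (1 - p)) / scale)))
  scheme <- structure(list(
    subs = matrix(as.integer(subs), 4, 4, dimnames = dimnames(model$p_sub)),
    del_open = gap_pen(model$p_del_open), del_ext = gap_pen(model$p_del_extend),
    ins_open = gap_pen(model$p_ins_open), ins_ext = gap_pen(model$p_ins_extend),
    scale = scale), class = "score_scheme")
  p_genome <- rowSums(model$p_sub * model$background) # ~genome composition proxy
  p_genome <- p_genome / sum(p_genome)
  e <- sum(outer(p_genome, model$background) * scheme$subs)
  if (e > 0) stop("expected score of random alignment is positive; ",
                  "increase scale or refit the model")
  if (e == 0) warning("expected score of random alignment is zero; ",
                      "local alignment under this scheme is not meaningful")
  scheme
}

#' @export
print.score_scheme <- function(x, ...) {
  cat("Log-odds score scheme (", format(x$scale, digits = 3), " bits/unit)\n", sep = "")
  print(x$subs)
  cat(sprintf("  gap penalties: del %d/%d, ins %d/%d (open/extend)\n",
              x$del_open, x$del_ext, x$ins_open, x$ins_ext))
  invisible(x)
}

#' Train an error model directly from MAF alignments
#'
#' Convenience composition of [count_alignment_events()] and
#' [estimate_error_model()], optionally iterated: with `rounds > 1` the
#' reads are re-aligned under the refreshed scores between rounds (requires
#' `genome` and `reads`).
#'
#' @param blocks MAF blocks.
#' @param pseudocount smoothing count.
#' @param rounds training rounds; 1 means count-and-normalize only.
#' @param genome,reads needed only when `rounds > 1`.
#' @export
train_error_model <- function(blocks, pseudocount = 0.5, rounds = 1,
                              genome = NULL, reads = NULL) {
  model <- estimate_error_model(count_alignment_events(blocks), pseudocount)
  if (rounds > 1) {
    stopifnot(!is.null(genome), !is.null(reads))
    for (i in seq_len(rounds - 1)) {
      scheme <- log_odds_scores(model)
      aln <- align_reads(reads, genome, scheme)
      blocks <- segments_to_maf(aln, genome, reads)
      model <- estimate_error_model(count_alignment_events(blocks), pseudocount)
    }
  }
  model
}

#' Default nanopore-like error model
#'
#' A fixed model with uniform substitution error and asymmetric affine
#' indels (deletions more frequent than insertions), totalling roughly 10%
#' error: per-base substitution probability `sub`, deletion/insertion open
#' probabilities `del`/`ins`, shared extension probability `ext` (geometric
#' gap lengths with mean `1/(1-ext)`).
#'
#' @param sub total substitution probability per aligned base.
#' @param del,ins gap-open probabilities per aligned base.
#' @param ext gap-extension probability.
#' @export
nanopore_error_model <- function(sub = 0.05, del = 0.02, ins = 0.012, ext = 0.25) {
  p_sub <- matrix(sub / 3, 4, 4); diag(p_sub) <- 1 - sub
  new_error_model(p_sub, del, ext, ins, ext, rep(0.25, 4))
}

#' Exact / error-free model (for simulations at zero error)
#' @export
exact_error_model <- function() nanopore_error_model(0, 0, 0, 0)
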