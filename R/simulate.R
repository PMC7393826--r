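## Synthetic references, rearrangement operators, noisy long reads, control
## cohorts, and ground-truth records for every oracle in the test suite.

#' Simulate a reference genome
#'
#' I.i.d. bases at a given GC content, deterministic per seed.  Optional
#' planted repeat pairs (exact copies) create the near-tied alignments that
#' exercise mismap estimation.
#'
#' @param chrom_lengths named integer vector.
#' @param gc GC content in `[0, 1]`.
#' @param seed integer seed.
#' @param repeat_pairs optional data.frame with columns `chrom`, `start`,
#'   `length`, `dest_chrom`, `dest_start`: the source interval is copied
#'   over the destination.
#' @return named [Biostrings::DNAStringSet].
#' @export
make_reference <- function(chrom_lengths, gc = 0.41, seed = 1,
                           repeat_pairs = NULL) {
  stopifnot(all(chrom_lengths >= 1), !is.null(names(chrom_lengths)))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(chrom_lengths, function(n) {
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }, "")
  if (!is.null(repeat_pairs)) {
    for (i in seq_len(nrow(repeat_pairs))) {
      r <- repeat_pairs[i, ]
      piece <- substr(seqs[[r$chrom]], r$start + 1L, r$start + r$length)
      s <- seqs[[r$dest_chrom]]
      seqs[[r$dest_chrom]] <- paste0(
        substr(s, 1L, r$dest_start),
        piece,
        substr(s, r$dest_start + r$length + 1L, nchar(s)))
    }
  }
  Biostrings::DNAStringSet(seqs)
}

## ---------------------------------------------------------------------------
## Rearrangement operators

op <- function(kind, ...) structure(list(kind = kind, ...), class = "rearrangement_op")

#' Rearrangement operators for the simulator
#'
#' Constructors for the operations [apply_rearrangements()] understands.
#' All coordinates are reference, 0-based half-open, and operated regions
#' must still be intact (unrearranged) when the operation applies.
#'
#' @param chrom,start,end target interval.
#' @name rearrangement-ops
NULL

#' @rdname rearrangement-ops
#' @export
op_deletion <- function(chrom, start, end) op("deletion", chrom = chrom, start = start, end = end)

#' @rdname rearrangement-ops
#' @export
op_inversion <- function(chrom, start, end) op("inversion", chrom = chrom, start = start, end = end)

#' @rdname rearrangement-ops
#' @param copies total copy count after multiplication (2 = duplication).
#' @export
op_tandem_multiplication <- function(chrom, start, end, copies = 2L)
  op("tandem_multiplication", chrom = chrom, start = start, end = end,
     copies = as.integer(copies))

#' @rdname rearrangement-ops
#' @param src_chrom,src_start,src_end,src_orient source interval copied.
#' @param target_chrom,target_pos insertion point.
#' @param tsd_len target-site deletion length (bases removed at the target).
#' @export
op_insertion_copy <- function(src_chrom, src_start, src_end, src_orient = "+",
                              target_chrom, target_pos, tsd_len = 0L)
  op("insertion_copy", src_chrom = src_chrom, src_start = src_start,
     src_end = src_end, src_orient = src_orient, target_chrom = target_chrom,
     target_pos = target_pos, tsd_len = as.integer(tsd_len))

#' @rdname rearrangement-ops
#' @param chrom_a,pos_a,chrom_b,pos_b the two exchange breakpoints.
#' @export
op_reciprocal_translocation <- function(chrom_a, pos_a, chrom_b, pos_b)
  op("reciprocal_translocation", chrom_a = chrom_a, pos_a = pos_a,
     chrom_b = chrom_b, pos_b = pos_b)

#' @rdname rearrangement-ops
#' @param n_fragments number of fragments the interval shatters into.
#' @param dropped indices (1-based) of fragments lost.
#' @param permutation permutation of the kept fragments (in new order);
#'   `NULL` draws one at random.
#' @param orientations `+`/`-` per kept fragment in new order; `NULL` draws
#'   at random.
#' @export
op_chromothripsis <- function(chrom, start, end, n_fragments,
                              dropped = integer(0), permutation = NULL,
                              orientations = NULL)
  op("chromothripsis", chrom = chrom, start = start, end = end,
     n_fragments = as.integer(n_fragments), dropped = as.integer(dropped),
     permutation = permutation, orientations = orientations)

## structure bookkeeping -----------------------------------------------------

identity_structures <- function(genome) {
  lens <- Biostrings::width(genome)
  stats::setNames(lapply(seq_along(genome), function(i) {
    data.frame(chrom = names(genome)[i], start = 0L, end = lens[i],
               orient = "+", stringsAsFactors = FALSE)
  }), names(genome))
}

# split, inside derivative `d`, any "+" segment containing reference
# position (chrom, pos) so that pos becomes a boundary
split_at <- function(structures, chrom, pos) {
  for (d in names(structures)) {
    s <- structures[[d]]
    hit <- which(s$chrom == chrom & s$orient == "+" & s$start < pos & s$end > pos)
    for (i in hit) {
      top <- if (i > 1) s[1:(i - 1), , drop = FALSE] else s[0, ]
      bot <- if (i < nrow(s)) s[(i + 1):nrow(s), , drop = FALSE] else s[0, ]
      s <- rbind(top,
                 data.frame(chrom = chrom, start = s$start[i], end = pos,
                            orient = "+", stringsAsFactors = FALSE),
                 data.frame(chrom = chrom, start = pos, end = s$end[i],
                            orient = "+", stringsAsFactors = FALSE),
                 bot)
      structures[[d]] <- s
    }
  }
  structures
}

# locate the intact run of segments exactly covering [start, end) of chrom
locate_run <- function(structures, chrom, start, end, what) {
  for (d in names(structures)) {
    s <- structures[[d]]
    i0 <- which(s$chrom == chrom & s$orient == "+" & s$start == start)
    if (length(i0) == 1) {
      i1 <- i0
      while (i1 <= nrow(s) && s$end[i1] < end) {
        if (i1 == nrow(s) || s$chrom[i1 + 1] != chrom || s$orient[i1 + 1] != "+" ||
            s$start[i1 + 1] != s$end[i1]) {
          stop(sprintf("%s: region %s:%d-%d is not intact", what, chrom, start, end))
        }
        i1 <- i1 + 1L
      }
      if (i1 > nrow(s) || s$end[i1] > end) next
      if (s$end[i1] == end) return(list(deriv = d, from = i0, to = i1))
    }
  }
  stop(sprintf("%s: region %s:%d-%d not found intact in any derivative",
               what, chrom, start, end))
}

replace_run <- function(structures, loc, replacement) {
  s <- structures[[loc$deriv]]
  top <- if (loc$from > 1) s[1:(loc$from - 1), , drop = FALSE] else s[0, ]
  bot <- if (loc$to < nrow(s)) s[(loc$to + 1):nrow(s), , drop = FALSE] else s[0, ]
  structures[[loc$deriv]] <- rbind(top, replacement, bot)
  structures
}

seg_row <- function(chrom, start, end, orient = "+") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             orient = orient, stringsAsFactors = FALSE)
}

#' Apply rearrangement operations to a genome
#'
#' Operations are applied in order to derivative-structure tables (ordered,
#' oriented reference segments per derived chromosome); each operation must
#' target a still-intact reference region and is validated against the
#' genome bounds.  The derived sequences are materialized from the final
#' structures, so the reconstruction invariant (structures regenerate the
#' derived genome) holds by construction and is cross-checked in tests by
#' independent string surgery.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param ops list of operators (see [rearrangement-ops]).
#' @param seed seed used for any randomized operator parameters.
#' @return list with `derived` (DNAStringSet), `truth` (list: `ops`,
#'   `structures`, `junctions`, `chrom_lengths`).
#' @export
apply_rearrangements <- function(genome, ops, seed = 1) {
  set.seed(seed)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  check <- function(chrom, ...) {
    pos <- c(...)
    if (!chrom %in% names(lens)) stop("unknown chromosome in op: ", chrom)
    if (any(pos < 0 | pos > lens[[chrom]])) {
      stop(sprintf("op out of bounds on %s: %s", chrom,
                   paste(pos, collapse = ",")))
    }
  }
  st <- identity_structures(genome)
  for (o in ops) {
    st <- switch(o$kind,
      deletion = {
        check(o$chrom, o$start, o$end)
        st <- split_at(split_at(st, o$chrom, o$start), o$chrom, o$end)
        loc <- locate_run(st, o$chrom, o$start, o$end, "deletion")
        replace_run(st, loc, seg_row(o$chrom, 0, 0)[0, ])
      },
      inversion = {
        check(o$chrom, o$start, o$end)
        st <- split_at(split_at(st, o$chrom, o$start), o$chrom, o$end)
        loc <- locate_run(st, o$chrom, o$start, o$end, "inversion")
        replace_run(st, loc, seg_row(o$chrom, o$start, o$end, "-"))
      },
      tandem_multiplication = {
        check(o$chrom, o$start, o$end)
        st <- split_at(split_at(st, o$chrom, o$start), o$chrom, o$end)
        loc <- locate_run(st, o$chrom, o$start, o$end, "tandem_multiplication")
        rep_block <- do.call(rbind, replicate(o$copies,
          seg_row(o$chrom, o$start, o$end), simplify = FALSE))
        replace_run(st, loc, rep_block)
      },
      insertion_copy = {
        check(o$src_chrom, o$src_start, o$src_end)
        check(o$target_chrom, o$target_pos, o$target_pos + o$tsd_len)
        st <- split_at(split_at(st, o$target_chrom, o$target_pos),
                       o$target_chrom, o$target_pos + o$tsd_len)
        ins <- seg_row(o$src_chrom, o$src_start, o$src_end, o$src_orient)
        if (o$tsd_len > 0) {
          loc <- locate_run(st, o$target_chrom, o$target_pos,
                            o$target_pos + o$tsd_len, "insertion_copy")
          replace_run(st, loc, ins)
        } else {
          # zero-length target: insert at the split boundary
          found <- FALSE
          for (d in names(st)) {
            s <- st[[d]]
            i <- which(s$chrom == o$target_chrom & s$orient == "+" &
                         s$start == o$target_pos)
            if (length(i) == 0 && o$target_pos == lens[[o$target_chrom]]) {
              i <- which(s$chrom == o$target_chrom & s$orient == "+" &
                           s$end == o$target_pos) + 1L
            }
            if (length(i) >= 1) {
              i <- i[1]
              top <- if (i > 1) s[1:(i - 1), , drop = FALSE] else s[0, ]
              bot <- if (i <= nrow(s)) s[i:nrow(s), , drop = FALSE] else s[0, ]
              st[[d]] <- rbind(top, ins, bot)
              found <- TRUE
              break
            }
          }
          if (!found) stop("insertion_copy: target position not intact")
          st
        }
      },
      reciprocal_translocation = {
        check(o$chrom_a, o$pos_a); check(o$chrom_b, o$pos_b)
        st <- split_at(split_at(st, o$chrom_a, o$pos_a), o$chrom_b, o$pos_b)
        la <- locate_run(st, o$chrom_a, o$pos_a, lens[[o$chrom_a]],
                         "reciprocal_translocation")
        lb <- locate_run(st, o$chrom_b, o$pos_b, lens[[o$chrom_b]],
                         "reciprocal_translocation")
        if (la$deriv == lb$deriv) stop("translocation breakpoints on one derivative")
        sa <- st[[la$deriv]]; sb <- st[[lb$deriv]]
        st[[la$deriv]] <- rbind(sa[seq_len(la$from - 1), , drop = FALSE],
                                sb[lb$from:nrow(sb), , drop = FALSE])
        st[[lb$deriv]] <- rbind(sb[seq_len(lb$from - 1), , drop = FALSE],
                                sa[la$from:nrow(sa), , drop = FALSE])
        st
      },
      chromothripsis = {
        check(o$chrom, o$start, o$end)
        n <- o$n_fragments
        stopifnot(n >= 2)
        bounds <- round(seq(o$start, o$end, length.out = n + 1L))
        kept <- setdiff(seq_len(n), o$dropped)
        perm <- o$permutation
        if (is.null(perm)) perm <- sample(seq_along(kept))
        ori <- o$orientations
        if (is.null(ori)) ori <- sample(c("+", "-"), length(kept), replace = TRUE)
        stopifnot(length(perm) == length(kept), length(ori) == length(kept))
        for (p in bounds[2:n]) st <- split_at(st, o$chrom, p)
        st <- split_at(split_at(st, o$chrom, o$start), o$chrom, o$end)
        loc <- locate_run(st, o$chrom, o$start, o$end, "chromothripsis")
        frag <- kept[perm]
        repl <- do.call(rbind, lapply(seq_along(frag), function(i) {
          f <- frag[i]
          seg_row(o$chrom, bounds[f], bounds[f + 1L], ori[i])
        }))
        replace_run(st, loc, repl)
      },
      stop("unknown op kind: ", o$kind))
  }
  derived <- derive_sequences(genome, st)
  truth <- list(ops = ops, structures = st,
                junctions = truth_junctions(st, min_gap = 1L),
                chrom_lengths = lens)
  list(derived = derived, truth = truth)
}

#' Materialize derived sequences from derivative structures
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param structures named list of segment data.frames
#'   (`chrom,start,end,orient`).
#' @export
derive_sequences <- function(genome, structures) {
  seqs <- toupper(as.character(genome))
  out <- vapply(structures, function(s) {
    if (nrow(s) == 0) return("")
    pieces <- vapply(seq_len(nrow(s)), function(i) {
      p <- substr(seqs[[s$chrom[i]]], s$start[i] + 1L, s$end[i])
      if (s$orient[i] == "-") revcomp_chr(p) else p
    }, "")
    paste(pieces, collapse = "")
  }, "")
  Biostrings::DNAStringSet(out[nchar(out) > 0])
}

#' True junctions implied by derivative structures
#'
#' Every non-colinear adjacency between consecutive segments of each
#' derivative, expressed as canonical breakend pairs.  `min_gap` filters
#' colinear forward gaps the same way [extract_junctions()] does, so truth
#' can be restricted to what the pipeline is asked to find.
#'
#' @param structures named list of segment data.frames, or a single one.
#' @param min_gap forward-gap threshold (1 reports every non-abutting
#'   adjacency).
#' @export
truth_junctions <- function(structures, min_gap = 1L) {
  if (is.data.frame(structures)) structures <- list(der = structures)
  rows <- lapply(names(structures), function(d) {
    s <- structures[[d]]
    if (nrow(s) < 2) return(NULL)
    lens <- s$end - s$start
    aln <- data.frame(read_id = d, read_start = cumsum(lens) - lens,
                      read_end = cumsum(lens), read_len = sum(lens),
                      chrom = s$chrom, ref_start = s$start, ref_end = s$end,
                      strand = s$orient, score = 0, mismap = 0, cigar = "",
                      stringsAsFactors = FALSE)
    extract_junctions(aln, min_gap = min_gap, max_mismap = 1)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_junctions()
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Reads

#' Simulate noisy long reads
#'
#' Read starts uniform over the (derived) genome, lengths from a truncated
#' log-normal, both strands equiprobable, errors drawn from the error model
#' (substitutions plus affine-geometric indels).  Deterministic per seed.
#'
#' @param genome named [Biostrings::DNAStringSet] to read from.
#' @param coverage mean fold-coverage.
#' @param length_law list with `mean`, `sd` (of log-lengths), `min`.
#' @param model an `error_model`.
#' @param seed integer.
#' @param prefix read-id prefix.
#' @return list: `reads` (DNAStringSet), `truth` (data.frame: read_id,
#'   chrom, start, end, strand — source intervals on the given genome).
#' @export
simulate_reads <- function(genome, coverage = 20,
                           length_law = list(mean = 12000, sd = 0.35, min = 1000),
                           model = nanopore_error_model(), seed = 1,
                           prefix = "r") {
  stopifnot(coverage > 0)
  set.seed(seed)
  seqs <- toupper(as.character(genome))
  lens <- nchar(seqs)
  total <- sum(as.numeric(lens))
  n <- ceiling(coverage * total / length_law$mean)
  chrom_i <- sample.int(length(seqs), n, replace = TRUE, prob = lens / total)
  meanlog <- log(length_law$mean) - length_law$sd^2 / 2
  rl <- pmax(length_law$min,
             round(stats::rlnorm(n, meanlog = meanlog, sdlog = length_law$sd)))
  start <- floor(stats::runif(n) * pmax(1, lens[chrom_i] - 1))
  end <- pmin(start + rl, lens[chrom_i])
  keep <- end - start >= length_law$min
  chrom_i <- chrom_i[keep]; start <- start[keep]; end <- end[keep]
  strand <- sample(c("+", "-"), sum(keep), replace = TRUE)
  ids <- sprintf("%s%05d", prefix, seq_along(start))
  reads <- character(length(ids))
  for (i in seq_along(ids)) {
    x <- substr(seqs[[chrom_i[i]]], start[i] + 1L, end[i])
    if (strand[i] == "-") x <- revcomp_chr(x)
    reads[i] <- mutate_sequence(x, model)
  }
  truth <- data.frame(read_id = ids, chrom = names(seqs)[chrom_i],
                      start = start, end = end, strand = strand,
                      stringsAsFactors = FALSE)
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- ids
  list(reads = out, truth = truth)
}

# apply model errors to one sequence (uses the current RNG stream)
mutate_sequence <- function(x, model) {
  n <- nchar(x)
  if (n == 0) return(x)
  b <- strsplit(x, "")[[1]]
  bi <- match(b, BASES)
  bi[is.na(bi)] <- sample.int(4L, sum(is.na(bi)), replace = TRUE)
  # substitutions
  p_err <- 1 - diag(model$p_sub)
  hit <- stats::runif(n) < p_err[bi]
  if (any(hit)) {
    for (a in 1:4) {
      ia <- which(hit & bi == a)
      if (length(ia)) {
        pr <- model$p_sub[a, ]; pr[a] <- 0
        b[ia] <- sample(BASES, length(ia), replace = TRUE, prob = pr)
      }
    }
  }
  # deletions: geometric runs starting at open positions
  keep <- rep(TRUE, n)
  if (model$p_del_open > 0) {
    opens <- which(stats::runif(n) < model$p_del_open)
    if (length(opens)) {
      dl <- 1L + stats::rgeom(length(opens), 1 - model$p_del_extend)
      for (j in seq_along(opens)) {
        keep[opens[j]:min(n, opens[j] + dl[j] - 1L)] <- FALSE
      }
    }
  }
  # insertions: random bases before a position
  ins <- character(n + 1L)
  if (model$p_ins_open > 0) {
    opens <- which(stats::runif(n + 1L) < model$p_ins_open)
    if (length(opens)) {
      il <- 1L + stats::rgeom(length(opens), 1 - model$p_ins_extend)
      for (j in seq_along(opens)) {
        ins[opens[j]] <- paste(sample(BASES, il[j], replace = TRUE), collapse = "")
      }
    }
  }
  body <- paste0(ins[1:n], ifelse(keep, b, ""))
  paste0(paste(body, collapse = ""), ins[n + 1L])
}

## ---------------------------------------------------------------------------
## Control cohorts

#' Simulate a control cohort sharing polymorphic rearrangements
#'
#' Each control genome carries each shared operation independently with its
#' population frequency; per-control truth junction tables (one pseudo-read
#' per junction) are always returned, and reads can be simulated on demand.
#'
#' @param genome reference [Biostrings::DNAStringSet].
#' @param shared_ops list of `list(op = <rearrangement_op>, freq = <p>)`.
#' @param n number of controls.
#' @param seed integer.
#' @param with_reads also simulate reads per control (slower).
#' @param ... passed to [simulate_reads()] when `with_reads`.
#' @return list of length `n`; each element has `ops` (those included),
#'   `junctions` (truth junction table), and optionally `reads`/`truth`.
#' @export
make_control_cohort <- function(genome, shared_ops, n, seed = 1,
                                with_reads = FALSE, ...) {
  stopifnot(n >= 1)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    inc <- vapply(shared_ops, function(s) stats::runif(1) < s$freq, TRUE)
    ops <- lapply(shared_ops[inc], `[[`, "op")
    ctl <- if (length(ops)) apply_rearrangements(genome, ops, seed = seed + i)
           else NULL
    jj <- if (is.null(ctl)) empty_junctions() else ctl$truth$junctions
    if (nrow(jj)) jj$read_id <- sprintf("ctrl%d_%s_%d", i, jj$read_id, seq_len(nrow(jj)))
    out <- list(ops = ops, junctions = jj)
    if (with_reads) {
      src <- if (is.null(ctl)) genome else ctl$derived
      rr <- simulate_reads(src, seed = seed + 1000L + i,
                           prefix = sprintf("c%d_", i), ...)
      out$reads <- rr$reads; out$read_truth <- rr$truth
    }
    out
  })
}
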