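## Parsimony linking of read groups into derivative chromosomes, with the
## emergent loss/gain report that only full reconstruction can provide.

#' Build a chain from a consensus (or any ordered segment alignment)
#'
#' A chain is the ordered, oriented run of reference segments implied by
#' one group's consensus, with two free ends describing how it would extend
#' along the reference if continued without further rearrangement.
#'
#' @param x a `group_consensus` with `chain_alignment` (see
#'   [consensus_chain()]), or a segment data.frame, or a data.frame with
#'   columns `chrom`, `start`, `end`, `orient`.
#' @param id chain id.
#' @return a `chain` object: `id` plus `segments` (chrom, start, end,
#'   orient, in derived order).
#' @export
build_chain <- function(x, id = NULL) {
  if (inherits(x, "group_consensus")) {
    if (is.null(x$chain_alignment) || nrow(x$chain_alignment) == 0) {
      stop("consensus has no chain alignment; run consensus_chain() first")
    }
    segs <- x$chain_alignment[order(x$chain_alignment$read_start), , drop = FALSE]
    segments <- data.frame(chrom = segs$chrom, start = segs$ref_start,
                           end = segs$ref_end, orient = segs$strand,
                           stringsAsFactors = FALSE)
    if (is.null(id)) id <- x$group_id
  } else if (all(c("chrom", "start", "end", "orient") %in% names(x))) {
    segments <- as.data.frame(x)[, c("chrom", "start", "end", "orient")]
  } else if (all(c("chrom", "ref_start", "ref_end", "strand") %in% names(x))) {
    segs <- x[order(x$read_start), , drop = FALSE]
    segments <- data.frame(chrom = segs$chrom, start = segs$ref_start,
                           end = segs$ref_end, orient = segs$strand,
                           stringsAsFactors = FALSE)
  } else stop("cannot interpret chain input")
  if (nrow(segments) == 0) stop("empty chain")
  stopifnot(all(segments$start < segments$end),
            all(segments$orient %in% c("+", "-")))
  if (is.null(id)) id <- "chain"
  structure(list(id = id, segments = segments), class = "chain")
}

# The two free ends of a chain.  outward is the reference direction in
# which the chain would extend if continued: "higher" or "lower".
chain_ends <- function(chain) {
  s <- chain$segments
  first <- s[1, ]; last <- s[nrow(s), ]
  left <- if (first$orient == "+") {
    list(chrom = first$chrom, pos = first$start, outward = "lower")
  } else list(chrom = first$chrom, pos = first$end, outward = "higher")
  right <- if (last$orient == "+") {
    list(chrom = last$chrom, pos = last$end, outward = "higher")
  } else list(chrom = last$chrom, pos = last$start, outward = "lower")
  list(left = left, right = right)
}

# interior breakends of every chain: positions flanking each junction
chain_breakends <- function(chains) {
  rows <- lapply(chains, function(ch) {
    s <- ch$segments
    n <- nrow(s)
    if (n < 2) return(NULL)
    out <- list()
    for (i in seq_len(n - 1L)) {
      a <- s[i, ]; b <- s[i + 1L, ]
      out[[i]] <- data.frame(
        chrom = c(a$chrom, b$chrom),
        pos = c(if (a$orient == "+") a$end else a$start,
                if (b$orient == "+") b$start else b$end))
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(chrom = character(), pos = integer()) else out
}

#' Link chains into a minimal number of derivative chromosomes
#'
#' Two free ends are joinable iff they lie on the same chromosome facing
#' each other (one outward-higher at `p`, the other outward-lower at `q`,
#' `p <= q`), no other free end lies strictly inside `(p, q)`, and the
#' connecting interval contains no breakend of any chain (such a breakend
#' would have to be linked through, not jumped over).  A solution is a set
#' of joins, each free end used at most once, forming no ring; among all
#' solutions those minimizing the number of resulting linear chromosomes
#' are found by exhaustive backtracking.  Unmatched free ends run out to
#' the chromosome ends.  `n_optimal` counts distinct optimal solutions
#' after canonicalization; if it exceeds 1 the canonically first solution
#' is returned with `unique = FALSE`.
#'
#' @param chains list of `chain` objects (pairwise distinct).
#' @param chrom_lengths named integer vector of reference chromosome lengths.
#' @return a `reconstruction` object: `derivatives` (list; each has `id`,
#'   `segments` with maximal colinear runs merged, `source_chains`),
#'   `unique`, `n_optimal`, `unlinked` (chain ids joinable with no other
#'   chain), `rings` (self-joinable chains, excluded), and `joins`.
#' @export
link_chains <- function(chains, chrom_lengths) {
  stopifnot(length(chains) >= 1)
  ids <- vapply(chains, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("chains must have distinct ids")
  # ring detection: a chain whose own two ends are joinable
  ends_of <- lapply(chains, chain_ends)
  bends <- chain_breakends(chains)
  all_ends <- do.call(rbind, lapply(seq_along(chains), function(i) {
    e <- ends_of[[i]]
    data.frame(chain = i, side = c("left", "right"),
               chrom = c(e$left$chrom, e$right$chrom),
               pos = c(e$left$pos, e$right$pos),
               outward = c(e$left$outward, e$right$outward),
               stringsAsFactors = FALSE)
  }))
  joinable <- function(i, j) { # rows of all_ends
    a <- all_ends[i, ]; b <- all_ends[j, ]
    if (a$chrom != b$chrom) return(FALSE)
    if (a$outward == b$outward) return(FALSE)
    hi <- if (a$outward == "higher") a else b
    lo <- if (a$outward == "higher") b else a
    p <- hi$pos; q <- lo$pos
    if (p > q) return(FALSE)
    inside <- all_ends$chrom == a$chrom & all_ends$pos > p & all_ends$pos < q
    inside[c(i, j)] <- FALSE
    if (any(inside)) return(FALSE)
    if (nrow(bends)) {
      inb <- bends$chrom == a$chrom & bends$pos > p & bends$pos < q
      if (any(inb)) return(FALSE)
    }
    TRUE
  }
  n_end <- nrow(all_ends)
  rings <- integer(0)
  for (ci in seq_along(chains)) {
    e <- which(all_ends$chain == ci)
    if (joinable(e[1], e[2])) rings <- c(rings, ci)
  }
  active <- setdiff(seq_along(chains), rings)
  act_ends <- which(all_ends$chain %in% active)
  pairs <- list()
  if (length(act_ends) >= 2) {
    cmb <- utils::combn(act_ends, 2)
    for (c2 in seq_len(ncol(cmb))) {
      i <- cmb[1, c2]; j <- cmb[2, c2]
      if (all_ends$chain[i] == all_ends$chain[j]) next
      if (joinable(i, j)) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  # exhaustive backtracking over candidate joins, forbidding reuse of ends
  # and ring-closing joins; maximize number of joins
  best_k <- -1L
  solutions <- list()
  n_pairs <- length(pairs)
  used <- rep(FALSE, n_end)
  parent <- seq_along(chains)
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  recurse <- function(idx, taken, k) {
    if (idx > n_pairs) {
      if (k > best_k) { best_k <<- k; solutions <<- list(taken) }
      else if (k == best_k) solutions[[length(solutions) + 1L]] <<- taken
      return(invisible())
    }
    if (k + (n_pairs - idx + 1L) < best_k) return(invisible()) # prune
    p <- pairs[[idx]]
    ca <- all_ends$chain[p[1]]; cb <- all_ends$chain[p[2]]
    if (!used[p[1]] && !used[p[2]] && findp(ca) != findp(cb)) {
      used[p[1]] <<- TRUE; used[p[2]] <<- TRUE
      old_parent <- parent
      parent[findp(ca)] <<- findp(cb)
      recurse(idx + 1L, c(taken, idx), k + 1L)
      parent <<- old_parent
      used[p[1]] <<- FALSE; used[p[2]] <<- FALSE
    }
    recurse(idx + 1L, taken, k)
    invisible()
  }
  recurse(1L, integer(0), 0L)
  # deduplicate solutions (sets of joins)
  sol_keys <- vapply(solutions, function(s) paste(sort(s), collapse = ","), "")
  solutions <- solutions[!duplicated(sol_keys)]
  canon_key <- function(sol) {
    d <- derivatives_from(chains, all_ends, pairs[sol], chrom_lengths, active)
    paste(vapply(d, function(x) paste(x$segments$chrom, x$segments$start,
                                      x$segments$end, x$segments$orient,
                                      collapse = ";"), ""), collapse = "|")
  }
  keys <- vapply(solutions, canon_key, "")
  o <- order(keys)
  solutions <- solutions[o][!duplicated(keys[o])]
  n_optimal <- length(solutions)
  chosen <- solutions[[1]]
  derivs <- derivatives_from(chains, all_ends, pairs[chosen], chrom_lengths,
                             active)
  # ring chains become their own circular derivatives, reported separately
  linked <- unique(unlist(lapply(pairs[chosen], function(p) all_ends$chain[p])))
  unlinked <- ids[setdiff(active, linked)]
  structure(list(derivatives = derivs, unique = n_optimal == 1L,
                 n_optimal = n_optimal, unlinked = unlinked,
                 rings = ids[rings],
                 joins = lapply(pairs[chosen], function(p) all_ends[p, ])),
            class = "reconstruction")
}

# assemble derivative chromosomes from a chosen set of joins
derivatives_from <- function(chains, all_ends, joins, chrom_lengths, active) {
  # partner map over end indices
  partner <- rep(NA_integer_, nrow(all_ends))
  for (p in joins) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
  end_idx <- function(ci, side) which(all_ends$chain == ci & all_ends$side == side)
  seen <- rep(FALSE, length(chains))
  seen[setdiff(seq_along(chains), active)] <- TRUE # rings handled elsewhere
  derivs <- list()
  ext_segment <- function(end, entering) {
    # reference run between a free end and its chromosome end.
    len <- chrom_lengths[[end$chrom]]
    if (is.null(len)) stop("missing chromosome length for ", end$chrom)
    if (end$outward == "lower") {
      if (end$pos == 0) return(NULL)
      # traversal: entering the path start moves 0 -> pos ('+'); leaving the
      # path end moves pos -> 0 ('-')
      data.frame(chrom = end$chrom, start = 0L, end = end$pos,
                 orient = if (entering) "+" else "-", stringsAsFactors = FALSE)
    } else {
      if (end$pos >= len) return(NULL)
      data.frame(chrom = end$chrom, start = end$pos, end = len,
                 orient = if (entering) "-" else "+", stringsAsFactors = FALSE)
    }
  }
  join_segment <- function(exit_end, enter_end) {
    p <- sort(c(exit_end$pos, enter_end$pos))
    if (p[1] == p[2]) return(NULL)
    # traversed upward if the exiting end points higher, else downward
    data.frame(chrom = exit_end$chrom, start = p[1], end = p[2],
               orient = if (exit_end$outward == "higher") "+" else "-",
               stringsAsFactors = FALSE)
  }
  chain_run <- function(ci, from_side) {
    s <- chains[[ci]]$segments
    if (from_side == "left") s else {
      s2 <- s[rev(seq_len(nrow(s))), , drop = FALSE]
      s2$orient <- ifelse(s2$orient == "+", "-", "+")
      s2
    }
  }
  repeat {
    remaining <- which(!seen)
    if (length(remaining) == 0) break
    # prefer starting from a chain with an unmatched end
    start_chain <- NULL
    for (ci in remaining) {
      for (side in c("left", "right")) {
        if (is.na(partner[end_idx(ci, side)])) { start_chain <- ci; break }
      }
      if (!is.null(start_chain)) break
    }
    if (is.null(start_chain)) break # only cycles left; should not happen
    # find a terminal end of this chain's path
    term_side <- NULL
    for (side in c("left", "right")) {
      if (is.na(partner[end_idx(start_chain, side)])) { term_side <- side; break }
    }
    if (is.null(term_side)) next # part of a cycle; should not happen
    segs <- list()
    srcs <- character(0)
    e0 <- all_ends[end_idx(start_chain, term_side), ]
    segs[[1]] <- ext_segment(e0, entering = TRUE)
    ci <- start_chain; enter_side <- term_side
    repeat {
      seen[ci] <- TRUE
      srcs <- c(srcs, chains[[ci]]$id)
      segs[[length(segs) + 1L]] <- chain_run(ci, enter_side)
      exit_side <- if (enter_side == "left") "right" else "left"
      eidx <- end_idx(ci, exit_side)
      pid <- partner[eidx]
      if (is.na(pid)) {
        segs[[length(segs) + 1L]] <- ext_segment(all_ends[eidx, ], entering = FALSE)
        break
      }
      segs[[length(segs) + 1L]] <- join_segment(all_ends[eidx, ], all_ends[pid, ])
      ci <- all_ends$chain[pid]; enter_side <- all_ends$side[pid]
    }
    segments <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
    derivs[[length(derivs) + 1L]] <- list(segments = segments, source_chains = srcs)
  }
  # canonical orientation: a derivative equals its reverse complement; pick
  # the lexicographically smaller rendering
  flip <- function(s) {
    s2 <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    s2$orient <- ifelse(s2$orient == "+", "-", "+")
    rownames(s2) <- NULL
    s2
  }
  render <- function(s) paste(s$chrom, s$start, s$end, s$orient, collapse = ";")
  derivs <- lapply(derivs, function(d) {
    m <- merge_colinear(d$segments)
    mf <- merge_colinear(flip(d$segments))
    if (render(mf) < render(m)) m <- mf
    list(segments = m, source_chains = d$source_chains)
  })
  o <- order(vapply(derivs, function(d) render(d$segments), ""))
  derivs <- derivs[o]
  for (i in seq_along(derivs)) derivs[[i]]$id <- sprintf("der%d", i)
  derivs
}

# merge maximal colinear runs of adjacent segments
merge_colinear <- function(s) {
  if (nrow(s) <= 1) { rownames(s) <- NULL; return(s) }
  out <- s[1, , drop = FALSE]
  for (i in 2:nrow(s)) {
    a <- out[nrow(out), ]; b <- s[i, ]
    colinear <- a$chrom == b$chrom && a$orient == b$orient &&
      ((a$orient == "+" && a$end == b$start) ||
       (a$orient == "-" && b$end == a$start))
    if (colinear) {
      out$start[nrow(out)] <- min(a$start, b$start)
      out$end[nrow(out)] <- max(a$end, b$end)
    } else out <- rbind(out, b)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction: %d derivative chromosome(s), %s (n_optimal = %d)\n",
              length(x$derivatives),
              if (x$unique) "unique" else "not unique", x$n_optimal))
  for (d in x$derivatives) {
    cat(sprintf("  %s (%d segments; from %s)\n", d$id, nrow(d$segments),
                paste(d$source_chains, collapse = ",")))
  }
  if (length(x$rings)) cat("  rings excluded:", paste(x$rings, collapse = ","), "\n")
  invisible(x)
}

#' Count junctions in a reconstruction
#'
#' The junction-count identity: the sum over derivatives of
#' (segment count - 1).
#'
#' @param result a `reconstruction`.
#' @export
n_junctions <- function(result) {
  sum(vapply(result$derivatives, function(d) nrow(d$segments) - 1L, 0L))
}

#' Emergent sequence loss / gain report
#'
#' Coverage of the reference by all derivative segments; losses are maximal
#' zero-coverage intervals on involved chromosomes (chromosomes with no
#' derivative segment are not reported), gains are maximal intervals with
#' coverage at least 2, annotated with their copy number.
#'
#' @param result a `reconstruction`.
#' @param chrom_lengths named integer vector.
#' @return list with `losses` (chrom, start, end, length) and `gains`
#'   (chrom, start, end, length, copy_number) data.frames.
#' @export
report_loss_gain <- function(result, chrom_lengths) {
  segs <- do.call(rbind, lapply(result$derivatives, `[[`, "segments"))
  losses <- list(); gains <- list()
  for (chrom in sort(unique(segs$chrom))) {
    len <- chrom_lengths[[chrom]]
    ss <- segs[segs$chrom == chrom, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(ss$start + 1L, ss$end),
                             width = len)
    rl <- S4Vectors::runLength(cov); rv <- S4Vectors::runValue(cov)
    ends <- cumsum(rl); starts <- ends - rl + 1L
    zero <- rv == 0
    if (any(zero)) {
      losses[[chrom]] <- data.frame(
        chrom = chrom, start = starts[zero] - 1L, end = ends[zero],
        stringsAsFactors = FALSE)
    }
    hi <- rv >= 2
    if (any(hi)) {
      gains[[chrom]] <- data.frame(
        chrom = chrom, start = starts[hi] - 1L, end = ends[hi],
        copy_number = rv[hi], stringsAsFactors = FALSE)
    }
  }
  losses <- if (length(losses)) do.call(rbind, losses) else
    data.frame(chrom = character(), start = integer(), end = integer())
  gains <- if (length(gains)) do.call(rbind, gains) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               copy_number = integer())
  losses$length <- losses$end - losses$start
  gains$length <- gains$end - gains$start
  rownames(losses) <- rownames(gains) <- NULL
  list(losses = losses, gains = gains)
}
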