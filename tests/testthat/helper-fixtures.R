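# Shared fixtures and independent oracles for the suite.

default_scheme <- function() {
  log_odds_scores(rearrangekit:::add_pseudo(nanopore_error_model()))
}

# a one-row segment table (the unit the aligner and junction code speak)
seg_df <- function(read_id, read_start, read_end, read_len, chrom,
                   ref_start, ref_end, strand, score = 100, mismap = 0,
                   cigar = "") {
  data.frame(read_id = read_id, read_start = read_start, read_end = read_end,
             read_len = read_len, chrom = chrom, ref_start = ref_start,
             ref_end = ref_end, strand = strand, score = score,
             mismap = mismap, cigar = cigar, stringsAsFactors = FALSE)
}

chain_of <- function(id, ...) {
  rows <- list(...)
  segs <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]),
               orient = if (length(r) >= 4) r[[4]] else "+",
               stringsAsFactors = FALSE)
  }))
  build_chain(segs, id)
}

# ---------------------------------------------------------------------------
# Brute-force oracle for the read-division DP: enumerate every assignment
# of read positions to a candidate (or none), require each position to lie
# inside its candidate's interval, score = sum of per-position profile
# values minus jump per segment (maximal run of one candidate) beyond the
# first; return the optimum under (max score, then fewest segments).
# Exhaustive over (C+1)^L assignments, so keep L <= 10 and C <= 3.
brute_force_split <- function(read_len, starts, ends, profiles, jump) {
  C <- length(starts)
  stopifnot((C + 1)^read_len <= 5e6)
  best <- list(score = 0, nseg = 0L)
  assign <- integer(read_len)
  recurse <- function(x) {
    if (x > read_len) {
      runs <- rle(assign)
      segs <- sum(runs$values != 0L)
      sc <- 0
      for (p in seq_len(read_len)) {
        c <- assign[p]
        if (c != 0L) sc <- sc + profiles[[c]][p - starts[c]]
      }
      if (segs > 0) sc <- sc - jump * (segs - 1L)
      if (sc > best$score + 1e-9 ||
          (sc > best$score - 1e-9 && segs < best$nseg)) {
        best <<- list(score = sc, nseg = segs)
      }
      return(invisible())
    }
    for (c in 0:C) {
      if (c > 0L && (x - 1L < starts[c] || x - 1L >= ends[c])) next
      assign[x] <<- c
      recurse(x + 1L)
    }
    assign[x] <<- 0L
    invisible()
  }
  recurse(1L)
  best
}

# ---------------------------------------------------------------------------
# Brute-force oracle for parsimony linking: enumerate every acyclic
# matching of free ends under an independently coded joinability test, and
# minimize the number of resulting paths.
brute_force_link <- function(chains, chrom_lengths) {
  ends <- list()
  for (ci in seq_along(chains)) {
    s <- chains[[ci]]$segments
    f <- s[1, ]; l <- s[nrow(s), ]
    ends[[length(ends) + 1L]] <- list(
      chain = ci,
      chrom = f$chrom,
      pos = if (f$orient == "+") f$start else f$end,
      outward = if (f$orient == "+") "lower" else "higher")
    ends[[length(ends) + 1L]] <- list(
      chain = ci,
      chrom = l$chrom,
      pos = if (l$orient == "+") l$end else l$start,
      outward = if (l$orient == "+") "higher" else "lower")
  }
  bends <- do.call(rbind, lapply(chains, function(ch) {
    s <- ch$segments
    if (nrow(s) < 2) return(NULL)
    data.frame(chrom = c(s$chrom[-nrow(s)], s$chrom[-1]),
               pos = c(ifelse(s$orient[-nrow(s)] == "+", s$end[-nrow(s)],
                              s$start[-nrow(s)]),
                       ifelse(s$orient[-1] == "+", s$start[-1], s$end[-1])))
  }))
  can_join <- function(i, j) {
    a <- ends[[i]]; b <- ends[[j]]
    if (a$chain == b$chain) return(FALSE)
    if (a$chrom != b$chrom || a$outward == b$outward) return(FALSE)
    hi <- if (a$outward == "higher") a else b
    lo <- if (a$outward == "higher") b else a
    if (hi$pos > lo$pos) return(FALSE)
    for (k in seq_along(ends)) {
      if (k == i || k == j) next
      e <- ends[[k]]
      if (e$chrom == a$chrom && e$pos > hi$pos && e$pos < lo$pos) return(FALSE)
    }
    if (!is.null(bends)) {
      inb <- bends$chrom == a$chrom & bends$pos > hi$pos & bends$pos < lo$pos
      if (any(inb)) return(FALSE)
    }
    TRUE
  }
  n <- length(ends)
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (can_join(i, j)) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  # also identify rings (self-joinable chains) the same way link_chains does
  rings <- integer(0)
  for (ci in seq_along(chains)) {
    i <- 2 * ci - 1; j <- 2 * ci
    a <- ends[[i]]; b <- ends[[j]]
    ok <- a$chrom == b$chrom && a$outward != b$outward
    if (ok) {
      hi <- if (a$outward == "higher") a else b
      lo <- if (a$outward == "higher") b else a
      ok <- hi$pos <= lo$pos
      if (ok) {
        for (k in seq_along(ends)) {
          if (k == i || k == j) next
          e <- ends[[k]]
          if (e$chrom == a$chrom && e$pos > hi$pos && e$pos < lo$pos) ok <- FALSE
        }
        if (ok && !is.null(bends)) {
          if (any(bends$chrom == a$chrom & bends$pos > hi$pos &
                  bends$pos < lo$pos)) ok <- FALSE
        }
      }
    }
    if (ok) rings <- c(rings, ci)
  }
  active <- setdiff(seq_along(chains), rings)
  pairs <- Filter(function(p) {
    ends[[p[1]]]$chain %in% active && ends[[p[2]]]$chain %in% active
  }, pairs)
  # recursive matching with union-find carried through arguments
  best <- list(paths = Inf, sols = list())
  rec <- function(idx, used, parent, taken) {
    if (idx > length(pairs)) {
      paths <- length(active) - length(taken)
      if (paths < best$paths) best <<- list(paths = paths, sols = list(taken))
      else if (paths == best$paths) best$sols[[length(best$sols) + 1L]] <<- taken
      return(invisible())
    }
    p <- pairs[[idx]]
    ca <- ends[[p[1]]]$chain; cb <- ends[[p[2]]]$chain
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (!used[p[1]] && !used[p[2]] && find(ca) != find(cb)) {
      parent2 <- parent; parent2[find(ca)] <- find(cb)
      used2 <- used; used2[p] <- TRUE
      rec(idx + 1L, used2, parent2, c(taken, idx))
    }
    rec(idx + 1L, used, parent, taken)
    invisible()
  }
  rec(1L, rep(FALSE, n), seq_along(chains), integer(0))
  keys <- vapply(best$sols, function(s) paste(sort(s), collapse = ","), "")
  list(n_paths = best$paths, n_optimal = length(unique(keys)), rings = rings)
}

# random chain set over few chromosomes for linker battery
random_chains <- function(n_chains, seed) {
  set.seed(seed)
  chroms <- c("c1", "c2")
  lens <- c(c1 = 200000L, c2 = 200000L)
  chains <- lapply(seq_len(n_chains), function(i) {
    k <- sample(1:3, 1)
    segs <- do.call(rbind, lapply(seq_len(k), function(j) {
      chrom <- sample(chroms, 1)
      a <- sample.int(lens[[chrom]] - 2000L, 1)
      w <- sample(500:5000, 1)
      data.frame(chrom = chrom, start = a, end = min(a + w, lens[[chrom]]),
                 orient = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }))
    build_chain(segs, sprintf("rc%d", i))
  })
  list(chains = chains, lens = lens)
}
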