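## Junction extraction, the "two rearranged fragments in common" sharing
## relation, control subtraction, corroboration, and read grouping.

DIR_LEVELS <- c("left", "right")

empty_junctions <- function() {
  data.frame(read_id = character(), chrom1 = character(), pos1 = integer(),
             dir1 = character(), chrom2 = character(), pos2 = integer(),
             dir2 = character(), read_pos = integer(), inserted = integer(),
             kind = character(), stringsAsFactors = FALSE)
}

# breakend of a segment at its read-exit (side = "exit") or read-entry side.
# direction is the side on which retained sequence continues:
# "right" means retained sequence extends toward higher coordinates.
segment_breakend <- function(seg, side) {
  if (side == "exit") {
    if (seg$strand == "+") list(chrom = seg$chrom, pos = seg$ref_end, dir = "left")
    else list(chrom = seg$chrom, pos = seg$ref_start, dir = "right")
  } else {
    if (seg$strand == "+") list(chrom = seg$chrom, pos = seg$ref_start, dir = "right")
    else list(chrom = seg$chrom, pos = seg$ref_end, dir = "left")
  }
}

canonicalize_junction <- function(j) {
  swap <- (j$chrom2 < j$chrom1) |
    (j$chrom2 == j$chrom1 & j$pos2 < j$pos1) |
    (j$chrom2 == j$chrom1 & j$pos2 == j$pos1 & j$dir2 < j$dir1)
  if (any(swap)) {
    tmp <- j[swap, c("chrom1", "pos1", "dir1")]
    j[swap, c("chrom1", "pos1", "dir1")] <- j[swap, c("chrom2", "pos2", "dir2")]
    j[swap, c("chrom2", "pos2", "dir2")] <- tmp
  }
  j
}

#' Extract rearrangement junctions from a split-aligned read
#'
#' A junction is emitted between each pair of read-adjacent segments that
#' is (a) on different chromosomes, (b) on different strands, or (c) on the
#' same chromosome and strand with a forward reference gap of at least
#' `min_gap`, a read gap of at least `min_gap`, or a backward jump relative
#' to read order (any overlap or duplication, however small).  Colinear
#' adjacencies with small forward gaps emit nothing: plain small deletions
#' are not rearrangements here.  Segments with mismap above `max_mismap`
#' are dropped first.  Junctions are canonicalized (breakends ordered).
#'
#' @param alignment segment data.frame for one read ([align_read()]).
#' @param min_gap forward-gap threshold in bp (default 10000; 100 is the
#'   supported sensitive setting).
#' @param max_mismap drop segments with mismap above this (default 0.5).
#' @return junction data.frame (possibly 0 rows): breakends
#'   (`chrom1,pos1,dir1`, `chrom2,pos2,dir2`), `read_pos`, `inserted`
#'   (non-templated bases), and geometric `kind`.
#' @export
extract_junctions <- function(alignment, min_gap = 10000L, max_mismap = 0.5) {
  if (nrow(alignment) == 0) return(empty_junctions())
  keep <- is.na(alignment$mismap) | alignment$mismap <= max_mismap
  segs <- alignment[keep, , drop = FALSE]
  if (nrow(segs) < 2) return(empty_junctions())
  segs <- segs[order(segs$read_start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(segs) - 1L)) {
    s1 <- segs[i, ]; s2 <- segs[i + 1L, ]
    read_gap <- s2$read_start - s1$read_end
    emit <- TRUE; kind <- NULL
    if (s1$chrom != s2$chrom) kind <- "interchromosomal"
    else if (s1$strand != s2$strand) kind <- "strand_switch"
    else {
      gap <- if (s1$strand == "+") s2$ref_start - s1$ref_end
             else s1$ref_start - s2$ref_end
      if (gap < 0) kind <- "order_violation"
      else if (gap >= min_gap) kind <- "long_gap"
      else if (read_gap >= min_gap) kind <- "long_gap"
      else emit <- FALSE
    }
    if (!emit) next
    b1 <- segment_breakend(s1, "exit")
    b2 <- segment_breakend(s2, "entry")
    out[[length(out) + 1L]] <- data.frame(
      read_id = s1$read_id, chrom1 = b1$chrom, pos1 = b1$pos, dir1 = b1$dir,
      chrom2 = b2$chrom, pos2 = b2$pos, dir2 = b2$dir,
      read_pos = s1$read_end, inserted = max(0L, read_gap), kind = kind,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_junctions())
  canonicalize_junction(do.call(rbind, out))
}

#' Extract junctions for every read in a segment table
#'
#' @param segments combined segment data.frame ([align_reads()]).
#' @inheritParams extract_junctions
#' @export
extract_all_junctions <- function(segments, min_gap = 10000L, max_mismap = 0.5) {
  if (nrow(segments) == 0) return(empty_junctions())
  parts <- lapply(split(segments, segments$read_id), extract_junctions,
                  min_gap = min_gap, max_mismap = max_mismap)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Do two junctions describe the same rearrangement?
#'
#' True iff, after canonical orientation (in either pairing of the ends),
#' both breakends agree: same chromosome, same retained-sequence direction,
#' positions within `tol`.  Symmetric, and reflexive for any `tol >= 0`.
#'
#' @param a,b single-row junction data.frames.
#' @param tol breakend position tolerance in bp.
#' @export
junctions_match <- function(a, b, tol = 2000L) {
  if (tol < 0) stop("tol must be >= 0")
  direct <- a$chrom1 == b$chrom1 & a$dir1 == b$dir1 & abs(a$pos1 - b$pos1) <= tol &
    a$chrom2 == b$chrom2 & a$dir2 == b$dir2 & abs(a$pos2 - b$pos2) <= tol
  swapped <- a$chrom1 == b$chrom2 & a$dir1 == b$dir2 & abs(a$pos1 - b$pos2) <= tol &
    a$chrom2 == b$chrom1 & a$dir2 == b$dir1 & abs(a$pos2 - b$pos1) <= tol
  direct | swapped
}

# For each row of A, is there any matching row in B?  B may equal A with
# self-matching excluded through `exclude_same_read`.
junction_has_match <- function(A, B, tol, exclude_same_read = FALSE) {
  if (nrow(A) == 0) return(logical(0))
  if (nrow(B) == 0) return(rep(FALSE, nrow(A)))
  keyA <- paste(A$chrom1, A$dir1, A$chrom2, A$dir2)
  keyB <- paste(B$chrom1, B$dir1, B$chrom2, B$dir2)
  res <- rep(FALSE, nrow(A))
  for (k in unique(keyA)) {
    ia <- which(keyA == k); ib <- which(keyB == k)
    if (length(ib) == 0) next
    for (i in ia) {
      ok <- abs(B$pos1[ib] - A$pos1[i]) <= tol & abs(B$pos2[ib] - A$pos2[i]) <= tol
      if (exclude_same_read) ok <- ok & B$read_id[ib] != A$read_id[i]
      if (any(ok)) res[i] <- TRUE
    }
  }
  res
}

# count, for each row of A, the number of distinct *other* reads in B
# carrying a matching junction
junction_support <- function(A, B, tol) {
  if (nrow(A) == 0) return(integer(0))
  keyA <- paste(A$chrom1, A$dir1, A$chrom2, A$dir2)
  keyB <- paste(B$chrom1, B$dir1, B$chrom2, B$dir2)
  res <- integer(nrow(A))
  for (k in unique(keyA)) {
    ia <- which(keyA == k); ib <- which(keyB == k)
    if (length(ib) == 0) next
    for (i in ia) {
      ok <- abs(B$pos1[ib] - A$pos1[i]) <= tol & abs(B$pos2[ib] - A$pos2[i]) <= tol &
        B$read_id[ib] != A$read_id[i]
      res[i] <- length(unique(B$read_id[ib][ok]))
    }
  }
  res
}

#' Discard case reads sharing a rearrangement with any control read
#'
#' A case read is removed if any of its junctions matches any junction of
#' any control read; removal is read-level (whole rearrangements have not
#' been resolved at this stage, so the read is the unit that is dropped).
#' Output order is preserved.
#'
#' @param case junction data.frame of the case reads.
#' @param controls a list of junction data.frames (one per control
#'   individual), or a single combined data.frame.
#' @param tol breakend tolerance in bp (default 2000).
#' @return the case junction table restricted to surviving reads.
#' @export
subtract_controls <- function(case, controls, tol = 2000L) {
  if (is.data.frame(controls)) controls <- list(controls)
  if (nrow(case) == 0 || length(controls) == 0) return(case)
  ctrl <- do.call(rbind, controls)
  if (is.null(ctrl) || nrow(ctrl) == 0) return(case)
  hit <- junction_has_match(case, ctrl, tol)
  bad_reads <- unique(case$read_id[hit])
  case[!(case$read_id %in% bad_reads), , drop = FALSE]
}

#' Discard reads carrying any uncorroborated rearrangement
#'
#' A read is kept iff every one of its junctions matches a junction in at
#' least `min_support - 1` other reads of the same individual (sporadic
#' chimeric artifacts rarely recur).  With `mode = "per-junction"` only the
#' unsupported junctions are dropped instead of the whole read.
#'
#' @param junctions junction data.frame.
#' @param tol breakend tolerance in bp.
#' @param min_support minimum reads (including this one) per rearrangement.
#' @param mode `"per-read"` (default, strict) or `"per-junction"`.
#' @export
require_corroboration <- function(junctions, tol = 2000L, min_support = 2L,
                                  mode = c("per-read", "per-junction")) {
  mode <- match.arg(mode)
  if (nrow(junctions) == 0) return(junctions)
  stopifnot(min_support >= 2)
  supp <- junction_support(junctions, junctions, tol)
  ok <- supp >= min_support - 1L
  if (mode == "per-junction") return(junctions[ok, , drop = FALSE])
  bad_reads <- unique(junctions$read_id[!ok])
  junctions[!(junctions$read_id %in% bad_reads), , drop = FALSE]
}

#' Group reads covering the same rearrangement
#'
#' Builds the graph whose vertices are reads and whose edges join reads
#' with at least one matching junction, takes connected components, and
#' discards components with fewer than `min_group` reads.  Group ids are
#' deterministic: groups are ordered by their smallest member junction.
#'
#' @param junctions junction data.frame (after filtering).
#' @param tol breakend tolerance in bp.
#' @param min_group minimum reads per group (default 3).
#' @return list of groups; each group has `id`, `read_ids`, and
#'   `junction_clusters` (consensus junctions: median breakend positions
#'   and supporting read count per distinct junction).
#' @export
group_reads <- function(junctions, tol = 2000L, min_group = 3L) {
  if (nrow(junctions) == 0) return(list())
  reads <- unique(junctions$read_id)
  key <- paste(junctions$chrom1, junctions$dir1, junctions$chrom2, junctions$dir2)
  edges <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    o <- idx[order(junctions$pos1[idx])]
    p1 <- junctions$pos1[o]; p2 <- junctions$pos2[o]; rid <- junctions$read_id[o]
    for (i in seq_along(o)) {
      j <- i + 1L
      while (j <= length(o) && p1[j] - p1[i] <= tol) {
        if (abs(p2[j] - p2[i]) <= tol && rid[i] != rid[j]) {
          edges[[length(edges) + 1L]] <- c(rid[i], rid[j])
        }
        j <- j + 1L
      }
    }
  }
  edf <- if (length(edges)) {
    m <- unique(do.call(rbind, edges))
    data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(from = character(), to = character())
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = data.frame(name = reads))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- groups[vapply(groups, length, 0L) >= min_group]
  if (length(groups) == 0) return(list())
  # deterministic order: by each group's smallest member junction
  jun_key <- function(ids) {
    jj <- junctions[junctions$read_id %in% ids, , drop = FALSE]
    o <- order(jj$chrom1, jj$pos1, jj$chrom2, jj$pos2)[1]
    sprintf("%s:%012d:%s:%012d", jj$chrom1[o], jj$pos1[o], jj$chrom2[o], jj$pos2[o])
  }
  ord <- order(vapply(groups, jun_key, ""))
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) {
    ids <- groups[[i]]
    jj <- junctions[junctions$read_id %in% ids, , drop = FALSE]
    list(id = sprintf("group%d", i), read_ids = sort(ids),
         junction_clusters = cluster_junctions(jj, tol))
  })
}

# single-linkage clustering of junctions by the matching relation;
# returns one consensus row per cluster (median positions, read support)
cluster_junctions <- function(junctions, tol) {
  n <- nrow(junctions)
  if (n == 0) return(empty_junctions())
  key <- paste(junctions$chrom1, junctions$dir1, junctions$chrom2, junctions$dir2)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    o <- idx[order(junctions$pos1[idx])]
    for (a in seq_along(o)) {
      b <- a + 1L
      while (b <= length(o) &&
             junctions$pos1[o[b]] - junctions$pos1[o[a]] <= tol) {
        if (abs(junctions$pos2[o[b]] - junctions$pos2[o[a]]) <= tol) {
          ra <- find(o[a]); rb <- find(o[b])
          if (ra != rb) parent[rb] <- ra
        }
        b <- b + 1L
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  parts <- split(seq_len(n), roots)
  rows <- lapply(parts, function(ii) {
    jj <- junctions[ii, , drop = FALSE]
    data.frame(read_id = NA_character_,
               chrom1 = jj$chrom1[1], pos1 = as.integer(stats::median(jj$pos1)),
               dir1 = jj$dir1[1],
               chrom2 = jj$chrom2[1], pos2 = as.integer(stats::median(jj$pos2)),
               dir2 = jj$dir2[1], read_pos = NA_integer_,
               inserted = as.integer(stats::median(jj$inserted)),
               kind = jj$kind[1], n_reads = length(unique(jj$read_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-command case-versus-controls filtering and grouping
#'
#' Composes [subtract_controls()], [require_corroboration()], and
#' [group_reads()] in that order, mirroring the one-command
#' `case : control1 control2 ...` semantics.
#'
#' @param case junction data.frame of the case individual.
#' @param controls list of junction data.frames, possibly empty.
#' @inheritParams group_reads
#' @inheritParams require_corroboration
#' @export
filter_and_group <- function(case, controls = list(), tol = 2000L,
                             min_support = 2L, min_group = 3L,
                             mode = "per-read") {
  x <- subtract_controls(case, controls, tol)
  x <- require_corroboration(x, tol, min_support, mode)
  group_reads(x, tol, min_group)
}
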