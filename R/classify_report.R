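## Rule-based geometric classification of rearrangement chains, insertion
## source annotation, summary tables, and dotplot coordinate tracks.

REARRANGEMENT_CATEGORIES <- c(
  "tandem_multiplication", "deletion", "inversion", "non_tandem_duplication",
  "insertion_from_elsewhere", "interchromosomal_translocation",
  "intrachromosomal_translocation", "complex", "unclassified")

#' Classify the rearrangement geometry of a chain
#'
#' Decision rules, applied in order, on the ordered oriented segments:
#' \itemize{
#' \item two same-strand segments on one chromosome jumping backward into
#'   (or before) the previous segment: tandem multiplication, with copy
#'   count the maximum self-coverage depth;
#' \item two colinear segments with a forward gap of at least `min_gap`:
#'   deletion;
#' \item three segments `+,-,+` (or the mirror) with colinear flanks:
#'   inversion;
#' \item a segment copied to a nearby locus (< `near` away) on the same
#'   chromosome, without strand change, between colinear flanks: non-tandem
#'   duplication;
#' \item an extra segment from a distant locus or another chromosome
#'   embedded between colinear flanks: insertion from elsewhere;
#' \item a two-segment chain across two chromosomes: interchromosomal
#'   translocation;
#' \item anything else: complex.
#' }
#'
#' @param chain a `chain` object.
#' @param min_gap forward-gap threshold (as in [extract_junctions()]).
#' @param near distance bound for "nearby" duplications (default 1 Mb).
#' @return a `rearrangement_type`: list with `category`, `subtype`
#'   (NA unless annotated), `copy_count` (NA unless a multiplication).
#' @export
classify_group <- function(chain, min_gap = 10000L, near = 1e6) {
  s <- chain$segments
  n <- nrow(s)
  one_chrom <- length(unique(s$chrom)) == 1
  one_strand <- length(unique(s$orient)) == 1
  res <- function(category, subtype = NA_character_, copy_count = NA_integer_) {
    structure(list(category = category, subtype = subtype,
                   copy_count = copy_count), class = "rearrangement_type")
  }
  if (n == 1) return(res("unclassified"))
  if (one_chrom && one_strand && n >= 2) {
    fwd <- s$orient[1] == "+"
    gaps <- if (fwd) s$start[-1] - s$end[-n] else s$start[-n] - s$end[-1]
    if (all(gaps < 0)) { # every adjacency jumps backward: tandem repeat stack
      cov <- IRanges::coverage(IRanges::IRanges(s$start + 1L, s$end))
      return(res("tandem_multiplication", copy_count = max(S4Vectors::runValue(cov))))
    }
    if (n == 2 && gaps[1] >= min_gap) return(res("deletion"))
  }
  if (one_chrom && n == 3 && s$orient[1] == s$orient[3] &&
      s$orient[2] != s$orient[1]) {
    slack <- 100L # breakpoint jitter / microhomology allowance
    fwd <- s$orient[1] == "+"
    flanks_colinear <- if (fwd) s$start[3] >= s$end[1] else s$end[3] <= s$start[1]
    mid_between <- if (fwd) {
      s$start[2] >= s$end[1] - slack && s$end[2] <= s$start[3] + slack
    } else s$start[2] >= s$end[3] - slack && s$end[2] <= s$start[1] + slack
    if (flanks_colinear && mid_between) return(res("inversion"))
  }
  if (n == 3 && s$orient[1] == s$orient[3] && colinear_pair(s[1, ], s[3, ])) {
    mid <- s[2, ]
    flank_chrom <- s$chrom[1]
    if (mid$chrom != flank_chrom) {
      return(res("insertion_from_elsewhere"))
    }
    gap_pos <- if (s$orient[1] == "+") s$end[1] else s$start[1]
    dist <- min(abs(mid$start - gap_pos), abs(mid$end - gap_pos))
    if (mid$orient == s$orient[1] && dist < near) {
      return(res("non_tandem_duplication"))
    }
    return(res("insertion_from_elsewhere"))
  }
  if (n == 2 && !one_chrom) return(res("interchromosomal_translocation"))
  res("complex")
}

# are a then b colinear in derived order (same chrom/orient, b after a)?
colinear_pair <- function(a, b) {
  a$chrom == b$chrom && a$orient == b$orient &&
    ((a$orient == "+" && b$start >= a$end) ||
     (a$orient == "-" && b$end <= a$start))
}

#' Label the source of an inserted segment from annotation intervals
#'
#' If the inserted (middle) segment of a chain overlaps an annotation
#' interval over at least half of its length, that label is returned (for
#' example a retrotransposon family).  A segment sourced from the
#' mitochondrial sequence is labelled `"NUMT"` regardless of annotation.
#' A middle segment whose source splits into two or more disjoint
#' same-orientation intervals on one chromosome separated by gaps of at
#' least `min_gap` (the intron-loss pattern) is labelled
#' `"processed_pseudogene"`.
#'
#' @param chain a `chain` whose middle segment(s) are the insertion.
#' @param annotation data.frame with `chrom`, `start`, `end`, `label`
#'   (0-based half-open); may be empty.
#' @param mito_chrom name of the mitochondrial sequence (default "chrM").
#' @param min_gap intron-gap threshold for the pseudogene rule.
#' @return a subtype string, or `NA` if nothing applies.
#' @export
annotate_insertion_source <- function(chain, annotation = NULL,
                                      mito_chrom = "chrM", min_gap = 10000L) {
  s <- chain$segments
  n <- nrow(s)
  if (n < 3) return(NA_character_)
  mid <- s[2:(n - 1L), , drop = FALSE]
  if (any(mid$chrom == mito_chrom)) return("NUMT")
  if (nrow(mid) >= 2 && length(unique(mid$chrom)) == 1 &&
      length(unique(mid$orient)) == 1) {
    o <- order(mid$start)
    gaps <- mid$start[o][-1] - mid$end[o][-nrow(mid)]
    ordered_consistent <- identical(o, if (mid$orient[1] == "+")
      seq_len(nrow(mid)) else rev(seq_len(nrow(mid))))
    if (all(gaps >= min_gap) && ordered_consistent) return("processed_pseudogene")
  }
  if (is.null(annotation) || nrow(annotation) == 0) return(NA_character_)
  for (i in seq_len(nrow(mid))) {
    hit <- annotation$chrom == mid$chrom[i] &
      pmin(annotation$end, mid$end[i]) - pmax(annotation$start, mid$start[i]) >=
        (mid$end[i] - mid$start[i]) / 2
    if (any(hit)) return(annotation$label[which(hit)[1]])
  }
  NA_character_
}

#' Summarize rearrangement types over groups
#'
#' @param types list of `rearrangement_type` objects (one per group).
#' @return data.frame of counts by category (and subtype where present);
#'   `sum(n)` equals the number of groups.
#' @export
summarize_rearrangements <- function(types) {
  if (length(types) == 0) {
    return(data.frame(category = character(), subtype = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    category = vapply(types, `[[`, "", "category"),
    subtype = vapply(types, function(t) {
      if (is.na(t$subtype)) NA_character_ else t$subtype
    }, ""), stringsAsFactors = FALSE)
  agg <- stats::aggregate(rep(1L, nrow(df)),
                          by = list(category = df$category,
                                    subtype = ifelse(is.na(df$subtype), "", df$subtype)),
                          FUN = length)
  names(agg)[3] <- "n"
  agg$subtype[agg$subtype == ""] <- NA_character_
  agg <- agg[order(-agg$n, agg$category), ]
  rownames(agg) <- NULL
  agg
}

#' Dotplot coordinates of a derived sequence versus the reference
#'
#' Returns one row per alignment segment (derived interval on the vertical
#' axis, reference interval on the horizontal) plus the two guide-line
#' sets of the two-panel layout: `derived_joins` connect the parts of the
#' derived sequence in derived order, and `reference_joins` connect
#' fragments coming from adjacent parts of the reference genome.
#'
#' @param x a segment data.frame (read or consensus alignment), a `chain`,
#'   or a derivative (list with `segments`).
#' @param adjacency_tol reference fragments whose ends lie within this
#'   distance count as adjacent (default 1).
#' @return a `dotplot_track`: list of `segments`, `derived_joins`,
#'   `reference_joins` data.frames.
#' @export
dotplot_data <- function(x, adjacency_tol = 1L) {
  if (inherits(x, "chain")) s0 <- x$segments
  else if (is.list(x) && !is.data.frame(x) && !is.null(x$segments)) s0 <- x$segments
  else s0 <- NULL
  if (!is.null(s0)) {
    lens <- s0$end - s0$start
    d_end <- cumsum(lens)
    segs <- data.frame(derived_start = d_end - lens, derived_end = d_end,
                       chrom = s0$chrom, ref_start = s0$start, ref_end = s0$end,
                       strand = s0$orient, mismap = 0, stringsAsFactors = FALSE)
  } else {
    s <- x[order(x$read_start), , drop = FALSE]
    segs <- data.frame(derived_start = s$read_start, derived_end = s$read_end,
                       chrom = s$chrom, ref_start = s$ref_start,
                       ref_end = s$ref_end, strand = s$strand,
                       mismap = ifelse(is.na(s$mismap), 0, s$mismap),
                       stringsAsFactors = FALSE)
  }
  n <- nrow(segs)
  derived_joins <- if (n >= 2) data.frame(
    from = segs$derived_end[-n], to = segs$derived_start[-1]) else
    data.frame(from = numeric(), to = numeric())
  # reference-adjacency joins: fragment ends that abut on the reference
  ref_joins <- list()
  if (n >= 2) {
    bounds <- data.frame(
      seg = rep(seq_len(n), 2),
      chrom = rep(segs$chrom, 2),
      pos = c(segs$ref_start, segs$ref_end),
      side = rep(c("start", "end"), each = n))
    o <- order(bounds$chrom, bounds$pos, bounds$side) # "end" sorts first on ties
    b <- bounds[o, ]
    for (i in seq_len(nrow(b) - 1L)) {
      if (b$chrom[i] == b$chrom[i + 1L] && b$seg[i] != b$seg[i + 1L] &&
          b$side[i] == "end" && b$side[i + 1L] == "start" &&
          b$pos[i + 1L] - b$pos[i] <= adjacency_tol) {
        ref_joins[[length(ref_joins) + 1L]] <- data.frame(
          chrom = b$chrom[i], from = b$pos[i], to = b$pos[i + 1L],
          seg_from = b$seg[i], seg_to = b$seg[i + 1L])
      }
    }
  }
  reference_joins <- if (length(ref_joins)) do.call(rbind, ref_joins) else
    data.frame(chrom = character(), from = integer(), to = integer(),
               seg_from = integer(), seg_to = integer())
  structure(list(segments = segs, derived_joins = derived_joins,
                 reference_joins = reference_joins), class = "dotplot_track")
}

#' Plot a dotplot track
#'
#' Base-graphics rendering of [dotplot_data()]: derived sequence vertical,
#' reference horizontal (chromosomes laid end to end), forward segments as
#' rising diagonals, reverse segments falling, low-confidence segments
#' (high mismap) dashed.
#'
#' @param x a `dotplot_track`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dotplot_track <- function(x, ...) {
  segs <- x$segments
  chroms <- unique(segs$chrom)
  offs <- stats::setNames(cumsum(c(0, vapply(chroms, function(cc)
    max(segs$ref_end[segs$chrom == cc]), 0)))[seq_along(chroms)], chroms)
  gx0 <- offs[segs$chrom] + segs$ref_start
  gx1 <- offs[segs$chrom] + segs$ref_end
  plot(NA, xlim = range(c(gx0, gx1)), ylim = range(c(segs$derived_start, segs$derived_end)),
       xlab = "reference", ylab = "derived sequence", ...)
  fwd <- segs$strand == "+"
  graphics::segments(gx0[fwd], segs$derived_start[fwd], gx1[fwd], segs$derived_end[fwd],
                     col = "red", lty = ifelse(segs$mismap[fwd] > 0.5, 2, 1))
  graphics::segments(gx0[!fwd], segs$derived_end[!fwd], gx1[!fwd], segs$derived_start[!fwd],
                     col = "blue", lty = ifelse(segs$mismap[!fwd] > 0.5, 2, 1))
  invisible(x)
}
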