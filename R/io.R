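#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that upper-cases the
#' sequence, keeps Phred+33 qualities (FASTQ) as an integer list in the
#' element metadata, and validates what Biostrings accepts silently: a FASTQ
#' record whose quality string length differs from its sequence length is a
#' parse error naming the record and line.
#'
#' @param source path to a FASTA or FASTQ file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (decide from the first
#'   non-empty character: `>` means FASTA, `@` means FASTQ).
#' @return A [Biostrings::DNAStringSet] named by record id; for FASTQ input
#'   the metadata column `qualities` holds an [IRanges::IntegerList] of
#'   Phred scores.
#' @export
read_sequences <- function(source, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    head <- readLines(source, n = 1L)
    if (length(head) == 0L) stop("empty sequence file: ", source)
    format <- if (startsWith(head, "@")) "fastq" else "fasta"
  }
  if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(source, format = "fasta")
  } else {
    # validate structure first: Biostrings tolerates (and mangles) records
    # whose quality string length differs from the sequence length
    lines <- readLines(source)
    lines <- lines[nzchar(lines)]
    if (length(lines) %% 4 != 0) stop("FASTQ parse error: truncated record at end of ", source)
    for (k in seq_len(length(lines) / 4)) {
      sq <- lines[4L * k - 2L]; ql <- lines[4L * k]
      if (nchar(sq) != nchar(ql)) {
        stop(sprintf(
          "FASTQ parse error: record '%s' (line %d) has %d bases but %d quality symbols",
          sub("^@", "", sub(" .*", "", lines[4L * k - 3L])), 4L * k,
          nchar(sq), nchar(ql)))
      }
    }
    x <- Biostrings::readDNAStringSet(source, format = "fastq",
                                      with.qualities = TRUE)
    quals <- IRanges::IntegerList(lapply(
      as.character(S4Vectors::mcols(x)$qualities),
      function(q) utf8ToInt(q) - 33L))
    S4Vectors::mcols(x)$qualities <- quals
  }
  if (any(Biostrings::width(x) < 1L)) {
    stop("sequence file contains an empty record: ",
         names(x)[which(Biostrings::width(x) < 1L)[1]])
  }
  # upper-case via DNAStringSet round trip (DNAStringSet is case-preserving)
  y <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(y) <- names(x)
  S4Vectors::mcols(y) <- S4Vectors::mcols(x)
  y
}

#' Write sequences to FASTA
#'
#' @param x a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## MAF (LAST dialect)

#' Read alignments in MAF format (LAST dialect)
#'
#' Parses `a`/`s`/`p` blocks.  Each block must have exactly two `s` rows;
#' the first is taken as the genome row, the second as the read row.  A `p`
#' line, when present, is attached to the read row and decoded with
#' [decode_prob_symbols()] on demand.  Coordinates follow the MAF
#' convention: 0-based starts; for `-` strand rows the start counts from
#' the start of the reverse-complemented sequence.
#'
#' @param source path to a MAF file.
#' @return A list of MAF blocks.  Each block is a list with `score`
#'   (numeric), `rows` (data.frame with columns `seq_name`, `start`,
#'   `aln_size`, `strand`, `src_size`, `text`), and `probs` (the raw `p`
#'   line symbols, or `NA`).
#' @export
read_maf <- function(source) {
  lines <- readLines(source)
  lines <- lines[!startsWith(lines, "#")]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, k) {
    if (is.null(cur)) return(NULL)
    if (nrow(cur$rows) != 2L) {
      stop(sprintf("MAF parse error in block %d: expected 2 's' rows, got %d",
                   k, nrow(cur$rows)))
    }
    if (nchar(cur$rows$text[1]) != nchar(cur$rows$text[2])) {
      stop(sprintf("MAF parse error in block %d: aligned texts differ in length", k))
    }
    for (i in 1:2) {
      ungapped <- nchar(gsub("-", "", cur$rows$text[i], fixed = TRUE))
      if (ungapped != cur$rows$aln_size[i]) {
        stop(sprintf(
          "MAF parse error in block %d: row %d aln_size %d != ungapped length %d",
          k, i, cur$rows$aln_size[i], ungapped))
      }
      if (cur$rows$start[i] + cur$rows$aln_size[i] > cur$rows$src_size[i]) {
        stop(sprintf("MAF parse error in block %d: row %d exceeds src_size", k, i))
      }
    }
    cur
  }
  k <- 0L
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      if (!is.null(cur)) { k <- k + 1L; blocks[[k]] <- flush(cur, k) }
      score <- NA_real_
      m <- regmatches(ln, regexec("score=([-0-9.eE+]+)", ln))[[1]]
      if (length(m) == 2L) score <- as.numeric(m[2])
      cur <- list(score = score,
                  rows = data.frame(seq_name = character(), start = integer(),
                                    aln_size = integer(), strand = character(),
                                    src_size = integer(), text = character(),
                                    stringsAsFactors = FALSE),
                  probs = NA_character_)
    } else if (startsWith(ln, "s")) {
      if (is.null(cur)) stop("MAF parse error: 's' line outside a block")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L) stop("MAF parse error: malformed 's' line: ", ln)
      cur$rows <- rbind(cur$rows, data.frame(
        seq_name = f[2], start = as.integer(f[3]), aln_size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE))
    } else if (startsWith(ln, "p")) {
      if (is.null(cur)) stop("MAF parse error: 'p' line outside a block")
      cur$probs <- strsplit(trimws(ln), "[ \t]+")[[1]][2]
    }
  }
  if (!is.null(cur)) { k <- k + 1L; blocks[[k]] <- flush(cur, k) }
  blocks
}

#' Write MAF blocks
#'
#' Inverse of [read_maf()]; `write_maf(read_maf(f))` reproduces the blocks.
#'
#' @param blocks list of MAF blocks as returned by [read_maf()].
#' @param path output path (or connection).
#' @export
write_maf <- function(blocks, path) {
  out <- character(0)
  for (b in blocks) {
    score <- if (is.na(b$score)) "" else sprintf(" score=%s", format(b$score, scientific = FALSE))
    out <- c(out, sprintf("a%s", score))
    w_name <- max(nchar(b$rows$seq_name))
    for (i in seq_len(nrow(b$rows))) {
      r <- b$rows[i, ]
      out <- c(out, sprintf("s %-*s %10d %9d %s %10d %s", w_name, r$seq_name,
                            r$start, r$aln_size, r$strand, r$src_size, r$text))
    }
    if (!is.na(b$probs)) {
      out <- c(out, sprintf("p %-*s %10s %9s %s %10s %s", w_name, "", "", "", " ", "", b$probs))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Decode / encode MAF "p"-line probability symbols
#'
#' LAST encodes the per-column probability that a base is wrongly aligned as
#' printable symbols: `chr(33 + round(-10 log10 p))`, capped at `~` (0x7e).
#' Symbols below `!` (or otherwise unknown) decode to probability 1,
#' permitting ingestion of alignments from other producers.
#'
#' @param symbols a single string of probability symbols.
#' @return numeric vector of error probabilities in `[0, 1]`.
#' @export
decode_prob_symbols <- function(symbols) {
  v <- utf8ToInt(symbols) - 33L
  p <- 10^(-v / 10)
  p[v < 0L] <- 1
  pmin(p, 1)
}

#' @rdname decode_prob_symbols
#' @param p numeric vector of error probabilities.
#' @export
encode_prob_symbols <- function(p) {
  p <- pmin(pmax(p, 1e-9), 1)
  v <- pmin(as.integer(round(-10 * log10(p))), 93L)
  intToUtf8(33L + v)
}

## ---------------------------------------------------------------------------
## BED

#' Write intervals in BED format
#'
#' Tab-separated, 0-based half-open, in input order, locale-independent
#' number formatting.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, and
#'   optionally `name` plus any extra columns, written in order.
#' @param path output path (or connection).
#' @export
write_intervals <- function(intervals, path) {
  if (nrow(intervals) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) {
    bad <- which(intervals$start >= intervals$end)[1]
    stop(sprintf("invalid interval %s:%d-%d (start must be < end)",
                 intervals$chrom[bad], intervals$start[bad], intervals$end[bad]))
  }
  cols <- lapply(intervals, function(col) {
    if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Group files

#' Write / read read-group files
#'
#' One block per group: a header line `# group <id> <n_reads>` followed by
#' one MAF block per aligned read fragment.  The MAF payload round-trips
#' through [read_maf()].
#'
#' @param groups list of read groups (see [group_reads()]).
#' @param genome named [Biostrings::DNAStringSet] used to regenerate aligned
#'   text for each fragment.
#' @param reads named [Biostrings::DNAStringSet] of the reads.
#' @param path output path.
#' @export
write_groups <- function(groups, genome, reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in groups) {
    ids <- unique(g$segments$read_id)
    writeLines(sprintf("# group %s %d", g$id, length(ids)), con)
    blocks <- segments_to_maf(g$segments, genome, reads)
    txt <- textConnection("zz", "w", local = TRUE)
    write_maf(blocks, txt)
    close(txt)
    writeLines(zz, con)
  }
  invisible(path)
}

#' @rdname write_groups
#' @return `read_groups()`: a list with one element per group, each holding
#'   `id`, `n_reads`, and the MAF `blocks`.
#' @export
read_groups <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# group ", lines)
  if (length(hdr) == 0L) return(list())
  bounds <- c(hdr, length(lines) + 1L)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    f <- strsplit(lines[hdr[i]], " +")[[1]]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    tc <- textConnection(body)
    blocks <- read_maf(tc)
    close(tc)
    out[[i]] <- list(id = f[3], n_reads = as.integer(f[4]), blocks = blocks)
  }
  out
}

## ---------------------------------------------------------------------------
## Error-model serialization

#' Save / load an error model as a flat key=value text file
#'
#' @param model an `error_model` object (see [estimate_error_model()]).
#' @param path file path.
#' @export
write_error_model <- function(model, path) {
  bases <- c("A", "C", "G", "T")
  kv <- c(
    sprintf("p_sub_%s%s=%.10g", rep(bases, each = 4), rep(bases, 4),
            as.vector(t(model$p_sub))),
    sprintf("p_del_open=%.10g", model$p_del_open),
    sprintf("p_del_extend=%.10g", model$p_del_extend),
    sprintf("p_ins_open=%.10g", model$p_ins_open),
    sprintf("p_ins_extend=%.10g", model$p_ins_extend),
    sprintf("background_%s=%.10g", bases, model$background))
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                          vapply(kv, `[`, "", 1))
  bases <- c("A", "C", "G", "T")
  p_sub <- matrix(vals[sprintf("p_sub_%s%s", rep(bases, each = 4), rep(bases, 4))],
                  4, 4, byrow = TRUE, dimnames = list(bases, bases))
  new_error_model(p_sub,
                  vals[["p_del_open"]], vals[["p_del_extend"]],
                  vals[["p_ins_open"]], vals[["p_ins_extend"]],
                  stats::setNames(vals[sprintf("background_%s", bases)], bases))
}
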