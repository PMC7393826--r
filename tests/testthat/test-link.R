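test_that("chains expose the right free ends and build from alignments", {
  lin <- chain_of("lin", list("c", 100L, 900L, "+"))
  e <- rearrangekit:::chain_ends(lin)
  expect_equal(e$left, list(chrom = "c", pos = 100L, outward = "lower"))
  expect_equal(e$right, list(chrom = "c", pos = 900L, outward = "higher"))

  inv <- chain_of("inv", list("c", 0L, 100L, "+"), list("c", 150L, 250L, "-"),
                  list("c", 250L, 400L, "+"))
  ei <- rearrangekit:::chain_ends(inv)
  expect_equal(ei$left$outward, "lower")
  expect_equal(ei$right$outward, "higher")
  expect_equal(ei$left$chrom, ei$right$chrom)

  expect_error(build_chain(data.frame(chrom = character(), start = integer(),
                                      end = integer(), orient = character())),
               "empty chain")
})

test_that("a single colinear chain is one trivially unique derivative", {
  res <- link_chains(list(chain_of("c1", list("c", 1000L, 5000L, "+"))),
                     c(c = 10000L))
  expect_length(res$derivatives, 1)
  expect_true(res$unique)
  expect_equal(res$n_optimal, 1)
  # telomere extensions merge into one segment covering the chromosome
  expect_equal(res$derivatives[[1]]$segments,
               data.frame(chrom = "c", start = 0L, end = 10000L, orient = "+"))
})

test_that("the chr11-style chains link to one linear derivative with the printed losses", {
  sc <- scenario_chr11(absolute_coords = TRUE)
  res <- link_chains(sc$chains, sc$chrom_lengths)
  expect_length(res$derivatives, 1)
  expect_true(res$unique)
  lg <- report_loss_gain(res, sc$chrom_lengths)
  expect_equal(nrow(lg$losses), 3)
  expect_equal(lg$losses$start, sc$expected_losses$start)
  expect_equal(lg$losses$end, sc$expected_losses$end)
  expect_equal(floor(sort(lg$losses$length, decreasing = TRUE) / 1000),
               c(51, 17, 10))
  expect_equal(nrow(lg$gains), 0)
})

test_that("the five-chromosome scenario links 15 chains into 5 derivatives with 18 junctions", {
  sc <- scenario_patient3(with_reads = FALSE)
  expect_length(sc$truth$chains, 15)
  res <- link_chains(sc$truth$chains, sc$chrom_lengths)
  expect_length(res$derivatives, 5)
  expect_true(res$unique)
  expect_equal(n_junctions(res), 18)
  expect_equal(sum(vapply(res$derivatives, function(d) nrow(d$segments), 0L)), 23)
  # reconstructed structures match the generating truth exactly
  canon <- function(s) { rownames(s) <- NULL; s }
  truth_keys <- sort(vapply(sc$truth$structures, function(s)
    paste(s$chrom, s$start, s$end, s$orient, collapse = ";"), ""))
  # compare up to whole-derivative reverse complement
  flip <- function(s) {
    s2 <- s[rev(seq_len(nrow(s))), ]
    s2$orient <- ifelse(s2$orient == "+", "-", "+")
    s2
  }
  got_keys <- sort(vapply(res$derivatives, function(d) {
    k1 <- paste(d$segments$chrom, d$segments$start, d$segments$end,
                d$segments$orient, collapse = ";")
    f <- flip(d$segments)
    k2 <- paste(f$chrom, f$start, f$end, f$orient, collapse = ";")
    if (k1 %in% truth_keys) k1 else k2
  }, ""))
  expect_equal(got_keys, unname(truth_keys))
})

test_that("rings are detected and reported, not silently dropped", {
  ring <- chain_of("ring", list("c", 5000L, 6000L, "+"), list("c", 1000L, 2000L, "+"))
  lin <- chain_of("lin", list("d", 100L, 900L, "+"))
  res <- link_chains(list(ring, lin), c(c = 10000L, d = 10000L))
  expect_equal(res$rings, "ring")
  expect_length(res$derivatives, 1)
})

test_that("linking matches brute force on random small instances", {
  n_checked <- 0
  for (seed in 1:25) {
    rc <- random_chains(sample(2:5, 1), seed)
    oracle <- brute_force_link(rc$chains, rc$lens)
    got <- link_chains(rc$chains, rc$lens)
    expect_equal(length(got$derivatives), oracle$n_paths,
                 info = sprintf("seed %d", seed))
    if (oracle$n_optimal == 1) {
      expect_true(got$unique, info = sprintf("seed %d", seed))
    }
    expect_lte(got$n_optimal, oracle$n_optimal)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 25)
})

test_that("balanced reciprocal translocations show no loss and no gain", {
  g <- make_reference(c(chrA = 50000L, chrB = 50000L), seed = 2)
  der <- apply_rearrangements(
    g, list(op_reciprocal_translocation("chrA", 20000L, "chrB", 30000L)), seed = 1)
  chains <- lapply(names(der$truth$structures), function(d)
    build_chain(der$truth$structures[[d]], d))
  res <- link_chains(chains, der$truth$chrom_lengths)
  expect_length(res$derivatives, 2)
  lg <- report_loss_gain(res, der$truth$chrom_lengths)
  expect_equal(nrow(lg$losses), 0)
  expect_equal(nrow(lg$gains), 0)
})

test_that("chromothripsis losses are exactly the dropped fragments", {
  g <- make_reference(c(chrA = 120000L), seed = 6)
  opc <- op_chromothripsis("chrA", 20000L, 100000L, n_fragments = 10,
                           dropped = c(3L, 7L),
                           permutation = c(5, 1, 8, 3, 6, 2, 7, 4),
                           orientations = c("+", "-", "+", "+", "-", "+", "-", "+"))
  der <- apply_rearrangements(g, list(opc), seed = 1)
  chains <- lapply(names(der$truth$structures), function(d)
    build_chain(der$truth$structures[[d]], d))
  res <- link_chains(chains, der$truth$chrom_lengths)
  lg <- report_loss_gain(res, der$truth$chrom_lengths)
  bounds <- round(seq(20000L, 100000L, length.out = 11))
  expected <- data.frame(start = bounds[c(3, 7)], end = bounds[c(4, 8)])
  expect_equal(lg$losses$start, expected$start)
  expect_equal(lg$losses$end, expected$end)
  # conservation for this copy-neutral reconstruction:
  # derivative length + losses = reference length
  der_len <- sum(vapply(res$derivatives, function(d)
    sum(d$segments$end - d$segments$start), 0))
  expect_equal(der_len + sum(lg$losses$length), sum(der$truth$chrom_lengths))
  # adjacency signature: fragment boundaries tile the shattered interval
  segs <- do.call(rbind, lapply(res$derivatives, `[[`, "segments"))
  inside <- segs[segs$start >= 20000 & segs$end <= 100000, ]
  kept <- setdiff(1:10, c(3, 7))
  expect_setequal(sort(unique(c(inside$start, inside$end))),
                  sort(unique(c(bounds[kept], bounds[kept + 1L]))))
})

test_that("conservation holds over random copy-neutral scrambles", {
  for (seed in 1:5) {
    g_len <- 150000L
    opc <- op_chromothripsis("chrA", 30000L, 130000L,
                             n_fragments = sample(4:8, 1),
                             dropped = sample(2:3, 1))
    der <- apply_rearrangements(
      make_reference(c(chrA = g_len), seed = seed), list(opc), seed = seed)
    chains <- lapply(names(der$truth$structures), function(d)
      build_chain(der$truth$structures[[d]], d))
    res <- link_chains(chains, der$truth$chrom_lengths)
    lg <- report_loss_gain(res, der$truth$chrom_lengths)
    der_len <- sum(vapply(res$derivatives, function(d)
      sum(d$segments$end - d$segments$start), 0))
    expect_equal(der_len + sum(lg$losses$length), g_len,
                 info = sprintf("seed %d", seed))
  }
})
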