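test_that("reference simulation is deterministic with controllable composition", {
  a <- make_reference(c(chrT = 1000L), seed = 7)
  b <- make_reference(c(chrT = 1000L), seed = 7)
  expect_identical(as.character(a), as.character(b))
  expect_false(identical(as.character(make_reference(c(chrT = 1000L), seed = 8)),
                         as.character(a)))

  at <- make_reference(c(chrT = 2000L), gc = 0, seed = 1)
  expect_true(all(strsplit(as.character(at[[1]]), "")[[1]] %in% c("A", "T")))

  rep2 <- make_reference(c(chrA = 30000L), seed = 5,
                         repeat_pairs = data.frame(chrom = "chrA", start = 2000L,
                                                   length = 2000L,
                                                   dest_chrom = "chrA",
                                                   dest_start = 20000L))
  s <- as.character(rep2[[1]])
  expect_identical(substr(s, 2001, 4000), substr(s, 20001, 22000))
})

test_that("rearrangement operators validate input and record exact truth", {
  g <- make_reference(c(chrA = 50000L, chrB = 50000L), seed = 2)
  ident <- apply_rearrangements(g, list(), seed = 1)
  expect_identical(as.character(ident$derived), as.character(g))
  expect_equal(nrow(ident$truth$junctions), 0)

  expect_error(apply_rearrangements(
    g, list(op_deletion("chrA", 40000L, 60000L)), 1), "out of bounds")
  expect_error(apply_rearrangements(
    g, list(op_deletion("nope", 1L, 10L)), 1), "unknown chromosome")

  tr <- apply_rearrangements(
    g, list(op_reciprocal_translocation("chrA", 20000L, "chrB", 30000L)), seed = 1)
  expect_length(tr$truth$structures, 2)
  expect_equal(nrow(tr$truth$junctions), 2)
  expect_true(all(tr$truth$junctions$kind == "interchromosomal"))
})

test_that("derived sequences equal independent string surgery for basic ops", {
  g <- make_reference(c(chrA = 30000L, chrB = 30000L), seed = 9)
  A <- as.character(g[["chrA"]]); B <- as.character(g[["chrB"]])

  del <- apply_rearrangements(g, list(op_deletion("chrA", 5000L, 9000L)), 1)
  expect_identical(as.character(del$derived[["chrA"]]),
                   paste0(substr(A, 1, 5000), substr(A, 9001, 30000)))

  inv <- apply_rearrangements(g, list(op_inversion("chrA", 5000L, 9000L)), 1)
  expect_identical(as.character(inv$derived[["chrA"]]),
                   paste0(substr(A, 1, 5000),
                          rearrangekit:::revcomp_chr(substr(A, 5001, 9000)),
                          substr(A, 9001, 30000)))

  tm <- apply_rearrangements(g, list(op_tandem_multiplication("chrA", 5000L, 7000L, 3L)), 1)
  expect_identical(as.character(tm$derived[["chrA"]]),
                   paste0(substr(A, 1, 5000), strrep(substr(A, 5001, 7000), 3),
                          substr(A, 7001, 30000)))

  tr <- apply_rearrangements(
    g, list(op_reciprocal_translocation("chrA", 10000L, "chrB", 20000L)), 1)
  expect_identical(as.character(tr$derived[["chrA"]]),
                   paste0(substr(A, 1, 10000), substr(B, 20001, 30000)))
  expect_identical(as.character(tr$derived[["chrB"]]),
                   paste0(substr(B, 1, 20000), substr(A, 10001, 30000)))

  ic <- apply_rearrangements(
    g, list(op_insertion_copy("chrB", 1000L, 1400L, "-", "chrA", 5000L, 12L)), 1)
  expect_identical(as.character(ic$derived[["chrA"]]),
                   paste0(substr(A, 1, 5000),
                          rearrangekit:::revcomp_chr(substr(B, 1001, 1400)),
                          substr(A, 5013, 30000)))
})

test_that("read simulation honors coverage, length law, and the error model", {
  g <- make_reference(c(chrA = 500000L), seed = 3)
  r1 <- simulate_reads(g, coverage = 20, seed = 5)
  r2 <- simulate_reads(g, coverage = 20, seed = 5)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  total <- sum(Biostrings::width(r1$reads))
  expect_lt(abs(total - 20 * 500000) / (20 * 500000), 0.10)

  # error-free reads are exact substrings
  r0 <- simulate_reads(g, coverage = 0.5, model = exact_error_model(), seed = 6)
  s <- as.character(g[[1]])
  for (i in seq_len(nrow(r0$truth))) {
    tr <- r0$truth[i, ]
    piece <- substr(s, tr$start + 1, tr$end)
    if (tr$strand == "-") piece <- rearrangekit:::revcomp_chr(piece)
    expect_identical(as.character(r0$reads[[tr$read_id]]), piece)
  }

  # ~10% error model: per-read edit distance to source near the expected rate
  model <- nanopore_error_model()
  rr <- simulate_reads(g, coverage = 0.3,
                       length_law = list(mean = 5000, sd = 0.2, min = 3000),
                       model = model, seed = 9)
  rates <- vapply(seq_len(min(10, nrow(rr$truth))), function(i) {
    tr <- rr$truth[i, ]
    piece <- substr(s, tr$start + 1, tr$end)
    if (tr$strand == "-") piece <- rearrangekit:::revcomp_chr(piece)
    as.integer(utils::adist(as.character(rr$reads[[tr$read_id]]), piece)) /
      nchar(piece)
  }, 0)
  expected <- rearrangekit:::expected_error_rate(model)
  expect_lt(abs(mean(rates) - expected), 0.02)
})

test_that("control cohorts include shared operations at their frequencies", {
  g <- make_reference(c(chrA = 60000L), seed = 4)
  always <- list(list(op = op_deletion("chrA", 10000L, 22000L), freq = 1),
                 list(op = op_inversion("chrA", 30000L, 45000L), freq = 1))
  cohort <- make_control_cohort(g, always, n = 3, seed = 2)
  for (ctl in cohort) {
    expect_length(ctl$ops, 2)
    expect_gte(nrow(ctl$junctions), 3)
  }
  never <- make_control_cohort(g, list(list(op = always[[1]]$op, freq = 0)),
                               n = 3, seed = 2)
  for (ctl in never) expect_equal(nrow(ctl$junctions), 0)
})

test_that("the five-chromosome scenario satisfies its own bookkeeping", {
  sc <- scenario_patient3(with_reads = FALSE)
  expect_length(sc$truth$chains, 15)
  expect_equal(nrow(sc$truth$junctions), 18)
  expect_equal(sum(vapply(sc$truth$structures, nrow, 0L)), 23)
  expect_length(sc$truth$structures, 5)
  # derived sequences materialize and junction depth is controllable
  sc2 <- scenario_patient3(scale = 1, seed = 3, with_reads = TRUE, coverage = 6)
  expect_gte(length(sc2$reads), 50)
  # every chain segment lies inside its chromosome
  for (ch in sc$truth$chains) {
    expect_true(all(ch$segments$end <= sc$chrom_lengths[ch$segments$chrom]))
  }
})

test_that("the chr11 scenario exists at both absolute and sequence scale", {
  abs <- scenario_chr11(absolute_coords = TRUE)
  expect_length(abs$chains, 3)
  expect_equal(abs$chrom_lengths[["chr11"]], 135086622L)
  expect_equal(abs$expected_losses$end - abs$expected_losses$start,
               c(51591L, 17337L, 10758L))
  sq <- scenario_chr11(absolute_coords = FALSE)
  expect_equal(nrow(sq$expected_losses), 3)
  res <- link_chains(sq$chains, sq$chrom_lengths)
  lg <- report_loss_gain(res, sq$chrom_lengths)
  expect_equal(lg$losses$start, sq$expected_losses$start)
  expect_equal(lg$losses$end, sq$expected_losses$end)
  expect_identical(names(sq$derived), "derZ")
})
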