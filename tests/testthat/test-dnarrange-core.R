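aln2 <- function(chrom1, s1, e1, st1, chrom2, s2, e2, st2, id = "r",
                 read_gap = 0L) {
  rbind(seg_df(id, 0L, e1 - s1, (e1 - s1) + (e2 - s2) + read_gap,
               chrom1, s1, e1, st1),
        seg_df(id, e1 - s1 + read_gap, (e1 - s1) + (e2 - s2) + read_gap,
               (e1 - s1) + (e2 - s2) + read_gap, chrom2, s2, e2, st2))
}

test_that("the 10-kb forward-gap rule and its sensitive variant behave as stated", {
  # colinear gap of 9,999: below threshold, no junction
  a <- aln2("c", 0L, 5000L, "+", "c", 14999L, 20000L, "+")
  expect_equal(nrow(extract_junctions(a, min_gap = 10000L)), 0)
  # gap of exactly 10,000: junction
  b <- aln2("c", 0L, 5000L, "+", "c", 15000L, 20000L, "+")
  jb <- extract_junctions(b, min_gap = 10000L)
  expect_equal(nrow(jb), 1)
  expect_equal(jb$kind, "long_gap")
  # the same 9,999-bp gap is reported under the 100-bp setting
  expect_equal(nrow(extract_junctions(a, min_gap = 100L)), 1)
  # backward jumps (duplications) are reported regardless of size
  d <- aln2("c", 1000L, 5000L, "+", "c", 4500L, 9000L, "+")
  jd <- extract_junctions(d, min_gap = 10000L)
  expect_equal(jd$kind, "order_violation")
})

test_that("junction geometry: interchromosomal, strand switch, single segment", {
  j <- extract_junctions(aln2("chr2", 0L, 5000L, "+", "chrX", 9000L, 14000L, "+"))
  expect_equal(j$kind, "interchromosomal")
  expect_setequal(c(j$chrom1, j$chrom2), c("chr2", "chrX"))

  inv <- extract_junctions(aln2("c", 0L, 5000L, "+", "c", 5000L, 9000L, "-"))
  expect_equal(inv$kind, "strand_switch")

  single <- seg_df("r", 0L, 1000L, 1000L, "c", 0L, 1000L, "+")
  expect_equal(nrow(extract_junctions(single)), 0)

  # high-mismap segments are excluded before extraction
  lowconf <- aln2("chr2", 0L, 5000L, "+", "chrX", 9000L, 14000L, "+")
  lowconf$mismap[2] <- 0.9
  expect_equal(nrow(extract_junctions(lowconf, max_mismap = 0.5)), 0)
})

test_that("a simulated inversion gives exactly two strand-switch junctions at truth", {
  g <- make_reference(c(chrA = 60000L), seed = 13)
  der <- apply_rearrangements(g, list(op_inversion("chrA", 20000L, 35000L)), seed = 1)
  tj <- der$truth$junctions
  expect_equal(nrow(tj), 2)
  expect_true(all(tj$kind == "strand_switch"))
  rr <- simulate_reads(der$derived, coverage = 3,
                       length_law = list(mean = 25000, sd = 0.1, min = 20000),
                       model = exact_error_model(), seed = 2)
  segs <- align_reads(rr$reads, genome_index(g), default_scheme())
  jj <- extract_all_junctions(segs)
  jj <- unique(jj[, c("chrom1", "pos1", "dir1", "chrom2", "pos2", "dir2", "kind")])
  expect_equal(nrow(jj), 2)
  expect_true(all(jj$kind == "strand_switch"))
  expect_setequal(jj$pos1, tj$pos1)
  expect_setequal(jj$pos2, tj$pos2)
})

test_that("junction matching has tolerance semantics and swap invariance", {
  j1 <- extract_junctions(aln2("c", 0L, 5000L, "+", "c", 20000L, 25000L, "+"))
  expect_true(junctions_match(j1, j1, tol = 0))
  j2 <- extract_junctions(aln2("c", 0L, 5037L, "+", "c", 20037L, 25000L, "+"))
  expect_true(junctions_match(j1, j2, tol = 100))
  expect_false(junctions_match(j1, j2, tol = 10))
  expect_error(junctions_match(j1, j2, tol = -1), "tol")

  # chr7->chr15 vs the same junction read in the opposite order
  fwd <- extract_junctions(aln2("chr7", 0L, 5000L, "+", "chr15", 9000L, 14000L, "+"))
  rev <- extract_junctions(aln2("chr15", 9000L, 14000L, "-", "chr7", 0L, 5000L, "-"))
  expect_true(junctions_match(fwd, rev, tol = 0))
})

test_that("control subtraction removes whole reads sharing any junction with controls", {
  case <- rbind(
    extract_junctions(aln2("c", 0L, 5000L, "+", "c", 50000L, 55000L, "+", id = "p1")),
    extract_junctions(aln2("c", 0L, 5000L, "+", "chrX", 100L, 6000L, "+", id = "p2")))
  expect_identical(subtract_controls(case, list()), case)

  ctrl <- extract_junctions(aln2("c", 10L, 5010L, "+", "c", 50010L, 55010L, "+",
                                 id = "ctl1"))
  out <- subtract_controls(case, list(ctrl), tol = 2000L)
  expect_equal(unique(out$read_id), "p2")

  # self-subtraction empties the table
  expect_equal(nrow(subtract_controls(case, list(case))), 0)
})

test_that("corroboration keeps reads only when every junction recurs", {
  mk <- function(id, shift = 0L, extra = FALSE) {
    j <- extract_junctions(aln2("c", 0L, 5000L + shift, "+", "c",
                                50000L + shift, 55000L, "+", id = id))
    if (extra) j <- rbind(j, extract_junctions(
      aln2("c", 0L, 7000L, "+", "chrY", 100L, 4100L, "+", id = id)))
    j
  }
  three <- rbind(mk("a"), mk("b", 20L), mk("c", 40L))
  expect_equal(nrow(require_corroboration(three, min_support = 2)), 3)

  lone <- extract_junctions(aln2("q", 0L, 900L, "+", "chrM", 10L, 910L, "+", id = "lone"))
  expect_equal(nrow(require_corroboration(rbind(three, lone), min_support = 2)), 3)

  # a read with one shared and one sporadic junction is dropped entirely...
  mixed <- rbind(mk("a"), mk("b", 20L), mk("m", 40L, extra = TRUE))
  strict <- require_corroboration(mixed, min_support = 2)
  expect_setequal(unique(strict$read_id), c("a", "b"))
  # ...unless per-junction mode is chosen
  perj <- require_corroboration(mixed, min_support = 2, mode = "per-junction")
  expect_true("m" %in% perj$read_id)
  expect_equal(sum(perj$read_id == "m"), 1)
})

test_that("grouping is a deterministic partition honoring min_group", {
  mk <- function(id, shift) extract_junctions(
    aln2("c", 0L, 5000L + shift, "+", "c", 50000L + shift, 55000L, "+", id = id))
  jj <- rbind(mk("a", 0L), mk("b", 15L), mk("c", 30L))
  g3 <- group_reads(jj, min_group = 3L)
  expect_length(g3, 1)
  expect_setequal(g3[[1]]$read_ids, c("a", "b", "c"))
  expect_equal(g3[[1]]$junction_clusters$n_reads, 3)

  g2 <- group_reads(rbind(mk("a", 0L), mk("b", 15L)), min_group = 3L)
  expect_length(g2, 0)

  # two independent rearrangements -> two groups; each read in exactly one
  far <- function(id, shift) extract_junctions(
    aln2("c", 100000L, 105000L + shift, "+", "chrX", 7000L + shift, 12000L, "+", id = id))
  jj2 <- rbind(jj, far("x", 0L), far("y", 10L), far("z", 20L))
  gg <- group_reads(jj2, min_group = 3L)
  expect_length(gg, 2)
  members <- unlist(lapply(gg, `[[`, "read_ids"))
  expect_equal(sort(members), sort(unique(jj2$read_id)))
  # determinism
  gg2 <- group_reads(jj2[sample(nrow(jj2)), ], min_group = 3L)
  expect_equal(lapply(gg, `[[`, "read_ids"), lapply(gg2, `[[`, "read_ids"))
})

test_that("simulated cohorts: shared rearrangements subtract, case-only survive", {
  g <- make_reference(c(chrA = 80000L, chrB = 80000L), seed = 17)
  shared_op <- op_deletion("chrA", 10000L, 30000L)
  case_op <- op_reciprocal_translocation("chrA", 60000L, "chrB", 40000L)
  case <- apply_rearrangements(g, list(shared_op, case_op), seed = 1)
  case_j <- case$truth$junctions
  case_j$read_id <- paste0("case_", seq_len(nrow(case_j)))
  # triplicate each case junction so corroboration/grouping pass
  case_j <- do.call(rbind, lapply(1:3, function(i) {
    x <- case_j; x$read_id <- paste0(x$read_id, "_", i); x
  }))
  controls <- make_control_cohort(g, list(list(op = shared_op, freq = 1)),
                                  n = 4, seed = 3)
  surv <- subtract_controls(case_j, lapply(controls, `[[`, "junctions"))
  expect_true(all(surv$kind == "interchromosomal"))
  expect_equal(length(unique(surv$read_id)), 6) # 2 translocation junctions x 3
  # the two reciprocal-translocation junctions form two groups
  groups <- filter_and_group(case_j, lapply(controls, `[[`, "junctions"))
  expect_length(groups, 2)
})

test_that("adding controls never increases the number of surviving groups", {
  g <- make_reference(c(chrA = 100000L), seed = 23)
  ops <- lapply(seq(5000, 85000, by = 10000), function(s)
    list(op = op_deletion("chrA", s, s + 8000L), freq = 0.5))
  set.seed(99)
  case_ops <- lapply(ops[runif(length(ops)) < 0.7], `[[`, "op")
  case <- apply_rearrangements(g, case_ops, seed = 2)
  cj <- case$truth$junctions
  cj <- do.call(rbind, lapply(1:3, function(i) {
    x <- cj; x$read_id <- sprintf("c%d_%d", seq_len(nrow(cj)), i); x
  }))
  cohort <- make_control_cohort(g, ops, n = 8, seed = 7)
  counts <- vapply(0:8, function(k) {
    length(filter_and_group(cj, lapply(cohort[seq_len(k)], `[[`, "junctions")))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})
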