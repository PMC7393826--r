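test_that("geometric categories follow the decision rules", {
  td <- classify_group(chain_of("t", list("chrA", 0L, 5000L, "+"),
                                list("chrA", 3000L, 8000L, "+")))
  expect_equal(td$category, "tandem_multiplication")
  expect_equal(td$copy_count, 2L)

  tri <- classify_group(chain_of("t3", list("chrA", 0L, 5000L, "+"),
                                 list("chrA", 2000L, 5000L, "+"),
                                 list("chrA", 2000L, 6000L, "+")))
  expect_equal(tri$category, "tandem_multiplication")
  expect_equal(tri$copy_count, 3L)

  del <- classify_group(chain_of("d", list("chrA", 0L, 5000L, "+"),
                                 list("chrA", 20000L, 25000L, "+")))
  expect_equal(del$category, "deletion")

  inv <- classify_group(chain_of("i", list("chrA", 0L, 5000L, "+"),
                                 list("chrA", 5000L, 8000L, "-"),
                                 list("chrA", 8000L, 12000L, "+")))
  expect_equal(inv$category, "inversion")

  dup <- classify_group(chain_of("nd", list("chrA", 0L, 5000L, "+"),
                                 list("chrA", 2000L, 3000L, "+"),
                                 list("chrA", 5000L, 9000L, "+")))
  expect_equal(dup$category, "non_tandem_duplication")

  ins <- classify_group(chain_of("ie", list("chrA", 0L, 5000L, "+"),
                                 list("chrB", 40000L, 40300L, "+"),
                                 list("chrA", 5000L, 9000L, "+")))
  expect_equal(ins$category, "insertion_from_elsewhere")

  far <- classify_group(chain_of("if", list("chrA", 0L, 5000L, "+"),
                                 list("chrA", 8e6, 8000300L, "+"),
                                 list("chrA", 5000L, 9000L, "+")))
  expect_equal(far$category, "insertion_from_elsewhere")

  tr <- classify_group(chain_of("tr", list("chr2", 0L, 5000L, "+"),
                                list("chrX", 9000L, 14000L, "+")))
  expect_equal(tr$category, "interchromosomal_translocation")

  cx <- classify_group(chain_of("cx", list("chrA", 0L, 5000L, "+"),
                                list("chrB", 9000L, 14000L, "-"),
                                list("chrC", 0L, 2000L, "+")))
  expect_equal(cx$category, "complex")

  expect_equal(classify_group(chain_of("u", list("chrA", 0L, 5000L, "+")))$category,
               "unclassified")
})

test_that("insertion sources are annotated: repeat family, NUMT, pseudogene", {
  ins <- chain_of("ie", list("chr10", 0L, 5000L, "+"),
                  list("chr20", 40000L, 40300L, "+"),
                  list("chr10", 5012L, 9000L, "+"))
  ann <- data.frame(chrom = "chr20", start = 39950L, end = 40350L,
                    label = "AluYa5", stringsAsFactors = FALSE)
  expect_equal(annotate_insertion_source(ins, ann), "AluYa5")
  expect_true(is.na(annotate_insertion_source(ins, NULL)))
  # <50% overlap: no label
  ann2 <- data.frame(chrom = "chr20", start = 40200L, end = 40300L, label = "L1HS")
  expect_true(is.na(annotate_insertion_source(ins, ann2)))

  numt <- chain_of("numt", list("chr2", 0L, 5000L, "+"),
                   list("chrM", 3000L, 4000L, "+"),
                   list("chr2", 5000L, 9000L, "+"))
  expect_equal(annotate_insertion_source(numt, ann), "NUMT")

  # intron-loss pattern: exons from one chromosome, in order, gaps >= min_gap
  pg <- chain_of("pg", list("chr15", 0L, 5000L, "+"),
                 list("chr2", 100000L, 100200L, "+"),
                 list("chr2", 130000L, 130150L, "+"),
                 list("chr2", 170000L, 170250L, "+"),
                 list("chr15", 5000L, 9000L, "+"))
  expect_equal(annotate_insertion_source(pg, NULL), "processed_pseudogene")
})

test_that("summaries count every group once", {
  types <- c(replicate(3, classify_group(chain_of("t", list("c", 0L, 5000L, "+"),
                                                  list("c", 3000L, 8000L, "+"))),
                       simplify = FALSE),
             replicate(2, classify_group(chain_of("d", list("c", 0L, 5000L, "+"),
                                                  list("c", 20000L, 25000L, "+"))),
                       simplify = FALSE))
  tab <- summarize_rearrangements(types)
  expect_equal(sum(tab$n), 5)
  expect_equal(tab$n[tab$category == "tandem_multiplication"], 3)
  expect_equal(tab$n[tab$category == "deletion"], 2)
  expect_equal(nrow(summarize_rearrangements(list())), 0)
})

test_that("dotplot tracks carry segments and the two guide-line sets", {
  ident <- dotplot_data(seg_df("r", 0L, 1000L, 1000L, "c", 0L, 1000L, "+"))
  expect_equal(nrow(ident$segments), 1)
  expect_equal(nrow(ident$derived_joins), 0)
  expect_equal(nrow(ident$reference_joins), 0)

  # balanced translocation derivative: derived joins link the two parts
  der <- chain_of("der", list("chrA", 0L, 20000L, "+"), list("chrB", 30000L, 50000L, "+"))
  tr <- dotplot_data(der)
  expect_equal(nrow(tr$segments), 2)
  expect_equal(nrow(tr$derived_joins), 1)

  # chromothripsis: reference-adjacency joins tile the shattered interval
  g <- make_reference(c(chrA = 100000L), seed = 3)
  opc <- op_chromothripsis("chrA", 20000L, 80000L, n_fragments = 6,
                           dropped = integer(0),
                           permutation = c(4, 2, 6, 1, 3, 5),
                           orientations = rep("+", 6))
  der2 <- apply_rearrangements(g, list(opc), seed = 1)
  track <- dotplot_data(build_chain(der2$truth$structures$chrA, "derA"))
  # nothing dropped: all 5 internal boundaries plus both flank boundaries
  # abut on the reference
  expect_equal(nrow(track$reference_joins), 7)
})

test_that("categories are recovered end-to-end at zero read error for each operation", {
  specs <- list(
    list(op = op_deletion("chrA", 20000L, 34000L), cat = "deletion"),
    list(op = op_inversion("chrA", 20000L, 30000L), cat = "inversion"),
    list(op = op_tandem_multiplication("chrA", 20000L, 24000L, 2L),
         cat = "tandem_multiplication"),
    list(op = op_insertion_copy("chrB", 10000L, 10400L, "+", "chrA", 20000L, 12L),
         cat = "insertion_from_elsewhere"),
    list(op = op_reciprocal_translocation("chrA", 20000L, "chrB", 30000L),
         cat = "interchromosomal_translocation"))
  g <- make_reference(c(chrA = 60000L, chrB = 60000L), seed = 19)
  idx <- genome_index(g)
  for (k in seq_along(specs)) {
    der <- apply_rearrangements(g, list(specs[[k]]$op), seed = k)
    rr <- simulate_reads(der$derived, coverage = 12,
                         length_law = list(mean = 26000, sd = 0.1, min = 18000),
                         model = exact_error_model(), seed = 100 + k)
    pl <- run_pipeline(rr$reads, idx, model = exact_error_model(),
                       min_gap = 10000L, link = FALSE, consensus = FALSE,
                       refine_breakpoints = FALSE)
    cats <- unique(vapply(pl$groups, function(grp) {
      reads_in <- pl$segments[pl$segments$read_id %in% grp$read_ids, ]
      spans <- tapply(reads_in$read_end - reads_in$read_start, reads_in$read_id, sum)
      best <- names(which.max(spans))
      classify_group(build_chain(reads_in[reads_in$read_id == best, ]))$category
    }, ""))
    expect_true(specs[[k]]$cat %in% cats, info = specs[[k]]$cat)
    if (specs[[k]]$cat != "interchromosomal_translocation") {
      expect_length(pl$groups, 1)
    }
  }
})
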