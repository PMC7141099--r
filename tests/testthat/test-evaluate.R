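mk_truth <- function(starts, strand = "+",
                     outcome = "retained", contig = "chr") {
  n <- length(starts)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             class_label = "CNL", contig = contig,
             nbarc_start = as.integer(starts),
             nbarc_end = as.integer(starts + 900L),
             gene_start = as.integer(starts - 100L),
             gene_end = as.integer(starts + 1200L),
             strand = rep_len(strand, n),
             expected_outcome = rep_len(outcome, n),
             stringsAsFactors = FALSE)
}

mk_cand <- function(starts, ends, strand = "+", contig = "chr") {
  n <- length(starts)
  data.frame(locus_id = sprintf("L%02d", seq_len(n)),
             contig = rep_len(contig, n), start = as.integer(starts),
             end = as.integer(ends), strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

test_that("perfect predictions give sensitivity 1 and no extras", {
  tr <- mk_truth(c(1000L, 20000L, 50000L))
  ev <- evaluate_candidates(mk_cand(tr$nbarc_start, tr$nbarc_end), tr)
  expect_identical(ev$n_found, 3L)
  expect_equal(ev$sensitivity, 1)
  expect_identical(length(ev$false_negatives), 0L)
  expect_identical(length(ev$extra_candidates), 0L)
  expect_identical(ev$tp + length(ev$false_negatives), 3L)
})

test_that("empty and non-overlapping predictions give sensitivity 0", {
  tr <- mk_truth(c(1000L, 20000L))
  ev0 <- evaluate_candidates(mk_cand(integer(0), integer(0)), tr)
  expect_equal(ev0$sensitivity, 0)
  expect_identical(ev0$false_negatives, c("g01", "g02"))
  shifted <- mk_cand(tr$nbarc_end + 10L, tr$nbarc_end + 500L)
  evs <- evaluate_candidates(shifted, tr)
  expect_equal(evs$sensitivity, 0)
  expect_identical(length(evs$extra_candidates), 2L)
})

test_that("matching requires the same strand and is one-to-one", {
  tr <- mk_truth(1000L)
  wrong <- mk_cand(1000L, 1900L, strand = "-")
  expect_equal(evaluate_candidates(wrong, tr)$sensitivity, 0)
  # two candidates over one gene: one match, one extra
  two <- mk_cand(c(1000L, 1200L), c(1900L, 2100L))
  ev <- evaluate_candidates(two, tr)
  expect_identical(ev$n_found, 1L)
  expect_identical(length(ev$extra_candidates), 1L)
  # greedy by overlap: the first candidate overlaps more and wins
  expect_identical(ev$matches$locus_id, "L01")
})

test_that("sensitivity denominator is the expected-retained subset", {
  tr <- rbind(mk_truth(c(1000L, 20000L)),
              mk_truth(50000L, outcome = "dropped_lrr"))
  ev <- evaluate_candidates(mk_cand(1000L, 1900L), tr)
  expect_identical(ev$n_expected, 2L)
  expect_equal(ev$sensitivity, 0.5)
  bo <- ev$by_outcome
  expect_identical(bo$n_detected[bo$expected_outcome == "dropped_lrr"], 0L)
})

test_that("evaluation is invariant to candidate row order", {
  tr <- mk_truth(c(1000L, 20000L, 50000L))
  cand <- mk_cand(tr$nbarc_start + c(-50L, 100L, 40L), tr$nbarc_end)
  ev1 <- evaluate_candidates(cand, tr)
  ev2 <- evaluate_candidates(cand[3:1, ], tr)
  expect_identical(ev1$n_found, ev2$n_found)
  expect_identical(sort(ev1$matches$gene_id), sort(ev2$matches$gene_id))
})

test_that("contig mismatch is reported as a join error", {
  tr <- mk_truth(1000L)
  expect_error(
    evaluate_candidates(mk_cand(1000L, 1900L, contig = "other"), tr),
    "contig")
})

test_that("evaluate_files agrees between GFF3 and TSV truth inputs", {
  sim <- small_test_sim()
  d <- tempfile()
  write_simulation(sim, d)
  bed <- file.path(d, "pred.bed")
  tr <- sim$truth
  keep <- tr$expected_outcome == "retained"
  write_bed(bed_intervals(tr$contig[keep], tr$nbarc_start[keep],
                          tr$nbarc_end[keep], name = "p1",
                          strand = tr$strand[keep]), bed)
  out1 <- file.path(d, "eval_gff.tsv")
  out2 <- file.path(d, "eval_tsv.tsv")
  ev1 <- evaluate_files(bed, file.path(d, "truth.gff3"), out1)
  ev2 <- evaluate_files(bed, file.path(d, "truth.tsv"), out2)
  expect_identical(ev1$n_found, ev2$n_found)
  expect_identical(readLines(out1), readLines(out2))
  tab <- read.table(out1, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(tab$value[tab$metric == "sensitivity"], 1)
  expect_equal(tab$value[tab$metric == "n_truth"], 3)
})
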