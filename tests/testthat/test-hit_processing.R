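# minimal hit-row factory with the columns the processing stage uses
mk_hits <- function(g_start, g_end, score = 100, query_id = "q",
                    contig = "c1", strand = "+", frame = 1L,
                    q_start = 0L, q_end = NULL) {
  n <- length(g_start)
  if (is.null(q_end)) q_end <- pmax(1L, (g_end - g_start) %/% 3L)
  data.frame(contig = rep_len(contig, n), g_start = as.integer(g_start),
             g_end = as.integer(g_end), strand = rep_len(strand, n),
             frame = rep_len(as.integer(frame), n),
             query_id = rep_len(query_id, n),
             q_start = rep_len(as.integer(q_start), n),
             q_end = as.integer(rep_len(q_end, n)),
             score = rep_len(score, n), stringsAsFactors = FALSE)
}

test_that("merge_overlapping equals the per-base oracle", {
  set.seed(201)
  for (rep in 1:30) {
    n <- sample(1:25, 1)
    st <- sample(0:3000, n, replace = TRUE)
    en <- st + sample(10:400, n, replace = TRUE)
    blocks <- merge_overlapping(mk_hits(st, en, score = runif(n, 50, 500)))
    oracle <- oracle_merge(st, en)
    expect_identical(cbind(start = blocks$start, end = blocks$end),
                     cbind(start = as.integer(oracle[, "start"]),
                           end = as.integer(oracle[, "end"])))
  }
})

test_that("merging respects contig and strand boundaries", {
  h <- rbind(mk_hits(0, 100, strand = "+"), mk_hits(50, 150, strand = "-"),
             mk_hits(60, 160, contig = "c2"))
  b <- merge_overlapping(h)
  expect_identical(nrow(b), 3L) # no cross-strand or cross-contig merging
})

test_that("block metadata tracks the best hit", {
  h <- rbind(mk_hits(0, 100, score = 50, query_id = "a"),
             mk_hits(50, 150, score = 80, query_id = "b", frame = 2L))
  b <- merge_overlapping(h)
  expect_identical(nrow(b), 1L)
  expect_identical(b$best_query_id, "b")
  expect_identical(b$best_frame, 2L)
  expect_identical(b$n_hits, 2L)
})

test_that("chain_adjacent matches the worked example and the oracle", {
  st <- c(0L, 800L, 2600L)
  en <- c(300L, 1100L, 2900L)
  loci <- chain_adjacent(merge_overlapping(mk_hits(st, en)),
                         max_gap = 1000L)
  # gaps are 500 and 1500: the first two blocks chain, the third does not
  expect_identical(nrow(loci), 2L)
  expect_identical(loci$start, c(0L, 2600L))
  expect_identical(loci$end, c(1100L, 2900L))
  expect_identical(loci$n_segments, c(2L, 1L))
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(1:15, 1)
    s <- sort(sample(0:20000, n))
    e <- s + sample(20:900, n, replace = TRUE)
    gap <- sample(c(0L, 100L, 1000L), 1)
    got <- chain_adjacent(merge_overlapping(mk_hits(s, e)), max_gap = gap)
    want <- oracle_chain(s, e, gap)
    expect_identical(cbind(start = got$start, end = got$end),
                     cbind(start = as.integer(want[, "start"]),
                           end = as.integer(want[, "end"])))
  }
})

test_that("a locus chained across a small gap sums its segment scores", {
  h <- rbind(mk_hits(0, 300, score = 120), mk_hits(700, 1000, score = 80))
  loci <- chain_adjacent(merge_overlapping(h), max_gap = 1000L)
  expect_identical(loci$score, 200)
  seg <- loci$segments[[1]]
  expect_identical(seg[, "start"], c(0L, 700L))
  expect_identical(seg[, "end"], c(300L, 1000L))
})

test_that("length filter is strictly greater than min_len_frac", {
  mk <- function(q_start, q_end) {
    h <- mk_hits(0, 3 * (q_end - q_start), q_start = q_start, q_end = q_end)
    chain_adjacent(merge_overlapping(h), 1000L)
  }
  lens <- c(q = 100)
  expect_identical(nrow(length_filter(mk(0L, 80L), lens)), 0L)  # 0.80: out
  expect_identical(nrow(length_filter(mk(0L, 81L), lens)), 1L)  # 0.81: in
  all80 <- length_filter(mk(0L, 80L), lens, return_all = TRUE)
  expect_identical(all80$coverage, 0.8)
  expect_false(all80$retained)
})

test_that("query coverage counts overlapping query residues once", {
  # two hits covering query [0,60) and [40,90): union 90 of 100 -> retained
  h <- rbind(mk_hits(0, 180, q_start = 0L, q_end = 60L),
             mk_hits(2000, 2150, q_start = 40L, q_end = 90L))
  loci <- length_filter(chain_adjacent(merge_overlapping(h), 5000L),
                        c(q = 100), return_all = TRUE)
  expect_identical(loci$aligned_len, 90L)
  # two hits both covering [0,60): union 60 -> dropped despite 120 columns
  h2 <- rbind(mk_hits(0, 180, q_start = 0L, q_end = 60L),
              mk_hits(2000, 2180, q_start = 0L, q_end = 60L))
  loci2 <- length_filter(chain_adjacent(merge_overlapping(h2), 5000L),
                         c(q = 100), return_all = TRUE)
  expect_identical(loci2$aligned_len, 60L)
  expect_false(loci2$retained)
})

test_that("length filter rejects unknown query ids", {
  loci <- chain_adjacent(merge_overlapping(mk_hits(0, 300)), 1000L)
  expect_error(length_filter(loci, c(other = 100)), "unknown query id")
})

test_that("empty inputs flow through the stack", {
  b <- merge_overlapping(nlrsweep:::.empty_hits())
  expect_identical(nrow(b), 0L)
  l <- chain_adjacent(b, 1000L)
  expect_identical(nrow(l), 0L)
  expect_identical(nrow(length_filter(l, c(q = 10))), 0L)
  expect_error(chain_adjacent(b, -1L), "max_gap")
})
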