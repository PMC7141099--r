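test_that("full-DP search scores match the Biostrings oracle exactly", {
  set.seed(101)
  smat <- nlrsweep:::.submat128("BLOSUM62")
  for (i in 1:40) {
    pr <- seeded_pair(60L)
    df <- nlrsweep:::cpp_search(pr$q, pr$s, smat, 11, 1, 30L, 60, 1, 4L,
                                1L, TRUE, 25L)
    expect_gt(nrow(df), 0)
    expect_equal(max(df$score), oracle_local_score(pr$q, pr$s))
  }
})

test_that("seeded search equals full DP in the planted-core regime", {
  set.seed(102)
  smat <- nlrsweep:::.submat128("BLOSUM62")
  for (i in 1:40) {
    pr <- seeded_pair(60L)
    seeded <- nlrsweep:::cpp_search(pr$q, pr$s, smat, 11, 1, 30L, 60, 1, 4L,
                                    1L, FALSE, 25L)
    expect_gt(nrow(seeded), 0)
    expect_equal(max(seeded$score), oracle_local_score(pr$q, pr$s))
  }
})

test_that("X-drop splits alignments bridged by a junk segment", {
  set.seed(103)
  smat <- nlrsweep:::.submat128("BLOSUM62")
  core1 <- random_peptide(40L)
  core2 <- random_peptide(40L)
  # the junk segments are mutually dissimilar by construction: every
  # D-vs-K column scores -1 under BLOSUM62, so bridging the 80-column
  # junk accumulates a deficit of 80
  q <- paste0(core1, strrep("D", 80L), core2)
  s <- paste0(core1, strrep("K", 80L), core2)
  # with pruning disabled (huge x_drop) one alignment spans both cores
  loose <- nlrsweep:::cpp_search(q, s, smat, 11, 1, 30L, 1e6, 1, 4L, 1L,
                                 TRUE, 25L)
  expect_true(any(loose$q_start < 40 & loose$q_end > 120))
  # with the default x_drop = 60 the bridge is pruned and the two cores
  # come back as separate hits
  strict <- nlrsweep:::cpp_search(q, s, smat, 11, 1, 30L, 60, 1, 4L, 1L,
                                  TRUE, 25L)
  expect_false(any(strict$q_start < 40 & strict$q_end > 120))
  expect_true(any(strict$q_end <= 45))    # first-core hit
  expect_true(any(strict$q_start >= 115)) # second-core hit
})

test_that("search_genome reports hits on both strands in genomic coords", {
  set.seed(104)
  pep <- random_peptide(60L)
  dna <- reverse_translate(pep, seed = 5L)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  fwd <- paste0(pad(301), dna, pad(200))
  rev <- paste0(pad(200), nlrsweep:::.revcomp_chr(dna), pad(301))
  genome <- Biostrings::DNAStringSet(c(cF = fwd, cR = rev))
  hits <- search_genome(c(q = pep), genome,
                        search_params(min_hit_score = 50))
  hf <- hits[hits$contig == "cF", ]
  hr <- hits[hits$contig == "cR", ]
  expect_gt(nrow(hf), 0)
  expect_gt(nrow(hr), 0)
  expect_true(all(hf$strand == "+"))
  expect_true(all(hr$strand == "-"))
  # the genomic interval of the best hit re-translates to the query
  best <- hf[which.max(hf$score), ]
  sub <- substr(fwd, best$g_start + 1L, best$g_end)
  expect_identical(nlrsweep:::.translate_chr(sub), pep)
  bestr <- hr[which.max(hr$score), ]
  subr <- nlrsweep:::.revcomp_chr(substr(rev, bestr$g_start + 1L,
                                         bestr$g_end))
  expect_identical(nlrsweep:::.translate_chr(subr), pep)
})

test_that("identity and score thresholds filter hits", {
  set.seed(105)
  pep <- random_peptide(60L)
  genome <- Biostrings::DNAStringSet(c(c1 = reverse_translate(pep, 6L)))
  strictp <- search_params(min_hit_score = 1e6)
  expect_identical(nrow(search_genome(c(q = pep), genome, strictp)), 0L)
  h <- search_genome(c(q = pep), genome, search_params(min_hit_score = 50))
  expect_true(all(h$identity >= 0.60))
  expect_true(all(h$identity == h$n_ident / h$aln_cols))
})

test_that("search input validation", {
  g <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTACGT"))
  expect_error(search_genome(Biostrings::AAStringSet(), g), "empty input")
  expect_error(search_genome(c(q = "MKV"), g[0]), "empty input")
  expect_error(search_genome(c(q = "MKU"), g), "alphabet")
  expect_error(search_params(gap_open = 0.5, gap_extend = 1))
  expect_error(search_params(x_drop = 0))
})

test_that("search results are deterministic", {
  set.seed(106)
  pep <- random_peptide(80L)
  pad <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(
    c(c1 = paste0(pad, reverse_translate(pep, 7L), pad)))
  h1 <- search_genome(c(q = pep), genome)
  h2 <- search_genome(c(q = pep), genome)
  expect_identical(h1, h2)
})
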