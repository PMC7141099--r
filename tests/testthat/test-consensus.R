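test_that("PSSM column scores match the hand formula", {
  msa <- structure(list(ids = paste0("s", 1:4),
                        rows = c("L", "L", "L", "I"), ncol = 1L,
                        centre = "s1"), class = "nlr_msa")
  p <- build_profile(msa, "CNL", pseudocount = 1)
  # counts: L=3, I=1, n=4, pseudocount 1, uniform background 0.05
  expect_equal(unname(p$scores[1, "L"]), log2((3 + 1 * 0.05) / (4 + 1) / 0.05))
  expect_equal(unname(p$scores[1, "L"]), log2(12.2))
  expect_equal(unname(p$scores[1, "I"]), log2((1 + 0.05) / 5 / 0.05))
  expect_equal(unname(p$scores[1, "A"]), log2((0 + 0.05) / 5 / 0.05))
  expect_identical(p$consensus, "L")
})

test_that("gap-heavy columns are dropped and gaps leave the count", {
  msa <- structure(list(ids = paste0("s", 1:4),
                        rows = c("LA", "L-", "L-", "L-"), ncol = 2L,
                        centre = "s1"), class = "nlr_msa")
  p <- build_profile(msa, "CNL", gap_col_frac = 0.5)
  expect_identical(p$ncol, 1L) # column 2 is 75% gaps -> dropped
  p2 <- build_profile(msa, "CNL", gap_col_frac = 0.8)
  expect_identical(p2$ncol, 2L)
  # column 2 non-gap count is 1 (the single A)
  expect_equal(unname(p2$scores[2, "A"]), log2((1 + 0.05) / (1 + 1) / 0.05))
  msa_all_gap <- structure(list(ids = c("a", "b"), rows = c("-", "-"),
                                ncol = 1L, centre = "a"),
                           class = "nlr_msa")
  expect_error(build_profile(msa_all_gap, "CNL"), "degenerate")
})

test_that("star alignment of identical sequences is trivial", {
  pep <- c(a = "MKVLIDGRETW", b = "MKVLIDGRETW", c = "MKVLIDGRETW")
  msa <- align_peptides(Biostrings::AAStringSet(pep))
  expect_identical(unique(msa$rows), "MKVLIDGRETW")
  expect_identical(msa$ncol, 11L)
})

test_that("star alignment degaps back to the input sequences", {
  set.seed(301)
  base <- random_peptide(60L)
  vars <- vapply(1:4, function(i) mutate_peptide(base, 0.85, i),
                 character(1))
  vars[2] <- paste0(substr(vars[2], 1, 30), "AAG", substr(vars[2], 31, 60))
  pep <- setNames(vars, paste0("p", 1:4))
  msa <- align_peptides(Biostrings::AAStringSet(pep))
  expect_identical(length(unique(nchar(msa$rows))), 1L)
  degapped <- gsub("-", "", msa$rows)
  expect_setequal(degapped, unname(pep))
})

test_that("pairwise identity in the MSA reflects the inputs", {
  set.seed(302)
  base <- random_peptide(80L)
  pep <- setNames(c(base, mutate_peptide(base, 0.9, 1)), c("a", "b"))
  msa <- align_peptides(Biostrings::AAStringSet(pep))
  a <- strsplit(msa$rows[1], "")[[1]]
  b <- strsplit(msa$rows[2], "")[[1]]
  expect_gt(mean(a == b), 0.85)
})

test_that("build_class_profiles falls back below the class-size floor", {
  set.seed(303)
  base <- random_peptide(60L)
  pep <- Biostrings::AAStringSet(c(
    a = mutate_peptide(base, 0.9, 1), b = mutate_peptide(base, 0.9, 2),
    c = mutate_peptide(base, 0.9, 3)))
  out <- build_class_profiles(pep, c("CNL", "CNL", "TNL"),
                              min_class_size = 2L)
  expect_identical(names(out$profiles), "CNL")
  expect_identical(out$fallback_classes, "TNL")
  expect_identical(out$profiles$CNL$n_sequences, 2L)
})

test_that("profile_score is the consensus self-score on the consensus", {
  msa <- structure(list(ids = c("a", "b"),
                        rows = c("MKVLID", "MKVLID"), ncol = 6L,
                        centre = "a"), class = "nlr_msa")
  p <- build_profile(msa, "CNL")
  expect_equal(profile_score(p, p$consensus),
               sum(apply(p$scores, 1, max)))
  expect_identical(profile_score(p, "GGGGGG"), 0)
})

test_that("candidate peptides extract phase-correct on both strands", {
  set.seed(304)
  pep <- random_peptide(70L)
  dna <- reverse_translate(pep, seed = 9L)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  genome <- Biostrings::DNAStringSet(c(
    cF = paste0(pad(1001), dna, pad(500)),
    cR = paste0(pad(500), nlrsweep:::.revcomp_chr(dna), pad(1001))))
  hits <- search_genome(c(q = pep), genome,
                        search_params(min_hit_score = 50))
  loci <- chain_adjacent(merge_overlapping(hits), 1000L)
  expect_identical(nrow(loci), 2L)
  out <- extract_candidate_peptides(loci, genome)
  expect_identical(unname(as.character(out)), c(pep, pep))
})

test_that("write_profiles emits FASTA and a readable matrix", {
  msa <- structure(list(ids = c("a", "b"), rows = c("MKV", "MKV"),
                        ncol = 3L, centre = "a"), class = "nlr_msa")
  p <- build_profile(msa, "CNL")
  d <- tempfile()
  write_profiles(list(CNL = p), d)
  expect_true(file.exists(file.path(d, "CNL.fa")))
  tab <- read.table(file.path(d, "CNL.pssm"), comment.char = "#")
  expect_identical(dim(tab), c(3L, 20L))
  expect_equal(unname(as.matrix(tab)), unname(round(p$scores, 4)),
               tolerance = 1e-6)
})
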