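test_that("mutate_peptide hits the identity target with substitutions only", {
  set.seed(501)
  for (target in c(0.6, 0.75, 0.9)) {
    pep <- random_peptide(280L)
    mut <- mutate_peptide(pep, target, seed = 17L)
    expect_identical(nchar(mut), nchar(pep))
    a <- strsplit(pep, "")[[1]]
    b <- strsplit(mut, "")[[1]]
    expect_lt(abs(mean(a == b) - target), 0.01)
  }
  pep <- random_peptide(40L)
  expect_identical(mutate_peptide(pep, 1, seed = 1L), pep)
})

test_that("mutate_peptide protects requested positions", {
  pep <- paste(rep("LAGE", 10), collapse = "")
  mut <- mutate_peptide(pep, 0.5, seed = 2L, protect = seq(0L, 36L, by = 4L))
  b <- strsplit(mut, "")[[1]]
  expect_true(all(b[seq(1L, 37L, by = 4L)] == "L"))
})

test_that("reverse_translate round-trips through translation", {
  set.seed(502)
  pep <- random_peptide(120L)
  dna <- reverse_translate(pep, seed = 3L)
  expect_identical(nchar(dna), 3L * nchar(pep))
  expect_identical(nlrsweep:::.translate_chr(dna), pep)
  # different seeds give different codon choices for the same peptide
  expect_false(identical(dna, reverse_translate(pep, seed = 4L)))
})

test_that("build_gene intron arithmetic and truncation are exact", {
  ref <- reference_peptides()
  plain <- build_gene(gene_spec("NL", names(ref)[1]), ref, seed = 5L)
  nb <- plain$features$nbarc
  reflen <- Biostrings::width(ref)[1]
  expect_identical(nb[2] - nb[1], 3L * reflen)
  with_intron <- build_gene(
    gene_spec("NL", names(ref)[1],
              introns = data.frame(codon = 100L, size = 543L)),
    ref, seed = 5L)
  nbi <- with_intron$features$nbarc
  expect_identical(nbi[2] - nbi[1], 3L * reflen + 543L)
  # GT..AG splice dinucleotides at the recorded codon boundary
  intron_start <- nbi[1] + 3L * 100L
  dna <- with_intron$dna
  expect_identical(substr(dna, intron_start + 1L, intron_start + 2L), "GT")
  expect_identical(substr(dna, intron_start + 542L, intron_start + 543L),
                   "AG")
  trunc <- build_gene(
    gene_spec("NL", names(ref)[1], truncation_frac = 0.5), ref, seed = 5L)
  nbt <- trunc$features$nbarc
  expect_identical(nbt[2] - nbt[1], 3L * as.integer(ceiling(0.5 * reflen)))
})

test_that("class-specific N-terminal domains are encoded upstream", {
  ref <- reference_peptides()
  src <- names(ref)[1]
  for (cl in c("CNL", "TNL", "RNL", "NL")) {
    g <- build_gene(gene_spec(cl, src), ref, seed = 6L)
    pep <- nlrsweep:::.translate_chr(
      substr(g$dna, 1L, g$features$nbarc[1]))
    calls <- detect_nterm_domains(pep)
    expect_identical(classify_nlr(unique(calls$kind)), cl, info = cl)
  }
})

test_that("expected_outcome maps specs to archetypes", {
  ref_id <- names(reference_peptides())[1]
  expect_identical(expected_outcome(gene_spec("CNL", ref_id)), "retained")
  expect_identical(
    expected_outcome(gene_spec("CNL", ref_id, truncation_frac = 0.7)),
    "dropped_length")
  expect_identical(
    expected_outcome(gene_spec("NL", ref_id, has_lrr = FALSE)),
    "dropped_lrr")
  expect_identical(
    expected_outcome(gene_spec("CNL", ref_id,
                               introns = data.frame(codon = 100L,
                                                    size = 1500L))),
    "dropped_split")
  # an intron at the chaining limit does not split
  expect_identical(
    expected_outcome(gene_spec("CNL", ref_id,
                               introns = data.frame(codon = 100L,
                                                    size = 1000L))),
    "retained")
})

test_that("generate_genome is deterministic and truth matches the DNA", {
  s1 <- small_test_sim()
  s2 <- small_test_sim()
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  tr <- s1$truth
  expect_identical(nrow(tr), 3L)
  expect_identical(tr$expected_outcome,
                   c("retained", "dropped_length", "dropped_lrr"))
  # the recorded NB-ARC of the minus-strand gene re-translates to ~90%
  # identity with its reference source
  g <- as.character(s1$genome[[1]])
  i <- 2L
  sub <- substr(g, tr$nbarc_start[i] + 1L, tr$nbarc_end[i])
  if (tr$strand[i] == "-") sub <- nlrsweep:::.revcomp_chr(sub)
  pep <- nlrsweep:::.translate_chr(sub)
  ref <- as.character(reference_peptides()[["ref_TNL_1"]])
  ref_trunc <- substr(ref, 1L, nchar(pep))
  a <- strsplit(pep, "")[[1]]
  b <- strsplit(ref_trunc, "")[[1]]
  expect_gt(mean(a == b), 0.85)
})

test_that("simulation files round-trip: FASTA, GFF3 offsets, specs.yaml", {
  sim <- small_test_sim()
  d <- tempfile()
  write_simulation(sim, d)
  expect_true(all(file.exists(file.path(
    d, c("genome.fa", "truth.gff3", "truth.tsv", "specs.yaml")))))
  g2 <- read_fasta(file.path(d, "genome.fa"), type = "DNA")
  expect_identical(as.character(g2), as.character(sim$genome))
  tsv <- read.table(file.path(d, "truth.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_identical(tsv$nbarc_start, sim$truth$nbarc_start)
  gff <- readLines(file.path(d, "truth.gff3"))
  gene1 <- strsplit(grep("\tgene\t", gff, value = TRUE)[1], "\t")[[1]]
  expect_identical(as.integer(gene1[4]), sim$truth$gene_start[1] + 1L)
  expect_identical(as.integer(gene1[5]), sim$truth$gene_end[1])
  y <- yaml::read_yaml(file.path(d, "specs.yaml"))
  expect_identical(length(y$specs), 3L)
  expect_identical(y$specs[[1]]$class_label, "CNL")
})
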