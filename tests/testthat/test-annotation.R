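test_that("classify_nlr covers the full truth table", {
  expect_identical(classify_nlr(c("TIR", "RPW8", "CC")), "TNL")
  expect_identical(classify_nlr(c("TIR", "RPW8")), "TNL")
  expect_identical(classify_nlr(c("TIR", "CC")), "TNL")
  expect_identical(classify_nlr("TIR"), "TNL")
  expect_identical(classify_nlr(c("RPW8", "CC")), "RNL")
  expect_identical(classify_nlr("RPW8"), "RNL")
  expect_identical(classify_nlr("CC"), "CNL")
  expect_identical(classify_nlr(character(0)), "NL")
})

test_that("the canonical LRR motif matches its textbook example", {
  d <- detect_lrr("LSELDLSNNKL", min_repeats = 1L)
  expect_identical(d$motifs, 0L)
  expect_identical(unname(d$domains[1, ]), c(0L, 11L))
})

test_that("LRR domains need clustered repeats inside a stop-free stretch", {
  unit <- "LTELDLSYNQLSGEIPASLGQLKN"
  two <- paste0(unit, unit)
  expect_gt(nrow(detect_lrr(two, min_repeats = 2L)$domains), 0)
  expect_identical(nrow(detect_lrr(unit, min_repeats = 2L)$domains), 0L)
  # the same two copies split by a stop codon never cluster
  split <- paste0(unit, "*", unit)
  expect_identical(nrow(detect_lrr(split, min_repeats = 2L)$domains), 0L)
  # and a motif can never span a stop
  broken <- "LSELD*LSNNKL"
  expect_identical(length(detect_lrr(broken, min_repeats = 1L)$motifs), 0L)
})

test_that("LRR clustering respects the window", {
  unit <- "LTELDLSYNQL"
  spacer <- paste(rep("G", 150), collapse = "")
  far <- paste0(unit, spacer, unit)
  expect_identical(nrow(detect_lrr(far, min_repeats = 2L,
                                   window = 120L)$domains), 0L)
  expect_gt(nrow(detect_lrr(far, min_repeats = 2L,
                            window = 200L)$domains), 0)
})

test_that("coiled-coil detector accepts amphipathic and rejects greasy", {
  ideal <- paste(rep("LEALEGK", 4), collapse = "")
  cc <- detect_coiled_coil(ideal)
  expect_identical(nrow(cc), 1L)
  expect_identical(unname(cc[1, ]), c(0L, 28L))
  # all-hydrophobic sequence satisfies a/d but fails the amphipathy cap
  greasy <- paste(rep("L", 28), collapse = "")
  expect_identical(nrow(detect_coiled_coil(greasy)), 0L)
  # a stop inside the window kills it
  stopped <- paste0(substr(ideal, 1, 10), "*", substr(ideal, 12, 28))
  expect_identical(nrow(detect_coiled_coil(stopped)), 0L)
  # one a/d position broken -> below min_frac 1 -> no call
  broken <- sub("^L", "E", ideal)
  weak <- detect_coiled_coil(broken)
  expect_identical(nrow(weak), 0L)
})

test_that("ORF finding reports ATG..stop spans on both strands", {
  set.seed(401)
  body <- reverse_translate(paste0("M", random_peptide(59L)), seed = 3L)
  orf <- paste0(body, "TAA") # 60 codons + stop
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  # place on the plus strand, then the same ORF reverse-complemented
  glue <- pad(90)
  dna <- paste0(glue, orf, pad(90), nlrsweep:::.revcomp_chr(orf), pad(90))
  genome <- Biostrings::DNAStringSet(c(c1 = dna))
  locus <- list(locus_id = "L1", contig = "c1", start = 100L, end = 150L)
  region <- extract_flanking(locus, genome, flank = 10000L)
  orfs <- find_orfs(region, min_aa = 50L)
  plus <- orfs[orfs$strand == "+", ]
  minus <- orfs[orfs$strand == "-", ]
  expect_gte(nrow(plus), 1L)
  expect_gte(nrow(minus), 1L)
  # the planted plus ORF: starts at the ATG, ends after the stop codon
  planted <- plus[plus$g_start == 90L, ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$g_end, 90L + 183L)
  expect_identical(substr(dna, planted$g_start + 1L,
                          planted$g_start + 3L), "ATG")
})

test_that("flanking extraction clips at contig bounds and reports it", {
  genome <- Biostrings::DNAStringSet(
    c(c1 = paste(rep("ACGT", 250), collapse = "")))
  r <- extract_flanking(list(locus_id = "L", contig = "c1", start = 10L,
                             end = 60L), genome, flank = 100L)
  expect_identical(r$start, 0L)
  expect_identical(r$end, 160L)
  expect_true(r$clipped_left)
  expect_false(r$clipped_right)
  expect_identical(nchar(r$seq), 160L)
})

test_that("N-terminal profile detectors fire on their own consensus", {
  profs <- detector_profiles()
  tir <- detect_nterm_domains(profs$TIR$consensus)
  expect_true("TIR" %in% tir$kind)
  expect_false("RPW8" %in% tir$kind)
  rpw8 <- detect_nterm_domains(profs$RPW8$consensus)
  expect_true("RPW8" %in% rpw8$kind)
  expect_false("TIR" %in% rpw8$kind)
  cc <- detect_nterm_domains(paste(rep("LEALEGK", 4), collapse = ""))
  expect_identical(unique(cc$kind), "CC")
})

test_that("annotation retains LRR-bearing and drops LRR-less candidates", {
  sim <- small_test_sim()
  hits <- search_genome(reference_peptides(), sim$genome)
  loci <- length_filter(chain_adjacent(merge_overlapping(hits), 1000L),
                        setNames(Biostrings::width(reference_peptides()),
                                 names(reference_peptides())))
  ann <- annotate_candidates(loci, sim$genome)
  expect_identical(nrow(ann), 2L) # complete CNL + LRR-less NL survive 80%
  expect_setequal(ann$class_label[ann$has_lrr], "CNL")
  expect_false(any(ann$retained & !ann$has_lrr))
  kept <- lrr_filter(ann)
  expect_identical(nrow(kept), 1L)
  # with the filter disabled, both stay
  ann2 <- annotate_candidates(loci, sim$genome,
                              annotate_params(lrr_filter = FALSE))
  expect_identical(sum(ann2$retained), 2L)
})
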