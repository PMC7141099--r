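# Synthetic genomes with embedded NLR gene models and truth annotations.
# The generator emulates the gene archetypes a genome-wide NB-ARC screen
# must handle: complete multi-exon genes of all four classes, truncated
# domain fragments, LRR-less pseudogene-like loci, large-intron genes and
# tandem clusters. All operations are deterministic for a fixed seed.

# run fn with a private RNG stream; never perturbs the caller's RNG
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  fn()
}

.subseed <- function(seed, i) as.integer((as.numeric(seed) * 7919 + i * 104729)
                                         %% 2147483647)

#' Mutate a peptide to a target identity
#'
#' Substitutes exactly `round((1 - target_identity) * L)` positions, chosen
#' uniformly at random, preferring BLOSUM-plausible replacements
#' (non-negative exchange score); every substitution changes the residue,
#' so the realized identity equals the target up to rounding.
#'
#' @param peptide Character peptide.
#' @param target_identity Fraction in (0, 1].
#' @param seed RNG seed.
#' @param protect Optional 0-based positions never mutated.
#' @return Mutated peptide string.
#' @export
mutate_peptide <- function(peptide, target_identity, seed, protect = NULL) {
  stopifnot(target_identity > 0, target_identity <= 1)
  chars <- strsplit(toupper(as.character(peptide)), "")[[1L]]
  L <- length(chars)
  nmut <- round((1 - target_identity) * L)
  if (nmut == 0L) return(peptide)
  elig <- setdiff(seq_len(L), (protect %||% integer(0)) + 1L)
  if (length(elig) < nmut) {
    warning("too few mutable positions; realized identity will be higher")
    nmut <- length(elig)
  }
  smat <- .load_submat("BLOSUM62")
  .with_seed(seed, function() {
    pos <- sample(elig, nmut)
    for (p in pos) {
      a <- chars[p]
      cand <- AA20[AA20 != a]
      if (a %in% rownames(smat)) {
        plausible <- cand[smat[a, cand] >= 0]
        if (length(plausible)) cand <- plausible
      }
      chars[p] <<- sample(cand, 1L)
    }
  })
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# codon table keyed by residue (standard genetic code)
.codons_by_aa <- function() {
  if (!is.null(.nlr_env$codons_by_aa)) return(.nlr_env$codons_by_aa)
  bases <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # no.init.codon: otherwise the initiator rule maps TTG/CTG -> M when a
  # codon is translated in isolation, corrupting the table
  aas <- vapply(cods, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)),
    character(1))
  out <- split(cods, aas)
  .nlr_env$codons_by_aa <- out
  out
}

#' Reverse-translate a peptide to DNA
#'
#' Codon choice is seeded sampling among synonymous codons (uniform by
#' default, or weighted by `codon_usage`); translating the result
#' reproduces the peptide exactly.
#'
#' @param peptide Character peptide (may contain `*`).
#' @param seed RNG seed.
#' @param codon_usage Optional named numeric vector of codon weights.
#' @return DNA string.
#' @export
reverse_translate <- function(peptide, seed, codon_usage = NULL) {
  tab <- .codons_by_aa()
  chars <- strsplit(toupper(as.character(peptide)), "")[[1L]]
  .with_seed(seed, function() {
    paste(vapply(chars, function(a) {
      cods <- tab[[a]]
      if (is.null(cods)) stop("cannot reverse-translate residue ", a)
      if (length(cods) == 1L) return(cods)
      w <- if (is.null(codon_usage)) rep(1, length(cods))
           else (codon_usage[cods] %||% rep(1, length(cods)))
      w[is.na(w)] <- 0.001
      sample(cods, 1L, prob = w)
    }, character(1)), collapse = "")
  })
}

#' Specify a synthetic NLR gene
#'
#' @param class_label `"CNL"`, `"TNL"`, `"RNL"` or `"NL"` (sets the
#'   N-terminal domain encoded upstream of the NB-ARC).
#' @param nbarc_source_id Id of the reference peptide the NB-ARC derives
#'   from.
#' @param identity_to_source Fraction in (0, 1].
#' @param introns Matrix/data frame with columns `codon` (0-based codon
#'   index into the (truncated) NB-ARC) and `size` (bp, >= 50), or `NULL`.
#' @param truncation_frac Fraction of the NB-ARC retained (N-terminal part).
#' @param has_lrr Whether an LRR array follows the NB-ARC.
#' @param n_lrr_repeats LRR repeat-unit copies.
#' @param strand `"+"` or `"-"`.
#' @param placement Genomic start position, or `NA` for auto-placement.
#' @return List of class `nlr_gene_spec`.
#' @export
gene_spec <- function(class_label, nbarc_source_id, identity_to_source = 1,
                      introns = NULL, truncation_frac = 1, has_lrr = TRUE,
                      n_lrr_repeats = 8L, strand = "+", placement = NA) {
  stopifnot(class_label %in% c("CNL", "TNL", "RNL", "NL"),
            identity_to_source > 0, identity_to_source <= 1,
            truncation_frac > 0, truncation_frac <= 1,
            strand %in% c("+", "-"))
  if (!is.null(introns)) {
    introns <- as.data.frame(introns)
    stopifnot(all(c("codon", "size") %in% names(introns)),
              all(introns$size >= 50))
  }
  structure(list(class_label = class_label,
                 nbarc_source_id = nbarc_source_id,
                 identity_to_source = identity_to_source, introns = introns,
                 truncation_frac = truncation_frac,
                 has_lrr = isTRUE(has_lrr),
                 n_lrr_repeats = as.integer(n_lrr_repeats), strand = strand,
                 placement = placement),
            class = "nlr_gene_spec")
}

# 24-residue plant-style LRR repeat unit; contains the canonical
# LxxLxLxxNxL core at offset 0
.LRR_UNIT <- "LTELDLSYNQLSGEIPASLGQLKN"
# positions of the motif anchors within the unit (kept un-mutated)
.LRR_PROTECT <- c(0L, 3L, 5L, 8L, 10L)

# ideal coiled-coil: 6 heptads, a/d hydrophobic
.CC_UNIT <- paste(rep("LEALEGK", 6L), collapse = "")

#' Construct the DNA of one synthetic NLR gene
#'
#' Layout (coding strand): start codon, class-specific N-terminal domain
#' (CC heptads, TIR- or RPW8-panel-derived), linker, NB-ARC (mutated to
#' `identity_to_source`, truncated to `truncation_frac`, GT..AG introns
#' inserted at the given codon boundaries), linker, LRR array (when
#' `has_lrr`), stop codon. For `strand = "-"` the caller reverse-complements
#' at placement time; the returned features are coding-strand local
#' coordinates (0-based half-open).
#'
#' @param spec A [gene_spec()].
#' @param reference Named `AAStringSet` of reference NB-ARC peptides.
#' @param seed RNG seed.
#' @param panels Optional list with `TIR`/`RPW8` consensus peptides;
#'   defaults to the bundled synthetic panels.
#' @return List: `dna`, `features` (list with `nbarc`, `gene`, `exons`),
#'   `nbarc_peptide`.
#' @export
build_gene <- function(spec, reference, seed, panels = NULL) {
  reference <- .as_aa_set(reference)
  if (!spec$nbarc_source_id %in% names(reference))
    stop("unknown NB-ARC source: ", spec$nbarc_source_id)
  if (is.null(panels)) panels <- detector_panels()
  src <- as.character(reference[[spec$nbarc_source_id]])
  pep <- mutate_peptide(src, spec$identity_to_source, .subseed(seed, 1L))
  keep <- ceiling(spec$truncation_frac * nchar(pep))
  pep <- substr(pep, 1L, keep)

  nterm_pep <- switch(spec$class_label,
    CNL = .CC_UNIT,
    TNL = mutate_peptide(panels$TIR, 0.9, .subseed(seed, 2L)),
    RNL = mutate_peptide(panels$RPW8, 0.9, .subseed(seed, 2L)),
    NL = NULL)

  linker <- function(n, s) {
    p <- .with_seed(s, function()
      paste(sample(setdiff(AA20, c("L", "M")), n, TRUE), collapse = ""))
    p
  }

  parts_dna <- character(0)
  pos <- 0L
  add <- function(dna) {
    parts_dna <<- c(parts_dna, dna)
    pos <<- pos + nchar(dna)
    invisible(NULL)
  }
  add("ATG")
  if (!is.null(nterm_pep))
    add(reverse_translate(nterm_pep, .subseed(seed, 3L)))
  add(reverse_translate(linker(10L, .subseed(seed, 4L)), .subseed(seed, 5L)))

  # NB-ARC with introns
  nbarc_start <- pos
  nbarc_dna <- reverse_translate(pep, .subseed(seed, 6L))
  introns <- spec$introns
  exons <- NULL
  if (!is.null(introns) && nrow(introns) > 0) {
    introns <- introns[order(introns$codon), , drop = FALSE]
    if (any(introns$codon >= nchar(pep)))
      stop("spec error: intron beyond truncated domain")
    segs <- character(0)
    prev <- 0L
    cursor <- nbarc_start
    for (r in seq_len(nrow(introns))) {
      cut <- 3L * introns$codon[r]
      exon <- substr(nbarc_dna, prev + 1L, cut)
      segs <- c(segs, exon)
      exons <- rbind(exons, c(cursor, cursor + nchar(exon)))
      cursor <- cursor + nchar(exon)
      isz <- introns$size[r]
      mid <- .with_seed(.subseed(seed, 100L + r), function()
        paste(sample(c("A", "C", "G", "T"), isz - 4L, TRUE), collapse = ""))
      segs <- c(segs, paste0("GT", mid, "AG"))
      cursor <- cursor + isz
      prev <- cut
    }
    exon <- substr(nbarc_dna, prev + 1L, nchar(nbarc_dna))
    segs <- c(segs, exon)
    exons <- rbind(exons, c(cursor, cursor + nchar(exon)))
    add(paste(segs, collapse = ""))
  } else {
    exons <- rbind(exons, c(nbarc_start, nbarc_start + nchar(nbarc_dna)))
    add(nbarc_dna)
  }
  nbarc_end <- pos

  add(reverse_translate(linker(10L, .subseed(seed, 7L)), .subseed(seed, 8L)))
  if (spec$has_lrr) {
    units <- vapply(seq_len(spec$n_lrr_repeats), function(u)
      mutate_peptide(.LRR_UNIT, 0.92, .subseed(seed, 200L + u),
                     protect = .LRR_PROTECT), character(1))
    add(reverse_translate(paste(units, collapse = ""), .subseed(seed, 9L)))
  }
  add("TGA")
  dna <- paste(parts_dna, collapse = "")
  list(dna = dna,
       features = list(nbarc = c(nbarc_start, nbarc_end),
                       gene = c(0L, nchar(dna)), exons = exons),
       nbarc_peptide = pep)
}

#' Expected pipeline outcome for a gene archetype
#'
#' The documented pure mapping from a [gene_spec()] to the outcome the
#' pipeline's default thresholds produce: an NB-ARC intron larger than the
#' chaining gap splits the locus (`dropped_split`); a domain truncated to
#' at most the retention fraction fails the length rule (`dropped_length`);
#' a complete domain with no LRR within the flank fails the LRR filter
#' (`dropped_lrr`); otherwise `retained`.
#'
#' @param spec A [gene_spec()].
#' @param max_gap Chaining gap, bp.
#' @param min_len_frac Length-rule fraction.
#' @return One of `"retained"`, `"dropped_length"`, `"dropped_lrr"`,
#'   `"dropped_split"`.
#' @export
expected_outcome <- function(spec, max_gap = 1000L, min_len_frac = 0.8) {
  if (!is.null(spec$introns) && nrow(spec$introns) > 0 &&
      any(spec$introns$size > max_gap)) return("dropped_split")
  if (spec$truncation_frac <= min_len_frac) return("dropped_length")
  if (!spec$has_lrr) return("dropped_lrr")
  "retained"
}

#' Generate a synthetic genome with truth annotations
#'
#' Builds an i.i.d. background of the requested GC content and splices in
#' the specified genes at recorded coordinates. Auto-placed genes keep at
#' least `min_spacing` bp between gene intervals so that each gene's
#' +/- 10 kb annotation window is unambiguous; pass explicit `placement`
#' values (or `cluster = TRUE`) to build tandem clusters.
#'
#' @param specs List of [gene_spec()] objects.
#' @param background_len Genome length in bp before gene insertion.
#' @param gc Background GC fraction.
#' @param seed RNG seed.
#' @param reference Named `AAStringSet` of reference NB-ARC peptides;
#'   defaults to the bundled synthetic reference set.
#' @param min_spacing Minimum distance between auto-placed gene intervals.
#' @param cluster If `TRUE`, auto-placement uses 2 kb spacing to build gene
#'   clusters (stress case for de-duplication).
#' @param contig_name Name of the single output contig.
#' @return List of class `nlr_sim`: `genome` (`DNAStringSet`), `truth`
#'   (data frame: `gene_id`, `class_label`, `contig`, `nbarc_start`,
#'   `nbarc_end`, `gene_start`, `gene_end`, `strand`, `identity`,
#'   `truncation`, `max_intron`, `has_lrr`, `expected_outcome`), `specs`.
#' @export
generate_genome <- function(specs, background_len, gc = 0.4, seed = 1L,
                            reference = reference_peptides(),
                            min_spacing = 12000L, cluster = FALSE,
                            contig_name = "chr_sim") {
  stopifnot(gc > 0, gc < 1, background_len >= 1000)
  if (cluster) min_spacing <- 2000L
  reference <- .as_aa_set(reference)
  built <- lapply(seq_along(specs), function(i)
    build_gene(specs[[i]], reference, .subseed(seed, 1000L + i)))
  glens <- vapply(built, function(b) nchar(b$dna), integer(1))
  bg <- .with_seed(.subseed(seed, 1L), function()
    paste(sample(c("A", "C", "G", "T"), background_len, TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""))
  # placement in background coordinates (insertion points)
  placed <- rep(NA_real_, length(specs))
  fixed <- vapply(specs, function(s) suppressWarnings(
    as.numeric(s$placement)), numeric(1))
  placed[!is.na(fixed)] <- fixed[!is.na(fixed)]
  auto <- which(is.na(placed))
  if (length(auto)) {
    taken <- lapply(which(!is.na(placed)), function(i)
      c(placed[i], placed[i] + glens[i]))
    .with_seed(.subseed(seed, 2L), function() {
      for (i in auto) {
        ok <- FALSE
        for (try in 1:2000) {
          p <- sample.int(background_len - glens[i] - 1L, 1L)
          clash <- any(vapply(taken, function(tv)
            p < tv[2L] + min_spacing && p + glens[i] + min_spacing > tv[1L],
            logical(1)))
          if (!clash) {
            placed[i] <<- p
            taken[[length(taken) + 1L]] <<- c(p, p + glens[i])
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("capacity error: genome too small for requested genes")
      }
    })
  }
  # splice genes into the background, highest insertion point first so
  # earlier coordinates stay valid; then compute final coordinates
  ord <- order(placed, decreasing = TRUE)
  gseq <- bg
  for (i in ord) {
    dna <- built[[i]]$dna
    if (specs[[i]]$strand == "-") dna <- .revcomp_chr(dna)
    gseq <- paste0(substr(gseq, 1L, placed[i]), dna,
                   substr(gseq, placed[i] + 1L, nchar(gseq)))
  }
  # final gene starts: insertion point + total length of genes inserted
  # before it
  ordf <- order(placed)
  shift <- 0L
  gstart <- numeric(length(specs))
  for (i in ordf) {
    gstart[i] <- placed[i] + shift
    shift <- shift + glens[i]
  }
  truth <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    b <- built[[i]]
    gs <- gstart[i]
    nb <- b$features$nbarc
    if (s$strand == "-") nb <- c(glens[i] - nb[2L], glens[i] - nb[1L])
    data.frame(gene_id = sprintf("sim_gene_%03d", i),
               class_label = s$class_label, contig = contig_name,
               nbarc_start = as.integer(gs + nb[1L]),
               nbarc_end = as.integer(gs + nb[2L]),
               gene_start = as.integer(gs),
               gene_end = as.integer(gs + glens[i]), strand = s$strand,
               identity = s$identity_to_source,
               truncation = s$truncation_frac,
               max_intron = if (is.null(s$introns) || nrow(s$introns) == 0) 0L
                            else as.integer(max(s$introns$size)),
               has_lrr = s$has_lrr,
               expected_outcome = expected_outcome(s),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(gene_id = character(0), class_label = character(0),
                        contig = character(0), nbarc_start = integer(0),
                        nbarc_end = integer(0), gene_start = integer(0),
                        gene_end = integer(0), strand = character(0),
                        identity = numeric(0), truncation = numeric(0),
                        max_intron = integer(0), has_lrr = logical(0),
                        expected_outcome = character(0),
                        stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(setNames(gseq, contig_name))
  structure(list(genome = genome, truth = truth, specs = specs, seed = seed),
            class = "nlr_sim")
}

#' Write a simulation's outputs
#'
#' Writes `genome.fa`, `truth.gff3` (gene + NB-ARC features with class and
#' expected outcome attributes) and `truth.tsv`.
#'
#' @param sim An `nlr_sim` from [generate_genome()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  tr <- sim$truth
  feats <- NULL
  for (i in seq_len(nrow(tr))) {
    feats <- rbind(feats,
      .gff_feature(tr$contig[i], "nlrsweep_sim", "gene", tr$gene_start[i],
                   tr$gene_end[i], NA_real_, tr$strand[i], tr$gene_id[i],
                   list(class = tr$class_label[i],
                        expected_outcome = tr$expected_outcome[i])),
      .gff_feature(tr$contig[i], "nlrsweep_sim", "protein_match",
                   tr$nbarc_start[i], tr$nbarc_end[i], NA_real_,
                   tr$strand[i], paste0(tr$gene_id[i], "_nbarc"),
                   list(Parent = tr$gene_id[i], Name = "NB-ARC")))
  }
  write_gff3(feats, file.path(dir, "truth.gff3"))
  write.table(tr, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  specs_plain <- lapply(sim$specs, function(s) {
    s <- unclass(s)
    s$introns <- if (is.null(s$introns)) list()
                 else lapply(seq_len(nrow(s$introns)), function(r)
                   list(codon = s$introns$codon[r], size = s$introns$size[r]))
    if (is.na(s$placement)) s$placement <- "random"
    s
  })
  yaml::write_yaml(list(seed = sim$seed, specs = specs_plain),
                   file.path(dir, "specs.yaml"))
  invisible(dir)
}
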