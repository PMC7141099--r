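# Two-pass orchestration: reference search, per-class profile refinement,
# second-pass profile search, union of candidates, annotation and outputs.

# one pass: raw hits -> merged blocks -> chained loci -> length-filtered
.run_pass <- function(hits, config, query_lens, pass_index) {
  blocks <- merge_overlapping(hits)
  loci <- chain_adjacent(blocks, config$chain$max_gap)
  kept <- length_filter(loci, query_lens, config$chain$min_len_frac)
  kept$pass_index <- rep(pass_index, nrow(kept))
  list(hits = hits, blocks = blocks, loci = loci, kept = kept,
       counts = c(hits = nrow(hits), blocks = nrow(blocks),
                  loci = nrow(loci), kept = nrow(kept)))
}

# union of pass-1 and pass-2 loci: same-strand overlapping duplicates are
# collapsed to the higher-scoring locus (ties: pass 1, then leftmost); the
# dropped duplicates are returned with a duplicate_of pointer for the report
.union_loci <- function(a, b) {
  combined <- rbind(a, b)
  dup_cols <- c("locus_id", "contig", "strand", "start", "end",
                "pass_index", "score")
  if (nrow(combined) <= 1L)
    return(list(kept = combined,
                duplicates = cbind(combined[0L, dup_cols],
                                   duplicate_of = character(0))))
  ord <- order(-combined$score, combined$pass_index, combined$start,
               method = "radix")
  combined <- combined[ord, , drop = FALSE]
  keep <- logical(nrow(combined))
  dup_of <- character(nrow(combined))
  for (i in seq_len(nrow(combined))) {
    prior <- which(keep)
    clash <- prior[combined$contig[prior] == combined$contig[i] &
                   combined$strand[prior] == combined$strand[i] &
                   combined$start[prior] < combined$end[i] &
                   combined$end[prior] > combined$start[i]]
    keep[i] <- length(clash) == 0L
    if (!keep[i]) dup_of[i] <- combined$locus_id[clash[1L]]
  }
  duplicates <- cbind(combined[!keep, dup_cols, drop = FALSE],
                      duplicate_of = dup_of[!keep])
  res <- combined[keep, , drop = FALSE]
  res <- res[order(res$contig, res$start, res$strand, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  rownames(duplicates) <- NULL
  list(kept = res, duplicates = duplicates)
}

#' Run the full candidate-identification pipeline
#'
#' Pass 1 searches the genome with class-labelled reference NB-ARC
#' peptides; merged, chained hits passing the length rule become first-pass
#' candidates. Their peptides (extracted in the reading frames of the
#' supporting hits) are grouped by the class of each candidate's most
#' similar reference and aligned into per-class profiles, which drive a
#' second, species-specific search pass; classes with too few candidates
#' fall back to their reference hits. The union of both passes (overlap
#' de-duplicated, higher score wins) is annotated for ORFs, LRR arrays and
#' N-terminal domains, classified, and filtered for LRR presence.
#'
#' If the first pass finds nothing, the pipeline degrades to a single pass
#' with a warning.
#'
#' @param genome Named `DNAStringSet` (or path to a genome FASTA).
#' @param reference Class-labelled reference peptides
#'   ([reference_peptides()] by default): an `AAStringSet` whose `class`
#'   metadata column holds CNL/TNL/NL/RNL labels.
#' @param config [pipeline_config()].
#' @param outdir Output directory; if `NULL`, nothing is written.
#' @return A list of class `nlr_run`: `candidates` (annotated loci, all),
#'   `retained` (after the LRR filter), `profiles`, `fallback_classes`,
#'   `counts` (per-stage row counts), `log` (character lines), `config`.
#' @export
run_pipeline <- function(genome, reference = reference_peptides(),
                         config = pipeline_config(), outdir = NULL) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- read_fasta(genome, type = "DNA")
  genome <- .as_dna_set(genome)
  reference <- .as_aa_set(reference)
  ref_class <- S4Vectors::mcols(reference)$class
  if (is.null(ref_class)) ref_class <- .parse_class_tags(reference)
  qlens <- setNames(Biostrings::width(reference), names(reference))

  log <- c(paste0("nlrsweep pipeline run (version ",
                  as.character(utils::packageVersion("nlrsweep")), ")"),
           sprintf("genome: %d contig(s), %d bp", length(genome),
                   sum(Biostrings::width(genome))),
           sprintf("reference: %d peptides (%s)", length(reference),
                   paste(sort(unique(ref_class)), collapse = ", ")))

  hits1 <- search_genome(reference, genome, config$search)
  p1 <- .run_pass(hits1, config, qlens, 1L)
  log <- c(log, sprintf(
    "pass 1: %d hits -> %d blocks -> %d loci -> %d candidates",
    p1$counts["hits"], p1$counts["blocks"], p1$counts["loci"],
    p1$counts["kept"]))

  profiles <- list()
  fallback <- character(0)
  p2 <- NULL
  if (config$pass2 && nrow(p1$kept) == 0) {
    warning("first pass found no candidates; running single-pass only")
    log <- c(log, "pass 2: skipped (no first-pass candidates)")
  } else if (config$pass2) {
    peptides <- extract_candidate_peptides(p1$kept, genome)
    cand_class <- ref_class[match(p1$kept$best_query_id, names(reference))]
    names(cand_class) <- p1$kept$locus_id
    cp <- build_class_profiles(
      peptides, cand_class[names(peptides)], params = config$search,
      pseudocount = config$profile$pseudocount,
      gap_col_frac = config$profile$gap_col_frac,
      min_class_size = config$profile$min_class_size)
    profiles <- cp$profiles
    fallback <- cp$fallback_classes
    log <- c(log, sprintf("profiles: %s%s",
      if (length(profiles)) paste(sort(names(profiles)), collapse = ", ")
      else "none",
      if (length(fallback)) paste0(" (fallback to reference: ",
                                   paste(sort(fallback), collapse = ", "),
                                   ")") else ""))
    hits2 <- if (length(profiles))
      profile_search(profiles, genome, config$search) else .empty_hits()
    if (length(fallback)) {
      fb_ids <- names(reference)[ref_class %in% fallback]
      hits2 <- rbind(hits2, hits1[hits1$query_id %in% fb_ids, ,
                                  drop = FALSE])
    }
    qlens2 <- qlens
    if (length(profiles))
      qlens2 <- c(qlens, setNames(
        vapply(profiles, function(p) nrow(p$scores), numeric(1)),
        paste0("profile:", names(profiles))))
    p2 <- .run_pass(hits2, config, qlens2, 2L)
    log <- c(log, sprintf(
      "pass 2: %d hits -> %d blocks -> %d loci -> %d candidates",
      p2$counts["hits"], p2$counts["blocks"], p2$counts["loci"],
      p2$counts["kept"]))
  } else {
    log <- c(log, "pass 2: disabled")
  }

  u <- .union_loci(p1$kept, if (is.null(p2)) p1$kept[0L, , drop = FALSE]
                            else p2$kept)
  final <- u$kept
  log <- c(log, sprintf("union: %d candidate loci (%d duplicate(s) dropped)",
                        nrow(final), nrow(u$duplicates)))

  ann <- annotate_candidates(final, genome, config$annotate, config$search)
  retained <- lrr_filter(ann, config$annotate$lrr_filter)
  log <- c(log, sprintf("annotated: %d; retained after LRR filter: %d",
                        nrow(ann), nrow(retained)))

  run <- structure(list(candidates = ann, retained = retained,
                        duplicates = u$duplicates,
                        profiles = profiles, fallback_classes = fallback,
                        counts = list(pass1 = p1$counts,
                                      pass2 = if (is.null(p2)) NULL
                                              else p2$counts,
                                      union = nrow(final),
                                      retained = nrow(retained)),
                        log = log, config = config), class = "nlr_run")
  if (!is.null(outdir)) write_run(run, outdir, genome)
  run
}

#' Write a pipeline run's outputs
#'
#' Writes `candidates.bed` (retained candidates, BED6, name = locus id,
#' score = search score), `annotations.gff3` (every candidate locus with
#' its domain calls as child features), `report.tsv` (one row per
#' candidate), `run.log`, and — when profiles were built — a `profiles/`
#' directory (see [write_profiles()]). All outputs are byte-deterministic
#' for a given run.
#'
#' @param run An `nlr_run` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param genome The genome searched (for BED bounds checking); optional.
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir, genome = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ret <- run$retained
  bed <- if (nrow(ret) == 0) {
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0),
               strand = character(0), stringsAsFactors = FALSE)
  } else {
    bed_intervals(ret$contig, ret$start, ret$end, ret$locus_id,
                  round(ret$score, 1), ret$strand)
  }
  write_bed(bed, file.path(outdir, "candidates.bed"), genome)

  feats <- NULL
  ann <- run$candidates
  for (i in seq_len(nrow(ann))) {
    lid <- ann$locus_id[i]
    feats <- rbind(feats, .gff_feature(
      ann$contig[i], "nlrsweep", "protein_match", ann$start[i], ann$end[i],
      ann$score[i], ann$strand[i], lid,
      list(Name = "NB-ARC_candidate", class = ann$class_label[i],
           pass = ann$pass_index[i],
           retained = tolower(as.character(ann$retained[i])))))
    calls <- ann$calls[[i]]
    calls <- calls[calls$kind != "NB-ARC", , drop = FALSE]
    for (r in seq_len(nrow(calls))) {
      feats <- rbind(feats, .gff_feature(
        ann$contig[i], "nlrsweep",
        if (calls$kind[r] == "ORF") "ORF" else "protein_match",
        calls$g_start[r], calls$g_end[r], calls$score[r], calls$strand[r],
        sprintf("%s_%s_%d", lid, tolower(calls$kind[r]), r),
        list(Parent = lid, Name = calls$kind[r])))
    }
  }
  write_gff3(feats, file.path(outdir, "annotations.gff3"))

  rep <- ann[, c("locus_id", "contig", "start", "end", "strand",
                 "pass_index", "score", "n_segments", "best_query_id",
                 "coverage", "class_label", "has_lrr", "retained")]
  rep$score <- round(rep$score, 1)
  rep$coverage <- round(rep$coverage, 4)
  rep$duplicate_of <- rep(".", nrow(rep))
  dup <- run$duplicates
  if (!is.null(dup) && nrow(dup) > 0) {
    # de-duplicated loci stay visible to curators, flagged by duplicate_of
    dup_rows <- data.frame(
      locus_id = dup$locus_id, contig = dup$contig, start = dup$start,
      end = dup$end, strand = dup$strand, pass_index = dup$pass_index,
      score = round(dup$score, 1), n_segments = NA_integer_,
      best_query_id = NA_character_, coverage = NA_real_,
      class_label = NA_character_, has_lrr = NA, retained = FALSE,
      duplicate_of = dup$duplicate_of, stringsAsFactors = FALSE)
    rep <- rbind(rep, dup_rows)
    rep <- rep[order(rep$contig, rep$start, rep$strand, method = "radix"), ,
               drop = FALSE]
  }
  write.table(rep, file.path(outdir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = ".")
  writeLines(run$log, file.path(outdir, "run.log"))
  if (length(run$profiles))
    write_profiles(run$profiles, file.path(outdir, "profiles"))
  invisible(outdir)
}

#' @export
print.nlr_run <- function(x, ...) {
  cat("nlr_run\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
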