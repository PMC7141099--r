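# Species- and class-specific NB-ARC profiles from first-pass candidates:
# phase-correct peptide extraction, a deterministic star multiple alignment,
# and position-specific log-odds matrices with a consensus sequence. These
# stand in for the TransDecoder -> MUSCLE -> HMMER chain of classic NB-ARC
# screens: the profile is used only as a refined second-pass query, and a
# PSSM captures the species-specific residue preferences that motivate it.

#' Extract candidate peptides from loci
#'
#' For each locus, translates each segment in the reading frame of its
#' best-scoring constituent hit (the frame evidence carried by the search —
#' no ORF re-prediction) and joins segment peptides in gene order. Internal
#' stops are retained as `*` so relatively intact pseudogenes stay in the
#' profile. Segments shorter than one codon are dropped with a warning.
#'
#' @param loci Loci data frame from [chain_adjacent()] / [length_filter()].
#' @param genome Named `DNAStringSet`.
#' @return An `AAStringSet` named by locus id.
#' @export
extract_candidate_peptides <- function(loci, genome) {
  genome <- .as_dna_set(genome)
  peps <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    contig <- genome[[loci$contig[i]]]
    len <- length(contig)
    seg <- loci$segments[[i]]
    strand <- loci$strand[i]
    ord <- order(seg[, "start"], decreasing = (strand == "-"))
    parts <- character(0)
    for (r in ord) {
      s <- seg[r, "start"]; e <- seg[r, "end"]; anchor <- seg[r, "anchor"]
      if (e - s < 3L) {
        warning("segment shorter than one codon dropped in locus ",
                loci$locus_id[i])
        next
      }
      if (strand == "+") {
        p <- s + ((anchor - s) %% 3L)
        k <- (e - p) %/% 3L
        if (k < 1L) next
        dna <- as.character(Biostrings::subseq(contig, p + 1L, p + 3L * k))
        parts <- c(parts, .translate_chr(dna))
      } else {
        # work in reverse-complement coordinates: rc(x) = len - x; hits span
        # whole codons, so (len - anchor) fixes the rc frame phase
        rc_s <- len - e
        rc_anchor <- len - anchor
        p <- rc_s + ((rc_anchor - rc_s) %% 3L)
        k <- ((len - s) - p) %/% 3L
        if (k < 1L) next
        gs <- len - (p + 3L * k); ge <- len - p
        dna <- .revcomp_chr(as.character(Biostrings::subseq(contig, gs + 1L,
                                                            ge)))
        parts <- c(parts, .translate_chr(dna))
      }
    }
    peps[i] <- paste(parts, collapse = "")
  }
  keep <- nzchar(peps)
  out <- Biostrings::AAStringSet(peps[keep])
  names(out) <- loci$locus_id[keep]
  out
}

#' Star multiple alignment of peptides
#'
#' The centre is the peptide with the highest summed pairwise global
#' alignment score to all others; every other peptide is aligned to the
#' centre by affine-gap global alignment and the pairwise alignments are
#' merged under "once a gap, always a gap".
#'
#' @param peptides `AAStringSet` or named character vector (>= 1 sequence).
#' @param params [search_params()] supplying matrix and gap penalties.
#' @return A list of class `nlr_msa`: `ids`, `rows` (equal-length gapped
#'   strings), `ncol`, `centre`.
#' @export
align_peptides <- function(peptides, params = search_params()) {
  seqs <- as.character(.as_aa_set(peptides))
  if (length(seqs) == 0L) stop("empty input: no peptides to align")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n == 1L) {
    return(structure(list(ids = ids, rows = unname(seqs),
                          ncol = nchar(seqs[[1L]]), centre = ids[1L]),
                     class = "nlr_msa"))
  }
  smat <- .submat128(params$matrix)
  go <- params$gap_open; ge <- params$gap_extend
  tot <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sc <- cpp_global_score(seqs[[i]], seqs[[j]], smat, go, ge)
      tot[i] <- tot[i] + sc
      tot[j] <- tot[j] + sc
    }
  }
  centre <- which.max(tot)
  c_seq <- seqs[[centre]]
  lc <- nchar(c_seq)
  leaves <- setdiff(seq_len(n), centre)
  alns <- lapply(leaves, function(j)
    cpp_global_align(c_seq, seqs[[j]], smat, go, ge))
  # inserts[p + 1]: gap run length in the centre row before centre residue p
  # (p = lc -> trailing)
  ins_of <- function(a_row) {
    ins <- integer(lc + 1L)
    p <- 0L
    run <- 0L
    for (ch in strsplit(a_row, "")[[1L]]) {
      if (ch == "-") run <- run + 1L
      else {
        ins[p + 1L] <- run
        run <- 0L
        p <- p + 1L
      }
    }
    ins[lc + 1L] <- run
    ins
  }
  ins_list <- lapply(alns, function(a) ins_of(a$a))
  master <- Reduce(pmax, ins_list, integer(lc + 1L))
  c_chars <- strsplit(c_seq, "")[[1L]]
  build_centre <- function() {
    out <- character(0)
    for (p in 0:(lc - 1L)) {
      out <- c(out, rep("-", master[p + 1L]), c_chars[p + 1L])
    }
    c(out, rep("-", master[lc + 1L]))
  }
  rows <- vector("list", n)
  rows[[centre]] <- paste(build_centre(), collapse = "")
  for (t in seq_along(leaves)) {
    a <- alns[[t]]
    ca <- strsplit(a$a, "")[[1L]]
    la <- strsplit(a$b, "")[[1L]]
    out <- character(0)
    p <- 0L
    buf <- character(0)
    flush_slot <- function(buf, p) {
      c(buf, rep("-", master[p + 1L] - length(buf)))
    }
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        buf <- c(buf, la[k])
      } else {
        out <- c(out, flush_slot(buf, p), la[k])
        buf <- character(0)
        p <- p + 1L
      }
    }
    out <- c(out, flush_slot(buf, lc))
    rows[[leaves[t]]] <- paste(out, collapse = "")
  }
  rows <- unlist(rows)
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(ids = ids, rows = unname(rows), ncol = nchar(rows[1L]),
                 centre = ids[centre]),
            class = "nlr_msa")
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Columns with more than `gap_col_frac` gaps are dropped; remaining columns
#' are scored as `log2((count_a + pseudocount * bg_a) / (n + pseudocount) /
#' bg_a)` where `n` is the column's non-gap count. The consensus takes each
#' column's argmax (ties to the lexicographically first residue).
#'
#' @param msa An `nlr_msa` from [align_peptides()].
#' @param class_label One of `"CNL"`, `"TNL"`, `"NL"`, `"RNL"` (or any label
#'   for detector profiles).
#' @param pseudocount Positive pseudocount weight.
#' @param background Named 20-vector of residue background frequencies
#'   summing to 1; default uniform 0.05.
#' @param gap_col_frac Gap fraction above which a column is dropped.
#' @return A list of class `nlr_profile`: `class_label`, `ncol`, `scores`
#'   (ncol x 20), `consensus`, `n_sequences`, `pseudocount`, `background`.
#' @export
build_profile <- function(msa, class_label, pseudocount = 1,
                          background = NULL, gap_col_frac = 0.5) {
  stopifnot(inherits(msa, "nlr_msa"), pseudocount > 0)
  if (is.null(background)) background <- setNames(rep(0.05, 20L), AA20)
  background <- background[AA20]
  stopifnot(abs(sum(background) - 1) < 1e-6)
  chars <- do.call(rbind, strsplit(msa$rows, ""))
  nseq <- nrow(chars)
  gap_frac <- colMeans(chars == "-")
  keep <- gap_frac <= gap_col_frac
  if (!any(keep)) stop("degenerate profile: all columns gap-heavy")
  chars <- chars[, keep, drop = FALSE]
  ncol_p <- ncol(chars)
  counts <- vapply(AA20, function(a) colSums(chars == a),
                   numeric(ncol_p))
  if (ncol_p == 1L) counts <- matrix(counts, nrow = 1L,
                                     dimnames = list(NULL, AA20))
  nongap <- as.numeric(colSums(chars != "-"))
  scores <- log2((counts + pseudocount * matrix(background, ncol_p, 20L,
                                                byrow = TRUE)) /
                 (nongap + pseudocount) /
                 matrix(background, ncol_p, 20L, byrow = TRUE))
  colnames(scores) <- AA20
  consensus <- paste(AA20[apply(scores, 1L, which.max)], collapse = "")
  structure(list(class_label = class_label, ncol = ncol_p, scores = scores,
                 consensus = consensus, n_sequences = nseq,
                 pseudocount = pseudocount, background = background),
            class = "nlr_profile")
}

#' @export
print.nlr_profile <- function(x, ...) {
  cat("nlr_profile <", x$class_label, ">: ", x$ncol, " columns from ",
      x$n_sequences, " sequence(s)\n", sep = "")
  invisible(x)
}

#' Build per-class profiles from candidate peptides
#'
#' One profile per class with at least `min_class_size` members; classes
#' below the floor are reported in `fallback_classes` and the pipeline falls
#' back to the original reference peptides of that class for the second pass.
#'
#' @param peptides `AAStringSet` of candidate NB-ARC peptides.
#' @param class_assignments Character vector (same length) of class labels —
#'   each peptide takes the class of its locus's best first-pass query.
#' @param params [search_params()] for the star alignment.
#' @param pseudocount,background,gap_col_frac See [build_profile()].
#' @param min_class_size Minimum members per class profile.
#' @return List with `profiles` (named list of `nlr_profile`) and
#'   `fallback_classes` (character).
#' @export
build_class_profiles <- function(peptides, class_assignments,
                                 params = search_params(), pseudocount = 1,
                                 background = NULL, gap_col_frac = 0.5,
                                 min_class_size = 2L) {
  peptides <- .as_aa_set(peptides)
  stopifnot(length(peptides) == length(class_assignments))
  classes <- unique(class_assignments)
  profiles <- list()
  fallback <- character(0)
  for (cl in classes) {
    members <- peptides[class_assignments == cl]
    if (length(members) < min_class_size) {
      fallback <- c(fallback, cl)
      next
    }
    msa <- align_peptides(members, params)
    profiles[[cl]] <- build_profile(msa, cl, pseudocount = pseudocount,
                                    background = background,
                                    gap_col_frac = gap_col_frac)
  }
  list(profiles = profiles, fallback_classes = fallback)
}

#' Score a peptide against a profile
#'
#' Best local alignment score of the peptide under the profile's
#' position-specific scores (same gap penalties as the search).
#'
#' @param profile An `nlr_profile`.
#' @param peptide Character peptide.
#' @param params [search_params()].
#' @return Numeric score (0 if no positive-scoring local alignment).
#' @export
profile_score <- function(profile, peptide, params = search_params()) {
  df <- cpp_search_pssm(.pssm128(profile$scores), profile$consensus,
                        toupper(as.character(peptide)), params$gap_open,
                        params$gap_extend, params$gap_cap, params$x_drop,
                        0.001, params$k, 1L, TRUE, 1L)
  if (nrow(df) == 0) 0 else max(df$score)
}

#' Write profiles to disk
#'
#' Writes each profile's consensus as FASTA (`<class>.fa`) and its matrix as
#' a plain-text table (`<class>.pssm`, one line per column, 20 tab-separated
#' log-odds values in residue order ACDEFGHIKLMNPQRSTVWY).
#'
#' @param profiles Named list of `nlr_profile`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(profiles)) {
    p <- profiles[[cl]]
    write_fasta(setNames(p$consensus, paste0("consensus_", cl)),
                file.path(dir, paste0(cl, ".fa")))
    con <- file(file.path(dir, paste0(cl, ".pssm")), "w")
    writeLines(paste0("# columns: ", paste(AA20, collapse = "\t")), con)
    writeLines(apply(p$scores, 1L, function(r)
      paste(sprintf("%.4f", r), collapse = "\t")), con)
    close(con)
  }
  invisible(dir)
}
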