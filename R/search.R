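# Translated homology search: local alignment of reference peptides (or
# class profiles) against all six reading frames of the genome. Replaces the
# role tBLASTn plays in classic NB-ARC screens with a deterministic
# seed-and-extend Smith-Waterman (exact k-mer seeds, affine gaps, capped gap
# runs, and X-drop path pruning as in gapped BLAST).

#' Search parameters
#'
#' @param matrix Substitution matrix name (a `Biostrings` data matrix).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param x_drop X-drop threshold in raw score units: an alignment path is
#'   pruned (restarted) once its score falls more than this below the
#'   running maximum along the path. This is what keeps a local alignment
#'   from bridging a translated intron by chaining capped gap runs with
#'   mismatch columns: the bridge accumulates a deficit far above `x_drop`
#'   (~1 per junk column) while genuine within-domain dips stay near zero
#'   when substitutions are conservative. 60 corresponds to a deficit no
#'   real exon boundary mismatch run approaches, yet ~3 times smaller than
#'   the deficit of the shortest intron the simulator can emit.
#' @param k Seed word length (exact peptide k-mer match).
#' @param min_seeds Minimum seeds per diagonal cluster before extension.
#' @param min_hit_score Minimum raw alignment score for a reported hit.
#'   The default sits above the empirical null maximum for a ~280-residue
#'   query against a multi-megabase six-frame translation, so random
#'   background yields no hits.
#' @param min_hit_identity Minimum fraction of identical alignment columns.
#' @param gap_cap Maximum gap run length in residues. Local alignments cannot
#'   bridge unrelated stretches longer than this; introns beyond
#'   `3 * gap_cap` bp therefore split a domain into separate hits, which the
#'   chaining stage may rejoin.
#' @param mode `"auto"` (full DP for small problems, seeded otherwise),
#'   `"seed"`, or `"full"`.
#' @param max_hits Maximum hits extracted per extension window.
#' @return A list of class `nlr_search_params`.
#' @export
search_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          x_drop = 60,
                          k = 4L, min_seeds = 2L, min_hit_score = 80,
                          min_hit_identity = 0.60, gap_cap = 30L,
                          mode = c("auto", "seed", "full"), max_hits = 25L) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= gap_extend, gap_extend > 0, k >= 2L,
            is.finite(min_hit_score), is.finite(min_hit_identity),
            min_hit_identity >= 0, min_hit_identity <= 1, gap_cap >= 1L,
            x_drop > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, x_drop = x_drop,
                 k = as.integer(k),
                 min_seeds = as.integer(min_seeds),
                 min_hit_score = min_hit_score,
                 min_hit_identity = min_hit_identity,
                 gap_cap = as.integer(gap_cap), mode = mode,
                 max_hits = as.integer(max_hits)),
            class = "nlr_search_params")
}

.empty_hits <- function() {
  data.frame(contig = character(0), g_start = integer(0), g_end = integer(0),
             strand = character(0), frame = integer(0),
             query_id = character(0), q_start = integer(0),
             q_end = integer(0), score = numeric(0), identity = numeric(0),
             n_ident = integer(0), aln_cols = integer(0),
             aligned_peptide = character(0), stringsAsFactors = FALSE)
}

# shared frame loop for sequence and profile queries
.search_frames <- function(genome, params, per_frame) {
  rows <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    dna <- genome[[ci]]
    len <- length(dna)
    frames <- six_frame_translate(dna)
    for (fr in frames) {
      pep <- fr$peptide
      if (nchar(pep) < 1L) next
      hits <- per_frame(pep)
      for (h in hits) {
        if (nrow(h$df) == 0) next
        df <- h$df
        g <- t(vapply(seq_len(nrow(df)), function(r) {
          .frame_to_genomic(fr$frame, df$s_start[r], df$s_end[r], len)
        }, numeric(2)))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig, g_start = as.integer(g[, 1L]),
          g_end = as.integer(g[, 2L]),
          strand = if (fr$frame > 0) "+" else "-", frame = fr$frame,
          query_id = h$query_id, q_start = df$q_start, q_end = df$q_end,
          score = df$score, identity = df$n_ident / df$aln_cols,
          n_ident = df$n_ident, aln_cols = df$aln_cols,
          aligned_peptide = substring(pep, df$s_start + 1L, df$s_end),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_hits()
  out <- out[out$identity >= params$min_hit_identity, , drop = FALSE]
  out <- out[order(out$contig, out$g_start, out$g_end, out$query_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.mode_full <- function(params, qlen, slen) {
  switch(params$mode,
         full = TRUE,
         seed = FALSE,
         auto = (as.numeric(qlen) * as.numeric(slen)) <= 2e6)
}

#' Translated search of a genome with peptide queries
#'
#' Aligns each query locally against all six reading frames of every contig
#' and reports hits above the score and identity thresholds, in genomic
#' 0-based half-open coordinates sorted by `(contig, g_start)`.
#'
#' @param queries Named `AAStringSet` (or named character vector) of peptide
#'   queries.
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param params A [search_params()] object.
#' @return A data frame of hits: `contig`, `g_start`, `g_end`, `strand`,
#'   `frame`, `query_id`, `q_start`, `q_end`, `score`, `identity`, `n_ident`,
#'   `aln_cols`, `aligned_peptide`.
#' @export
search_genome <- function(queries, genome, params = search_params()) {
  queries <- .as_aa_set(queries)
  genome <- .as_dna_set(genome)
  if (length(queries) == 0L) stop("empty input: no queries")
  if (length(genome) == 0L) stop("empty input: no genome sequences")
  qs <- as.character(queries)
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", qs)
  if (any(bad)) stop("query alphabet error: ", names(qs)[which(bad)[1L]])
  smat <- .submat128(params$matrix)
  .search_frames(genome, params, function(pep) {
    lapply(seq_along(qs), function(qi) {
      q <- qs[[qi]]
      df <- cpp_search(q, pep, smat, params$gap_open, params$gap_extend,
                       params$gap_cap, params$x_drop,
                       params$min_hit_score, params$k,
                       if (nchar(q) < 30L) 1L else params$min_seeds,
                       .mode_full(params, nchar(q), nchar(pep)),
                       params$max_hits)
      list(query_id = names(qs)[qi], df = df)
    })
  })
}

#' Translated search with class profiles (PSSMs)
#'
#' As [search_genome()], but each aligned column is scored by the profile's
#' position-specific log-odds; seeding uses the profile consensus and hit
#' identity is measured against it. The `query_id` of reported hits is
#' `profile:<class_label>`.
#'
#' @param profiles A single profile from [build_profile()] or a list of them.
#' @inheritParams search_genome
#' @return Hit data frame as in [search_genome()].
#' @export
profile_search <- function(profiles, genome, params = search_params()) {
  if (inherits(profiles, "nlr_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("empty input: no profiles")
  stopifnot(all(vapply(profiles, inherits, logical(1), "nlr_profile")))
  genome <- .as_dna_set(genome)
  if (length(genome) == 0L) stop("empty input: no genome sequences")
  prepped <- lapply(profiles, function(p) {
    list(id = paste0("profile:", p$class_label), m128 = .pssm128(p$scores),
         consensus = p$consensus, ncol = p$ncol)
  })
  .search_frames(genome, params, function(pep) {
    lapply(prepped, function(p) {
      df <- cpp_search_pssm(p$m128, p$consensus, pep, params$gap_open,
                            params$gap_extend, params$gap_cap,
                            params$x_drop,
                            params$min_hit_score, params$k,
                            if (p$ncol < 30L) 1L else params$min_seeds,
                            .mode_full(params, p$ncol, nchar(pep)),
                            params$max_hits)
      list(query_id = p$id, df = df)
    })
  })
}

.as_aa_set <- function(x) {
  if (methods::is(x, "AAStringSet")) return(x)
  out <- Biostrings::AAStringSet(toupper(as.character(x)))
  # the constructor drops names from length-1 character input
  if (is.null(names(out))) names(out) <- names(x)
  out
}

.as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- "seq"
    return(out)
  }
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  if (is.null(names(out))) names(out) <- names(x)
  out
}
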