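# Independent test oracles. These deliberately use different machinery than
# the package (Biostrings dynamic programming, per-base bit vectors, plain
# character loops) so that agreement is evidence, not tautology.

AA20_H <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Smith-Waterman oracle: Biostrings full-DP local alignment under the same
# scoring model (gap of length L costs gapOpening + L * gapExtension).
oracle_local_score <- function(q, s, gap_open = 11, gap_extend = 1) {
  suppressWarnings(
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s),
      substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
      gapExtension = gap_extend, type = "local", scoreOnly = TRUE))
}

# random peptide of length n from the 20-letter alphabet
random_peptide <- function(n) {
  paste(sample(AA20_H, n, replace = TRUE), collapse = "")
}

# a (query, subject) pair sharing a planted identical core, so the seeded
# search regime (exact k-mer seeds) is guaranteed applicable
seeded_pair <- function(max_len = 60L) {
  core_len <- sample(15:25, 1L)
  core <- random_peptide(core_len)
  pad <- function() {
    extra <- sample(0:(max_len - core_len), 1L)
    left <- sample(0:extra, 1L)
    paste0(random_peptide(left), core, random_peptide(extra - left))
  }
  list(q = pad(), s = pad())
}

# per-base interval union oracle: paint covered bases, read off runs
oracle_merge <- function(starts, ends) {
  if (!length(starts)) return(matrix(integer(0), 0L, 2L))
  lo <- min(starts)
  hi <- max(ends)
  cov <- logical(hi - lo)
  for (i in seq_along(starts)) {
    cov[(starts[i] - lo + 1L):(ends[i] - lo)] <- TRUE
  }
  r <- rle(cov)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  cbind(start = lo + begins[keep] - 1L, end = lo + stops[keep])
}

# per-base chaining oracle: dilate each interval by max_gap to the right,
# read off runs, then trim each run back to the last truly covered base
oracle_chain <- function(starts, ends, max_gap) {
  if (!length(starts)) return(matrix(integer(0), 0L, 2L))
  lo <- min(starts)
  hi <- max(ends) + max_gap
  cov <- logical(hi - lo)
  real <- logical(hi - lo)
  for (i in seq_along(starts)) {
    cov[(starts[i] - lo + 1L):(ends[i] - lo + max_gap)] <- TRUE
    real[(starts[i] - lo + 1L):(ends[i] - lo)] <- TRUE
  }
  r <- rle(cov)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  out <- NULL
  for (k in which(keep)) {
    span <- begins[k]:stops[k]
    covered <- span[real[span]]
    out <- rbind(out, c(lo + covered[1L] - 1L,
                        lo + covered[length(covered)]))
  }
  colnames(out) <- c("start", "end")
  out
}

# plain character-loop LRR motif oracle: [LIVF]..[LIVF].[LIVF]..N.[LIVF]
# at every position (overlaps allowed), never spanning a stop
oracle_lrr_motifs <- function(peptide) {
  ch <- strsplit(peptide, "")[[1]]
  n <- length(ch)
  L <- c("L", "I", "V", "F")
  hits <- integer(0)
  if (n >= 11L) {
    for (i in seq_len(n - 10L)) {
      w <- ch[i:(i + 10L)]
      if (any(w == "*")) next
      if (w[1] %in% L && w[4] %in% L && w[6] %in% L && w[9] == "N" &&
          w[11] %in% L) {
        hits <- c(hits, i - 1L)
      }
    }
  }
  hits
}

# independent LRR domain-presence oracle built on the motif oracle
oracle_lrr_present <- function(peptide, min_repeats = 2L, window = 120L) {
  m <- oracle_lrr_motifs(peptide)
  if (length(m) < min_repeats) return(FALSE)
  stops <- which(strsplit(peptide, "")[[1]] == "*") - 1L
  stretch <- vapply(m, function(p) sum(stops < p), integer(1))
  for (s in unique(stretch)) {
    pos <- m[stretch == s]
    for (i in seq_along(pos)) {
      j <- sum(pos - pos[i] <= window & pos >= pos[i])
      if (j >= min_repeats) return(TRUE)
    }
  }
  FALSE
}

# small deterministic simulated genome shared by pipeline-level tests:
# one retained CNL (with a 500 bp intron), one truncated TNL, one LRR-less NL
small_test_sim <- function(seed = 11L) {
  specs <- list(
    gene_spec("CNL", "ref_CNL_1", identity_to_source = 0.9,
              introns = data.frame(codon = 120L, size = 500L)),
    gene_spec("TNL", "ref_TNL_1", identity_to_source = 0.9,
              truncation_frac = 0.6, strand = "-"),
    gene_spec("NL", "ref_NL_1", identity_to_source = 0.9, has_lrr = FALSE))
  generate_genome(specs, 120000L, seed = seed)
}
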