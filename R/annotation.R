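# Annotation of candidate loci over a +/- 10 kb window: ORFs in six frames,
# LRR motif arrays, coiled-coil heptads, TIR/RPW8 profile matches, NLR class
# assignment and the LRR-presence retention filter. These in-house detectors
# play the curation-support role InterProScan plays in annotation-driven
# screens; the LRR call is the only one that gates retention.

#' Annotation parameters
#'
#' @param flank Flanking window on each side of a locus, bp.
#' @param min_aa Minimum ORF length in codons (excluding the stop).
#' @param lrr_pattern `"canonical"` (default) — the plant LRR core
#'   LxxLxLxxNxL with L in \{L,I,V,F\}; `"core"` — the bare 8-mer LxxLxLxx.
#'   The canonical form includes the conserved asparagine; the bare 8-mer is
#'   too permissive on six-frame translations of non-coding DNA (hydrophobic
#'   codon bias) to act as a retention filter.
#' @param lrr_min_repeats Motif copies required within `lrr_window` residues
#'   of one stop-free stretch for an LRR domain call. Real LRR domains carry
#'   many tandem repeats; a single pair of canonical 11-mers is within the
#'   background noise of six-frame translations of AT-rich DNA (measured:
#'   roughly one spurious pair-cluster per ten 20 kb windows, versus none in
#'   300 windows when three clustered copies are required).
#' @param lrr_window Clustering window, residues.
#' @param cc_window Coiled-coil window length, residues (4 heptads).
#' @param cc_hydrophobic Residues accepted at heptad a/d positions.
#' @param cc_max_other Maximum hydrophobic residues tolerated at non-a/d
#'   positions of a qualifying coiled-coil window (see
#'   [detect_coiled_coil()]).
#' @param nterm_score_frac TIR/RPW8 call threshold as a fraction of the
#'   profile's consensus self-score.
#' @param nterm_upstream How far upstream (strand-aware, bp) of the locus
#'   the N-terminal domain scan reaches. N-terminal domains sit directly
#'   before the NB-ARC, so a short window keeps the coiled-coil heuristic's
#'   false-positive exposure low; the LRR scan still covers the full flank.
#' @param lrr_filter Whether the LRR-presence filter removes candidates.
#' @return List of class `nlr_annotate_params`.
#' @export
annotate_params <- function(flank = 10000L, min_aa = 50L,
                            lrr_pattern = c("canonical", "core"),
                            lrr_min_repeats = 3L, lrr_window = 120L,
                            cc_window = 28L,
                            cc_hydrophobic = c("L", "I", "V", "M", "F", "A"),
                            cc_max_other = 4L, nterm_score_frac = 0.5,
                            nterm_upstream = 3000L, lrr_filter = TRUE) {
  lrr_pattern <- match.arg(lrr_pattern)
  stopifnot(flank >= 0, min_aa >= 1, lrr_min_repeats >= 1, lrr_window >= 8,
            cc_window >= 7, cc_max_other >= 0, nterm_score_frac > 0,
            nterm_score_frac <= 1, nterm_upstream >= 0)
  structure(list(flank = as.integer(flank), min_aa = as.integer(min_aa),
                 lrr_pattern = lrr_pattern,
                 lrr_min_repeats = as.integer(lrr_min_repeats),
                 lrr_window = as.integer(lrr_window),
                 cc_window = as.integer(cc_window),
                 cc_hydrophobic = cc_hydrophobic,
                 cc_max_other = as.integer(cc_max_other),
                 nterm_score_frac = nterm_score_frac,
                 nterm_upstream = as.integer(nterm_upstream),
                 lrr_filter = isTRUE(lrr_filter)),
            class = "nlr_annotate_params")
}

#' Extract the flanking region of a locus
#'
#' @param locus One-row locus data frame (or list) with `contig`, `start`,
#'   `end`, `locus_id`.
#' @param genome Named `DNAStringSet`.
#' @param flank Flank size in bp on each side; clipped at contig bounds.
#' @return List of class `nlr_region`: `contig`, `start`, `end` (0-based
#'   half-open), `locus_ref`, `seq` (character), `clipped_left`,
#'   `clipped_right`.
#' @export
extract_flanking <- function(locus, genome, flank = 10000L) {
  genome <- .as_dna_set(genome)
  contig <- genome[[locus$contig]]
  len <- length(contig)
  start <- max(0L, locus$start - as.integer(flank))
  end <- min(len, locus$end + as.integer(flank))
  structure(list(contig = locus$contig, start = start, end = end,
                 locus_ref = locus$locus_id,
                 seq = as.character(Biostrings::subseq(contig, start + 1L,
                                                       end)),
                 clipped_left = start == 0L && locus$start - flank < 0L,
                 clipped_right = end == len && locus$end + flank > len),
            class = "nlr_region")
}

.empty_calls <- function() {
  data.frame(kind = character(0), r_start = integer(0), r_end = integer(0),
             g_start = integer(0), g_end = integer(0), strand = character(0),
             frame = integer(0), score = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

.call_row <- function(region, kind, r_start, r_end, strand, frame, score,
                      source) {
  data.frame(kind = kind, r_start = as.integer(r_start),
             r_end = as.integer(r_end),
             g_start = region$start + as.integer(r_start),
             g_end = region$start + as.integer(r_end), strand = strand,
             frame = as.integer(frame), score = score, source = source,
             stringsAsFactors = FALSE)
}

#' Find ORFs in a region
#'
#' Reports all maximal ATG-to-stop ORFs of at least `min_aa` codons in all
#' six frames, with strand-correct genomic coordinates that include the stop
#' codon. ORFs without a stop codon are not reported.
#'
#' @param region An `nlr_region` from [extract_flanking()].
#' @param min_aa Minimum ORF length in codons, excluding the stop.
#' @return Data frame of `kind = "ORF"` domain calls.
#' @export
find_orfs <- function(region, min_aa = 50L) {
  len <- nchar(region$seq)
  frames <- six_frame_translate(region$seq)
  out <- list()
  for (fr in frames) {
    pep <- fr$peptide
    if (!nzchar(pep)) next
    stops <- c(0L, gregexpr("\\*", pep)[[1L]])
    if (length(stops) == 2L && stops[2L] == -1L) next # no stop, no ORF
    stops <- stops[stops >= 0L]
    for (si in seq_len(length(stops) - 1L)) {
      seg_start <- stops[si] + 1L            # 1-based peptide position
      seg_stop <- stops[si + 1L]             # position of '*'
      seg <- substr(pep, seg_start, seg_stop - 1L)
      m <- regexpr("M", seg, fixed = TRUE)
      if (m < 0L) next
      atg <- seg_start + as.integer(m) - 1L  # 1-based position of the M
      n_codons <- seg_stop - atg             # excludes the stop
      if (n_codons < min_aa) next
      g <- .frame_to_genomic(fr$frame, atg - 1L, seg_stop, len) # incl stop
      out[[length(out) + 1L]] <- .call_row(
        region, "ORF", g[1L], g[2L],
        if (fr$frame > 0) "+" else "-", fr$frame, n_codons, "orf_finder")
    }
  }
  if (!length(out)) return(.empty_calls())
  res <- do.call(rbind, out)
  res[order(res$r_start, res$r_end), , drop = FALSE]
}

.lrr_regex <- function(pattern) {
  # wildcard positions exclude '*': a motif never spans a stop codon
  switch(pattern,
         core = "(?=[LIVF][^*][^*][LIVF][^*][LIVF][^*][^*])",
         canonical =
           "(?=[LIVF][^*][^*][LIVF][^*][LIVF][^*][^*]N[^*][LIVF])")
}

.lrr_motif_len <- function(pattern) if (pattern == "core") 8L else 11L

#' Detect LRR motif arrays in a peptide
#'
#' Scans for the plant LRR core motif (overlapping matches allowed) and
#' reports an LRR domain wherever at least `min_repeats` motif copies fall
#' within `window` residues of each other inside one stop-free stretch.
#'
#' @param peptide Character peptide (may contain `*`; motifs never span a
#'   stop and repeat copies are clustered within stop-free stretches, since a
#'   real LRR array is uninterrupted coding sequence).
#' @param min_repeats Motif copies required for a domain call.
#' @param window Maximum span between consecutive clustered motifs, residues.
#' @param pattern `"canonical"` (LxxLxLxxNxL) or `"core"` (LxxLxLxx).
#' @return List with `motifs` (0-based start positions of all matches) and
#'   `domains` (two-column matrix of 0-based half-open domain spans).
#' @examples
#' detect_lrr("LSELDLSNNKL", min_repeats = 1)$motifs # 0
#' @export
detect_lrr <- function(peptide, min_repeats = 3L, window = 120L,
                       pattern = c("canonical", "core")) {
  pattern <- match.arg(pattern)
  peptide <- toupper(as.character(peptide))
  if (!nzchar(peptide)) stop("empty peptide")
  rx <- .lrr_regex(pattern)
  mlen <- .lrr_motif_len(pattern)
  m <- gregexpr(rx, peptide, perl = TRUE)[[1L]]
  motifs <- if (m[1L] < 0L) integer(0) else as.integer(m) - 1L
  domains <- NULL
  if (length(motifs)) {
    # stop-free stretch index for each motif start
    stretch <- cumsum(strsplit(peptide, "")[[1L]] == "*")
    sid <- stretch[motifs + 1L]
    for (s in unique(sid)) {
      pos <- motifs[sid == s]
      # greedy clustering: consecutive motifs within `window` of the
      # cluster's first motif
      i <- 1L
      while (i <= length(pos)) {
        j <- i
        while (j < length(pos) && pos[j + 1L] - pos[i] <= window) j <- j + 1L
        if (j - i + 1L >= min_repeats) {
          domains <- rbind(domains, c(pos[i], pos[j] + mlen))
        }
        i <- j + 1L
      }
    }
  }
  if (is.null(domains)) domains <- matrix(integer(0), 0L, 2L)
  colnames(domains) <- c("start", "end")
  list(motifs = motifs, domains = domains)
}

#' Detect coiled-coil segments by heptad hydrophobicity
#'
#' Slides a `window`-residue window over the peptide; for each of the 7
#' heptad phases, scores the fraction of a/d positions holding a hydrophobic
#' residue. A window qualifies when some phase reaches `min_frac` at a/d
#' with at most `max_other` hydrophobic residues at the remaining (b,c,e,f,g)
#' positions — amphipathy, not mere hydrophobicity — and the window is
#' stop-free; overlapping qualifying windows are merged.
#'
#' The `max_other` cap suppresses false calls on six-frame translations of
#' non-coding DNA, whose hydrophobic-rich codon spectrum otherwise satisfies
#' the a/d rule by chance; an ideal amphipathic helix such as
#' `"LEALEGK"` repeated 4 times has 8/8 hydrophobic a/d positions and exactly 4
#' hydrophobic residues elsewhere, so it passes.
#'
#' @param peptide Character peptide.
#' @param window Window length in residues (default 28 = 4 heptads).
#' @param hydrophobic Residues counted as hydrophobic at a/d positions.
#' @param min_frac Required a/d hydrophobic fraction (default 1: all 8
#'   positions of a 28-residue window).
#' @param max_other Maximum hydrophobic residues tolerated at non-a/d
#'   positions of the qualifying phase (default 4 of 20, the count in the
#'   ideal amphipathic heptad).
#' @return Two-column matrix of 0-based half-open CC spans (possibly empty).
#' @export
detect_coiled_coil <- function(peptide, window = 28L,
                               hydrophobic = c("L", "I", "V", "M", "F", "A"),
                               min_frac = 1, max_other = 4L) {
  chars <- strsplit(toupper(as.character(peptide)), "")[[1L]]
  n <- length(chars)
  if (n < window) return(matrix(integer(0), 0L, 2L,
                                dimnames = list(NULL, c("start", "end"))))
  hyd <- chars %in% hydrophobic
  stp <- chars == "*"
  stop_cum <- cumsum(stp)
  qual <- logical(n - window + 1L)
  for (w0 in seq_len(n - window + 1L)) {
    if ((if (w0 == 1L) stop_cum[w0 + window - 1L]
         else stop_cum[w0 + window - 1L] - stop_cum[w0 - 1L]) > 0L) next
    win <- w0:(w0 + window - 1L)
    n_hyd <- sum(hyd[win])
    for (ph in 0:6) {
      ad <- w0 + sort(c(seq(ph, window - 1L, by = 7L),
                        seq((ph + 3L) %% 7L, window - 1L, by = 7L)))
      ad <- ad[ad <= w0 + window - 1L]
      n_ad <- sum(hyd[ad])
      if (n_ad / length(ad) >= min_frac && n_hyd - n_ad <= max_other) {
        qual[w0] <- TRUE
        break
      }
    }
  }
  if (!any(qual)) return(matrix(integer(0), 0L, 2L,
                                dimnames = list(NULL, c("start", "end"))))
  idx <- which(qual)
  runs <- split(idx, cumsum(c(1L, diff(idx) > 1L)))
  out <- t(vapply(runs, function(r) c(r[1L] - 1L, r[length(r)] - 1L + window),
                  integer(2)))
  colnames(out) <- c("start", "end")
  out
}

#' Detect N-terminal domains (TIR, RPW8, coiled-coil) in a peptide
#'
#' TIR and RPW8 are called when the best local profile score exceeds
#' `nterm_score_frac` of the profile's consensus self-score; CC by the
#' heptad heuristic of [detect_coiled_coil()].
#'
#' @param peptide Character peptide.
#' @param profiles Named list with `TIR` and `RPW8` `nlr_profile` objects;
#'   defaults to the bundled synthetic detector panels.
#' @param params [annotate_params()].
#' @param search [search_params()] for gap penalties.
#' @return Data frame with columns `kind`, `start`, `end` (0-based half-open
#'   peptide coordinates), `score`.
#' @export
detect_nterm_domains <- function(peptide, profiles = detector_profiles(),
                                 params = annotate_params(),
                                 search = search_params()) {
  if (is.null(profiles$TIR) || is.null(profiles$RPW8))
    stop("configuration error: TIR/RPW8 detector profiles missing")
  peptide <- toupper(as.character(peptide))
  out <- list()
  for (kind in c("TIR", "RPW8")) {
    p <- profiles[[kind]]
    thr <- params$nterm_score_frac * sum(apply(p$scores, 1L, max))
    df <- cpp_search_pssm(.pssm128(p$scores), p$consensus, peptide,
                          search$gap_open, search$gap_extend, search$gap_cap,
                          search$x_drop, thr, search$k, 1L, TRUE, 5L)
    if (nrow(df)) {
      out[[length(out) + 1L]] <- data.frame(
        kind = kind, start = df$s_start, end = df$s_end, score = df$score,
        stringsAsFactors = FALSE)
    }
  }
  cc <- detect_coiled_coil(peptide, window = params$cc_window,
                           hydrophobic = params$cc_hydrophobic,
                           max_other = params$cc_max_other)
  if (nrow(cc)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = "CC", start = cc[, "start"], end = cc[, "end"],
      score = NA_real_, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Assign the NLR class from domain calls
#'
#' TIR present -> TNL; else RPW8 -> RNL; else CC -> CNL; else NL. The
#' precedence handles rare co-occurrence of N-terminal signals.
#'
#' @param kinds Character vector of domain kinds present at a candidate
#'   (subset of `c("TIR", "RPW8", "CC", "NB-ARC", "LRR", "ORF")`).
#' @return One of `"TNL"`, `"RNL"`, `"CNL"`, `"NL"`.
#' @export
classify_nlr <- function(kinds) {
  if ("TIR" %in% kinds) "TNL"
  else if ("RPW8" %in% kinds) "RNL"
  else if ("CC" %in% kinds) "CNL"
  else "NL"
}

#' Annotate candidate loci
#'
#' For each locus: extracts the flanking region, finds ORFs, scans all six
#' frames of the whole region for LRR arrays (so split LRR exons still
#' count), scans the strand-aware upstream portion plus the locus itself for
#' N-terminal domains (TIR/RPW8/CC), records the locus as an NB-ARC call,
#' and assigns the NLR class.
#'
#' @param loci Loci data frame (from [length_filter()]), one row per
#'   candidate.
#' @param genome Named `DNAStringSet`.
#' @param params [annotate_params()].
#' @param search [search_params()].
#' @param profiles Detector profiles, see [detect_nterm_domains()].
#' @return The loci data frame with added columns: `class_label`, `has_lrr`,
#'   `retained` (equal to `has_lrr` when the LRR filter is enabled, else
#'   `TRUE`), plus list-columns `calls` (domain-call data frame per locus)
#'   and `region` (the `nlr_region`).
#' @export
annotate_candidates <- function(loci, genome, params = annotate_params(),
                                search = search_params(),
                                profiles = detector_profiles()) {
  genome <- .as_dna_set(genome)
  n <- nrow(loci)
  calls_l <- vector("list", n)
  region_l <- vector("list", n)
  class_v <- character(n)
  lrr_v <- logical(n)
  for (i in seq_len(n)) {
    locus <- loci[i, , drop = FALSE]
    region <- extract_flanking(locus, genome, params$flank)
    calls <- .call_row(region, "NB-ARC", locus$start - region$start,
                       locus$end - region$start, locus$strand, 0L,
                       locus$score, "nbarc_search")
    calls <- rbind(calls, find_orfs(region, params$min_aa))
    # LRR: all six frames of the whole region, either strand
    rlen <- nchar(region$seq)
    for (fr in six_frame_translate(region$seq)) {
      if (!nzchar(fr$peptide)) next
      doms <- detect_lrr(fr$peptide, params$lrr_min_repeats,
                         params$lrr_window, params$lrr_pattern)$domains
      for (d in seq_len(nrow(doms))) {
        g <- .frame_to_genomic(fr$frame, doms[d, "start"], doms[d, "end"],
                               rlen)
        calls <- rbind(calls, .call_row(region, "LRR", g[1L], g[2L],
                                        if (fr$frame > 0) "+" else "-",
                                        fr$frame, NA_real_, "lrr_motif"))
      }
    }
    # N-terminal domains: upstream (strand-aware) + the locus, locus strand
    nt <- .nterm_subregion(region, locus, params$nterm_upstream)
    if (nchar(nt$seq) >= 3L) {
      for (fr in six_frame_translate(nt$seq)) {
        same_strand <- (fr$frame > 0) == (locus$strand == "+")
        if (!same_strand || !nzchar(fr$peptide)) next
        hits <- detect_nterm_domains(fr$peptide, profiles, params, search)
        for (r in seq_len(nrow(hits))) {
          g <- .frame_to_genomic(fr$frame, hits$start[r], hits$end[r],
                                 nchar(nt$seq))
          calls <- rbind(calls, .call_row(
            region, hits$kind[r], nt$offset + g[1L], nt$offset + g[2L],
            locus$strand, fr$frame, hits$score[r],
            if (hits$kind[r] == "CC") "cc_heptad" else "nterm_pssm"))
        }
      }
    }
    calls_l[[i]] <- calls
    region_l[[i]] <- region
    class_v[i] <- classify_nlr(unique(calls$kind))
    lrr_v[i] <- "LRR" %in% calls$kind
  }
  loci$class_label <- class_v
  loci$has_lrr <- lrr_v
  loci$retained <- if (params$lrr_filter) lrr_v else rep(TRUE, n)
  loci$calls <- I(calls_l)
  loci$region <- I(region_l)
  loci
}

# region-relative window covering (up to) `upstream` bp of strand-aware
# upstream flank + the locus itself
.nterm_subregion <- function(region, locus, upstream = 3000L) {
  if (locus$strand == "+") {
    r0 <- max(0L, locus$start - region$start - as.integer(upstream))
    r1 <- locus$end - region$start
  } else {
    r0 <- locus$start - region$start
    r1 <- min(region$end - region$start,
              locus$end - region$start + as.integer(upstream))
  }
  list(seq = substr(region$seq, r0 + 1L, r1), offset = r0)
}

#' Apply the LRR-presence filter
#'
#' Retains candidates with at least one LRR domain call anywhere in their
#' flanking region (any frame, either strand).
#'
#' @param annotated Output of [annotate_candidates()].
#' @param enabled If `FALSE`, all candidates pass (config passthrough).
#' @return The retained subset.
#' @export
lrr_filter <- function(annotated, enabled = TRUE) {
  if (!enabled) return(annotated)
  annotated[annotated$has_lrr, , drop = FALSE]
}
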