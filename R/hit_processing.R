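# From raw hits to candidate NB-ARC loci: per-strand interval union, chaining
# of same-strand neighbours across small introns/divergent stretches, and the
# "greater than 80% of the most similar NB-ARC sequence" retention rule.

#' Chaining parameters
#'
#' @param max_gap Maximum nucleotide separation (next block start minus
#'   previous block end) for two merged blocks to be chained into one locus.
#'   The 1 kb default reflects the typical plant intron size distribution;
#'   NB-ARC introns larger than this split a gene into separate loci, which
#'   then usually fail the length rule — a documented limitation.
#' @param min_len_frac Retention threshold: a locus is kept iff its aligned
#'   coverage of the most similar query exceeds this fraction (strictly).
#' @return A list of class `nlr_chain_params`.
#' @export
chain_params <- function(max_gap = 1000L, min_len_frac = 0.8) {
  if (max_gap < 0) stop("parameter error: max_gap must be >= 0")
  stopifnot(min_len_frac > 0, min_len_frac <= 1)
  structure(list(max_gap = as.integer(max_gap), min_len_frac = min_len_frac),
            class = "nlr_chain_params")
}

#' Merge overlapping hits into blocks
#'
#' Within each `(contig, strand)` group, computes the connected components of
#' the interval overlap graph (touching intervals merge too) and records, per
#' block, the contributing hits and the single best-scoring one.
#'
#' @param hits Hit data frame from [search_genome()]/[profile_search()].
#' @return A data frame of blocks: `contig`, `strand`, `start`, `end`,
#'   `n_hits`, `best_score`, `best_query_id`, `best_frame`, `best_g_start`,
#'   plus a `hits` list-column holding each block's contributing hit rows.
#' @export
merge_overlapping <- function(hits) {
  out <- list()
  if (!is.null(hits) && nrow(hits) > 0) {
    grp <- split(seq_len(nrow(hits)),
                 paste(hits$contig, hits$strand, sep = "\r"))
    for (idx in grp) {
      sub <- hits[idx, , drop = FALSE]
      ir <- IRanges::IRanges(start = sub$g_start + 1L, end = sub$g_end)
      red <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(ir, red)
      comp <- integer(nrow(sub))
      comp[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
      for (b in seq_along(red)) {
        members <- sub[comp == b, , drop = FALSE]
        best <- .best_hit_row(members)
        out[[length(out) + 1L]] <- data.frame(
          contig = members$contig[1L], strand = members$strand[1L],
          start = IRanges::start(red)[b] - 1L, end = IRanges::end(red)[b],
          n_hits = nrow(members), best_score = members$score[best],
          best_query_id = members$query_id[best],
          best_frame = members$frame[best],
          best_g_start = members$g_start[best],
          hits = I(list(members)), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_hits = integer(0), best_score = numeric(0),
                      best_query_id = character(0), best_frame = integer(0),
                      best_g_start = integer(0), hits = I(list()),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# best = max score; ties broken by longer query span then lexicographic id
.best_hit_row <- function(members) {
  ord <- order(-members$score, -(members$q_end - members$q_start),
               members$query_id, method = "radix")
  ord[1L]
}

#' Chain adjacent blocks into candidate loci
#'
#' Consecutive blocks on the same contig and strand separated by at most
#' `max_gap` bp are chained into one locus whose segments are the blocks;
#' larger gaps start a new locus.
#'
#' @param blocks Output of [merge_overlapping()].
#' @param max_gap Maximum inter-block gap in bp (end-to-start distance).
#' @return A data frame of loci: `locus_id`, `contig`, `strand`, `start`,
#'   `end`, `n_segments`, `score` (sum of per-block best scores), a
#'   `segments` list-column (matrices with columns `start`, `end`, `frame`,
#'   `anchor` — the per-block best hit's frame and genomic start, used later
#'   for phase-correct peptide extraction) and a `hits` list-column.
#' @export
chain_adjacent <- function(blocks, max_gap = 1000L) {
  if (max_gap < 0) stop("parameter error: max_gap must be >= 0")
  loci <- list()
  if (nrow(blocks) > 0) {
    grp <- split(seq_len(nrow(blocks)),
                 paste(blocks$contig, blocks$strand, sep = "\r"))
    for (idx in grp) {
      sub <- blocks[idx, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      gap <- c(Inf, sub$start[-1L] - sub$end[-nrow(sub)])
      chain_id <- cumsum(gap > max_gap)
      for (ch in split(seq_len(nrow(sub)), chain_id)) {
        seg <- sub[ch, , drop = FALSE]
        segments <- cbind(start = seg$start, end = seg$end,
                          frame = seg$best_frame, anchor = seg$best_g_start)
        allhits <- do.call(rbind, seg$hits)
        loci[[length(loci) + 1L]] <- data.frame(
          contig = seg$contig[1L], strand = seg$strand[1L],
          start = seg$start[1L], end = seg$end[nrow(seg)],
          n_segments = nrow(seg), score = sum(seg$best_score),
          segments = I(list(segments)), hits = I(list(allhits)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(loci)) {
    return(data.frame(locus_id = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), n_segments = integer(0),
                      score = numeric(0), segments = I(list()),
                      hits = I(list()), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, loci)
  res <- res[order(res$contig, res$start, res$strand, method = "radix"), ,
             drop = FALSE]
  res <- cbind(locus_id = sprintf("%s_%d_%d_%s", res$contig, res$start,
                                  res$end, ifelse(res$strand == "+", "p", "m")),
               res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Apply the domain-completeness (80%) retention rule
#'
#' For each locus, the most similar query is the query of its highest-scoring
#' constituent hit (ties: longer query, then lexicographic id). The aligned
#' length is the number of distinct residues of that query covered across the
#' locus's hits (query overlaps counted once, so tandem duplications do not
#' inflate coverage). The locus is retained iff
#' `aligned_len / best_query_len > min_len_frac` (strict).
#'
#' @param loci Output of [chain_adjacent()].
#' @param query_lens Named numeric vector of query lengths (reference peptide
#'   lengths and/or profile column counts).
#' @param min_len_frac Retention threshold (default 0.8).
#' @param return_all If `TRUE`, return all loci with a `retained` flag
#'   instead of the retained subset.
#' @return Loci data frame with `best_query_id`, `best_query_len`,
#'   `aligned_len`, `coverage` and `retained` columns added.
#' @export
length_filter <- function(loci, query_lens, min_len_frac = 0.8,
                          return_all = FALSE) {
  if (nrow(loci) == 0) {
    loci$best_query_id <- character(0)
    loci$best_query_len <- integer(0)
    loci$aligned_len <- integer(0)
    loci$coverage <- numeric(0)
    loci$retained <- logical(0)
    return(loci)
  }
  info <- lapply(loci$hits, function(h) {
    best <- .best_hit_row(h)
    bq <- h$query_id[best]
    qh <- h[h$query_id == bq, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = qh$q_start + 1L,
                                           end = qh$q_end))
    list(bq = bq, aligned = sum(IRanges::width(ir)))
  })
  loci$best_query_id <- vapply(info, `[[`, character(1), "bq")
  unknown <- setdiff(loci$best_query_id, names(query_lens))
  if (length(unknown))
    stop("reference mismatch: unknown query id ", unknown[1L])
  loci$best_query_len <- as.integer(query_lens[loci$best_query_id])
  loci$aligned_len <- vapply(info, function(x) as.integer(x$aligned),
                             integer(1))
  loci$coverage <- loci$aligned_len / loci$best_query_len
  loci$retained <- loci$coverage > min_len_frac
  if (return_all) loci else loci[loci$retained, , drop = FALSE]
}
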