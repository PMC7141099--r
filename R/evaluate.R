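# Evaluation of pipeline candidates against a simulation truth table.

#' Evaluate candidates against a simulation truth table
#'
#' Matches candidate loci to true NB-ARC intervals by same-strand overlap of
#' at least one base, one-to-one: pairs are considered in decreasing order
#' of overlap length (ties broken by truth coordinate, then candidate
#' coordinate) and each truth gene and each candidate may be used once.
#'
#' Sensitivity is computed over the genes the method is *expected* to
#' recover (`expected_outcome == "retained"` in the truth table); recovered
#' genes from other archetypes are still reported in the per-archetype
#' breakdown but do not enter the sensitivity denominator.
#'
#' @param candidates Data frame with columns `contig`, `start`, `end`,
#'   `strand` (0-based half-open), e.g. retained loci from a pipeline run.
#' @param truth Truth data frame from [generate_genome()] (`$truth`), with
#'   columns `gene_id`, `contig`, `nbarc_start`, `nbarc_end`, `strand`,
#'   `expected_outcome`.
#' @return List of class `nlr_eval`: `matches` (data frame `gene_id`,
#'   `locus_id`, `overlap`), `n_truth`, `n_predicted`, `tp` (matched genes
#'   among the expected-retained ones), `n_expected`, `n_found` (alias of
#'   `tp`), `sensitivity`, `false_negatives` (gene ids),
#'   `extra_candidates` (candidate indices matching no truth gene),
#'   `by_outcome` (data frame `expected_outcome`, `n`, `n_detected`).
#'   Invariant: `tp + length(false_negatives)` equals the number of truth
#'   genes with `expected_outcome == "retained"`.
#' @export
evaluate_candidates <- function(candidates, truth) {
  stopifnot(is.data.frame(candidates), is.data.frame(truth))
  need_c <- c("contig", "start", "end", "strand")
  need_t <- c("gene_id", "contig", "nbarc_start", "nbarc_end", "strand",
              "expected_outcome")
  if (!all(need_c %in% names(candidates)))
    stop("candidates must have columns: ", paste(need_c, collapse = ", "))
  if (!all(need_t %in% names(truth)))
    stop("truth must have columns: ", paste(need_t, collapse = ", "))
  if (nrow(candidates) > 0 && nrow(truth) > 0 &&
      !any(candidates$contig %in% truth$contig))
    stop("no candidate contig matches any truth contig; ",
         "were these produced from the same genome?")

  # all overlapping same-strand pairs
  pairs <- NULL
  for (ti in seq_len(nrow(truth))) {
    sel <- which(candidates$contig == truth$contig[ti] &
                 candidates$strand == truth$strand[ti] &
                 candidates$start < truth$nbarc_end[ti] &
                 candidates$end > truth$nbarc_start[ti])
    for (ci in sel) {
      ov <- min(candidates$end[ci], truth$nbarc_end[ti]) -
            max(candidates$start[ci], truth$nbarc_start[ti])
      pairs <- rbind(pairs, data.frame(ti = ti, ci = ci, overlap = ov))
    }
  }
  matched_t <- integer(0)
  matched_c <- integer(0)
  matches <- data.frame(gene_id = character(0), locus_id = character(0),
                        overlap = integer(0), stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs$overlap, truth$nbarc_start[pairs$ti],
                         candidates$start[pairs$ci]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      ti <- pairs$ti[r]; ci <- pairs$ci[r]
      if (ti %in% matched_t || ci %in% matched_c) next
      matched_t <- c(matched_t, ti)
      matched_c <- c(matched_c, ci)
      lid <- if ("locus_id" %in% names(candidates))
        candidates$locus_id[ci] else as.character(ci)
      matches <- rbind(matches, data.frame(
        gene_id = truth$gene_id[ti], locus_id = lid,
        overlap = as.integer(pairs$overlap[r]), stringsAsFactors = FALSE))
    }
  }
  detected <- logical(nrow(truth))
  detected[matched_t] <- TRUE
  expected <- truth$expected_outcome == "retained"
  n_expected <- sum(expected)
  n_found <- sum(expected & detected)
  by_outcome <- do.call(rbind, lapply(
    split(seq_len(nrow(truth)), truth$expected_outcome), function(idx)
      data.frame(expected_outcome = truth$expected_outcome[idx[1L]],
                 n = length(idx), n_detected = sum(detected[idx]),
                 stringsAsFactors = FALSE)))
  if (is.null(by_outcome))
    by_outcome <- data.frame(expected_outcome = character(0), n = integer(0),
                             n_detected = integer(0))
  rownames(by_outcome) <- NULL
  structure(list(
    matches = matches,
    n_truth = nrow(truth),
    n_predicted = nrow(candidates),
    tp = n_found,
    sensitivity = if (n_expected == 0) NA_real_ else n_found / n_expected,
    n_expected = n_expected,
    n_found = n_found,
    false_negatives = truth$gene_id[expected & !detected],
    extra_candidates = setdiff(seq_len(nrow(candidates)), matched_c),
    by_outcome = by_outcome), class = "nlr_eval")
}

#' @export
print.nlr_eval <- function(x, ...) {
  cat(sprintf("nlr_eval: %d/%d expected genes recovered (sensitivity %.3f)\n",
              x$n_found, x$n_expected,
              if (is.na(x$sensitivity)) NA else x$sensitivity))
  cat(sprintf("  extra candidates: %d\n", length(x$extra_candidates)))
  if (nrow(x$by_outcome)) {
    cat("  by archetype:\n")
    for (i in seq_len(nrow(x$by_outcome)))
      cat(sprintf("    %-16s %d/%d detected\n",
                  x$by_outcome$expected_outcome[i],
                  x$by_outcome$n_detected[i], x$by_outcome$n[i]))
  }
  invisible(x)
}

#' Read a 6-column BED file
#'
#' @param path BED file path.
#' @return `nlr_bed` data frame (`contig`, `start`, `end`, `name`, `score`,
#'   `strand`; coordinates 0-based half-open as in the file).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (!length(lines))
    return(bed_intervals(character(0), integer(0), integer(0))[0, ])
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6L)) stop("BED line with fewer than 6 columns")
  bed_intervals(vapply(f, `[`, "", 1L),
                as.integer(vapply(f, `[`, "", 2L)),
                as.integer(vapply(f, `[`, "", 3L)),
                vapply(f, `[`, "", 4L),
                as.numeric(vapply(f, `[`, "", 5L)),
                vapply(f, `[`, "", 6L))
}

# truth from either truth.tsv or truth.gff3 (gene features carry class and
# expected_outcome attributes; NB-ARC spans come from protein_match children)
.read_truth <- function(path) {
  if (grepl("\\.(gff3?|gff)$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    attr1 <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]*)"), a))[[1L]]
      if (length(m)) m[3L] else NA_character_
    }
    genes <- list(); nbarc <- list()
    for (x in f) {
      a <- x[9L]
      if (x[3L] == "gene") {
        genes[[attr1(a, "ID")]] <- list(
          class = attr1(a, "class"), outcome = attr1(a, "expected_outcome"))
      } else if (x[3L] == "protein_match" &&
                 identical(attr1(a, "Name"), "NB-ARC")) {
        parent <- attr1(a, "Parent")
        nbarc[[parent]] <- data.frame(
          gene_id = parent, contig = x[1L],
          nbarc_start = as.integer(x[4L]) - 1L, nbarc_end = as.integer(x[5L]),
          strand = x[7L], stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, nbarc)
    if (is.null(truth)) stop("no NB-ARC protein_match features in ", path)
    truth$class_label <- vapply(truth$gene_id,
                                function(g) genes[[g]]$class, character(1))
    truth$expected_outcome <- vapply(truth$gene_id,
                                     function(g) genes[[g]]$outcome,
                                     character(1))
    rownames(truth) <- NULL
    truth
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
}

#' Evaluate a candidates BED file against a truth file
#'
#' File-level front end to [evaluate_candidates()]: reads a 6-column BED of
#' predicted loci and a truth table (`truth.tsv`) or truth GFF3
#' (`truth.gff3`) as written by [write_simulation()], and optionally writes
#' a small TSV summary.
#'
#' @param bed_path Path to the candidates BED.
#' @param truth_path Path to `truth.tsv` or `truth.gff3`.
#' @param out_path If non-`NULL`, the summary TSV is written here.
#' @return An `nlr_eval` (invisibly if `out_path` is given).
#' @export
evaluate_files <- function(bed_path, truth_path, out_path = NULL) {
  bed <- read_bed(bed_path)
  names(bed)[names(bed) == "name"] <- "locus_id"
  ev <- evaluate_candidates(bed, .read_truth(truth_path))
  if (!is.null(out_path)) {
    summ <- data.frame(
      metric = c("n_truth", "n_predicted", "n_expected_retained",
                 "true_positives", "false_negatives", "extra_candidates",
                 "sensitivity"),
      value = c(ev$n_truth, ev$n_predicted, ev$n_expected, ev$tp,
                length(ev$false_negatives), length(ev$extra_candidates),
                round(ev$sensitivity, 6)), stringsAsFactors = FALSE)
    write.table(summ, out_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(ev))
  }
  ev
}
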