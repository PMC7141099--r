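# FASTA in, BED/GFF3 out. All internal coordinates are 0-based half-open;
# conversion to GFF3's 1-based closed convention happens only at write time.

#' Read a FASTA file
#'
#' Reads plain or line-wrapped FASTA. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description. Sequences are uppercased (soft-masking is not honoured).
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"`, `"AA"`, or `"auto"` (default): alphabet of the
#'   returned set. `"auto"` guesses from residue composition.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] with the
#'   ids as names and a `description` metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test contig", "acgtACGT"), fa)
#' read_fasta(fa, type = "DNA")
#' @export
read_fasta <- function(path, type = c("auto", "DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty input: no FASTA records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  seqs <- toupper(as.character(raw))
  if (type == "auto") {
    type <- if (all(grepl("^[ACGTN]*$", seqs))) "DNA" else "AA"
  }
  if (type == "DNA") {
    bad <- !grepl("^[ACGTN]*$", seqs)
    if (any(bad)) stop("non-DNA characters in record ", ids[which(bad)[1L]])
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX*]*$", seqs)
    if (any(bad)) stop("non-peptide characters in record ", ids[which(bad)[1L]])
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  ids <- names(x)
  seqs <- as.character(x)
  if (is.null(ids) || any(ids == "")) stop("all records need an id")
  desc <- NULL
  if (methods::is(x, "XStringSet")) desc <- S4Vectors::mcols(x)$description
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- ids[i]
    if (!is.null(desc) && !is.na(desc[i]) && nzchar(desc[i]))
      hdr <- paste(hdr, desc[i])
    writeLines(paste0(">", hdr), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct BED6 intervals
#'
#' @param contig,start,end,name,score,strand Vectors of equal length; `start`
#'   is 0-based inclusive, `end` exclusive, per the BED convention.
#' @return A data frame of class `nlr_bed`.
#' @export
bed_intervals <- function(contig, start, end, name = ".", score = 0,
                          strand = "+") {
  df <- data.frame(contig = as.character(contig), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   score = as.numeric(score), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L)) stop("invalid interval: start < 0")
  if (any(df$end <= df$start)) stop("invalid interval: end <= start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- c("nlr_bed", class(df))
  df
}

#' Write intervals as 6-column BED
#'
#' @param intervals Data frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @param path Output path.
#' @param genome Optional `DNAStringSet`; when supplied, interval ends are
#'   checked against contig lengths.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, genome = NULL) {
  req <- c("contig", "start", "end", "name", "score", "strand")
  missing_cols <- setdiff(req, names(intervals))
  if (length(missing_cols)) stop("missing BED columns: ",
                                 paste(missing_cols, collapse = ", "))
  if (nrow(intervals) > 0) {
    if (any(intervals$end <= intervals$start))
      stop("invalid interval: end <= start")
    if (any(intervals$start < 0L)) stop("invalid interval: start < 0")
    if (!is.null(genome)) {
      lens <- setNames(Biostrings::width(genome), names(genome))
      if (any(intervals$end > lens[intervals$contig]))
        stop("interval beyond contig end")
    }
  }
  lines <- character(0)
  if (nrow(intervals) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$contig,
                     as.integer(intervals$start), as.integer(intervals$end),
                     intervals$name, format(intervals$score, trim = TRUE,
                                            scientific = FALSE),
                     intervals$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write features as GFF3
#'
#' Internal 0-based half-open feature coordinates are converted to GFF3's
#' 1-based closed convention here (`gff_start = start + 1`, `gff_end = end`).
#'
#' @param features Data frame with columns `contig`, `source`, `type`,
#'   `start`, `end` (0-based half-open), `score`, `strand` and an
#'   `attributes` list/character column whose entries contain at least `ID`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(features) || nrow(features) == 0) return(invisible(path))
  attrs <- features$attributes
  fmt_attr <- function(a) {
    if (is.character(a) && length(a) == 1L) {
      if (!grepl("(^|;)ID=", a)) stop("GFF3 feature without ID attribute")
      return(a)
    }
    if (is.null(a$ID) || !nzchar(a$ID)) stop("GFF3 feature without ID attribute")
    paste(paste0(names(a), "=", vapply(a, as.character, character(1))),
          collapse = ";")
  }
  attr_str <- vapply(attrs, fmt_attr, character(1))
  ids <- sub("^.*?ID=([^;]*).*$", "\\1", attr_str)
  if (anyDuplicated(ids)) stop("duplicate GFF3 ID: ", ids[duplicated(ids)][1L])
  score <- features$score
  score_str <- ifelse(is.na(score), ".",
                      format(score, trim = TRUE, scientific = FALSE))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s", features$contig,
                   features$source, features$type,
                   as.integer(features$start) + 1L, as.integer(features$end),
                   score_str, features$strand, attr_str)
  writeLines(lines, con)
  invisible(path)
}

# feature-table constructor shared by annotation/simulation output
.gff_feature <- function(contig, source, type, start, end, score, strand, id,
                         extra = list()) {
  data.frame(contig = contig, source = source, type = type,
             start = as.integer(start), end = as.integer(end),
             score = if (is.null(score)) NA_real_ else score,
             strand = strand,
             attributes = I(list(c(list(ID = id), extra))),
             stringsAsFactors = FALSE)
}
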