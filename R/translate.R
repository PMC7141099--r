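# Six-frame translation with an invertible peptide-index -> genomic map.
# Frames +1/+2/+3 read the forward strand at offsets 0/1/2; frames -1/-2/-3
# read the reverse complement at the same offsets. Codons containing N
# translate to 'X'; stops to '*'.

#' Translate a DNA sequence in all six reading frames
#'
#' @param dna A `DNAString`, single-element `DNAStringSet`, or character DNA
#'   string (A/C/G/T/N).
#' @return A list with one element per frame (names `"+1" ... "-3"`), each a
#'   list with `frame` (integer in `c(1, 2, 3, -1, -2, -3)`), `offset`
#'   (0-based offset into the read strand) and `peptide` (character). Use
#'   [frame_codon_start()] to map a peptide index back to its genomic codon.
#' @examples
#' six_frame_translate("ATGGCC")[["+1"]]$peptide # "MA"
#' @export
six_frame_translate <- function(dna) {
  dna <- .as_dnastring(dna)
  len <- length(dna)
  rc <- Biostrings::reverseComplement(dna)
  out <- list()
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    off <- abs(f) - 1L
    src <- if (f > 0) dna else rc
    ncod <- (len - off) %/% 3L
    pep <- ""
    if (len >= 3L && ncod > 0L) {
      sub <- Biostrings::subseq(src, start = off + 1L, width = 3L * ncod)
      pep <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                                no.init.codon = TRUE))
    }
    out[[.frame_name(f)]] <- list(frame = f, offset = off, peptide = pep)
  }
  out
}

#' Genomic codon interval of a translated residue
#'
#' Inverse of the six-frame coordinate map: for residue `i` (0-based) of the
#' frame's peptide, returns the 0-based half-open genomic interval of its
#' codon on the forward strand.
#'
#' @param frame Frame in `c(1, 2, 3, -1, -2, -3)`.
#' @param i 0-based peptide index (vectorised).
#' @param dna_len Length of the source sequence.
#' @return A two-column matrix (`start`, `end`).
#' @export
frame_codon_start <- function(frame, i, dna_len) {
  off <- abs(frame) - 1L
  if (frame > 0) {
    s <- off + 3L * i
    cbind(start = s, end = s + 3L)
  } else {
    e <- dna_len - off - 3L * i
    cbind(start = e - 3L, end = e)
  }
}

# peptide [s, e) half-open -> genomic [start, end) half-open
.frame_to_genomic <- function(frame, s, e, dna_len) {
  off <- abs(frame) - 1L
  if (frame > 0) c(off + 3L * s, off + 3L * e)
  else c(dna_len - off - 3L * e, dna_len - off - 3L * s)
}

.frame_name <- function(f) paste0(ifelse(f > 0, "+", ""), f)

.as_dnastring <- function(x) {
  if (methods::is(x, "DNAString")) return(x)
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(x[[1L]])
  }
  Biostrings::DNAString(toupper(as.character(x)))
}

# translate a character DNA string (must be codon-phased already)
.translate_chr <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, 3L * n)), if.fuzzy.codon = "X",
    no.init.codon = TRUE))
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
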