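# Substitution matrix plumbing. BLOSUM62 comes from Biostrings; the compiled
# aligner consumes a 128x128 ASCII-indexed lookup so that peptides containing
# 'X' (ambiguous codons) and '*' (stops, kept so intact pseudogenes remain
# detectable) score with the matrix's own values.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.load_submat <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.nlr_env[[key]])) return(.nlr_env[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  .nlr_env[[key]] <- m
  m
}

# 128x128 ASCII lookup; characters outside the matrix score `unknown`.
.submat128 <- function(name = "BLOSUM62", unknown = -4) {
  key <- paste0("submat128_", name)
  if (!is.null(.nlr_env[[key]])) return(.nlr_env[[key]])
  m <- .load_submat(name)
  out <- matrix(unknown, 128, 128)
  codes <- vapply(rownames(m), function(ch) utf8ToInt(ch), integer(1))
  out[codes + 1, codes + 1] <- m
  .nlr_env[[key]] <- out
  out
}

# ncol x 128 ASCII lookup for a PSSM whose scores cover the 20 standard
# residues; other subject characters (X, *) get `unknown`.
.pssm128 <- function(scores, unknown = -4) {
  out <- matrix(unknown, nrow(scores), 128)
  codes <- vapply(colnames(scores), function(ch) utf8ToInt(ch), integer(1))
  out[, codes + 1] <- scores
  out
}
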