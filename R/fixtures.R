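# Bundled synthetic fixture sequences. These are seeded constructions, NOT
# redistributed Pfam PF00931 or Vitis vinifera sequences: random peptides
# with the family's canonical motifs (P-loop, GLPL, MHD for NB-ARC) planted
# at realistic positions, two related members per class. They make the
# package self-contained and its tests reproducible; for real screens users
# should supply their own class-labelled NB-ARC reference FASTA.

#' Path to a bundled fixture file
#'
#' @param file File name under the package's `extdata/`.
#' @return Absolute path.
#' @export
nlr_fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "nlrsweep")
  if (!nzchar(p)) stop("configuration error: missing fixture ", file)
  p
}

#' Bundled synthetic class-labelled NB-ARC reference peptides
#'
#' Eight peptides, two per class, with headers carrying `class=` tags.
#'
#' @return `AAStringSet` with a `class` metadata column.
#' @export
reference_peptides <- function() {
  x <- read_fasta(nlr_fixture_path("synthetic_nbarc_reference.fa"),
                  type = "AA")
  S4Vectors::mcols(x)$class <- .parse_class_tags(x)
  x
}

# class=XXX key-value tags in FASTA descriptions
.parse_class_tags <- function(x) {
  desc <- S4Vectors::mcols(x)$description
  cls <- rep(NA_character_, length(x))
  hit <- grepl("class=", desc)
  cls[hit] <- sub("^.*class=([A-Za-z0-9]+).*$", "\\1", desc[hit])
  if (anyNA(cls))
    stop("reference peptide without class= tag: ",
         names(x)[which(is.na(cls))[1L]])
  bad <- !cls %in% c("CNL", "TNL", "NL", "RNL")
  if (any(bad)) stop("unknown class label: ", cls[which(bad)[1L]])
  cls
}

#' Bundled TIR/RPW8 detector panel consensus peptides
#'
#' @return List with `TIR` and `RPW8` consensus peptide strings (the first
#'   record of each synthetic panel).
#' @export
detector_panels <- function() {
  if (!is.null(.nlr_env$panels)) return(.nlr_env$panels)
  tir <- read_fasta(nlr_fixture_path("synthetic_tir_panel.fa"), type = "AA")
  rpw8 <- read_fasta(nlr_fixture_path("synthetic_rpw8_panel.fa"), type = "AA")
  out <- list(TIR = as.character(tir[[1L]]), RPW8 = as.character(rpw8[[1L]]))
  .nlr_env$panels <- out
  out
}

#' Detector profiles for TIR and RPW8
#'
#' PSSMs built once per session from the bundled synthetic panels
#' (star-aligned, default pseudocount and background).
#'
#' @return Named list of `nlr_profile` objects (`TIR`, `RPW8`).
#' @export
detector_profiles <- function() {
  if (!is.null(.nlr_env$detector_profiles))
    return(.nlr_env$detector_profiles)
  build <- function(file, label) {
    panel <- read_fasta(nlr_fixture_path(file), type = "AA")
    build_profile(align_peptides(panel), label)
  }
  out <- list(TIR = build("synthetic_tir_panel.fa", "TIR"),
              RPW8 = build("synthetic_rpw8_panel.fa", "RPW8"))
  .nlr_env$detector_profiles <- out
  out
}
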