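# Pipeline configuration: one nested list of parameter blocks, buildable in
# code or from a YAML file.

#' Pipeline configuration
#'
#' Bundles the parameter blocks of every pipeline stage. All defaults are
#' the stage defaults; pass modified blocks to change them.
#'
#' @param search [search_params()] used for both the reference and the
#'   profile search pass.
#' @param chain [chain_params()].
#' @param profile List with `pseudocount`, `gap_col_frac` and
#'   `min_class_size` controlling second-pass profile construction (see
#'   [build_profile()] and [build_class_profiles()]).
#' @param annotate [annotate_params()].
#' @param pass2 Logical; run the species/class-specific profile second pass.
#' @return A list of class `nlr_config`.
#' @export
pipeline_config <- function(search = search_params(), chain = chain_params(),
                            profile = list(pseudocount = 1,
                                           gap_col_frac = 0.5,
                                           min_class_size = 2L),
                            annotate = annotate_params(), pass2 = TRUE) {
  stopifnot(inherits(search, "nlr_search_params"),
            inherits(chain, "nlr_chain_params"),
            inherits(annotate, "nlr_annotate_params"),
            is.logical(pass2), length(pass2) == 1L)
  prof_def <- list(pseudocount = 1, gap_col_frac = 0.5, min_class_size = 2L)
  bad <- setdiff(names(profile), names(prof_def))
  if (length(bad)) stop("unknown profile option: ", bad[1L])
  profile <- utils::modifyList(prof_def, profile)
  structure(list(search = search, chain = chain, profile = profile,
                 annotate = annotate, pass2 = pass2),
            class = "nlr_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain any subset of the blocks `search`, `chain`,
#' `profile`, `annotate` and the scalar `pass2`; block entries override the
#' corresponding constructor defaults and unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return An `nlr_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("search", "chain", "profile", "annotate", "pass2")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config block: ", bad[1L])
  block <- function(name, ctor) {
    args <- y[[name]]
    if (is.null(args)) return(ctor())
    ok <- names(formals(ctor))
    bad <- setdiff(names(args), ok)
    if (length(bad)) stop("unknown ", name, " option: ", bad[1L])
    do.call(ctor, args)
  }
  pipeline_config(search = block("search", search_params),
                  chain = block("chain", chain_params),
                  profile = if (is.null(y$profile)) list() else y$profile,
                  annotate = block("annotate", annotate_params),
                  pass2 = if (is.null(y$pass2)) TRUE else isTRUE(y$pass2))
}
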