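#' Label scheme for tissue classes and subcortical structures
#'
#' The package's fixed label convention: code 0 is background, codes 1--4 are
#' the tissue classes (CSF, gray matter, white matter, white matter signal
#' abnormality) and codes 10--18 are the nine manually segmented structures.
#' Left/right counterparts of a structure share a single code.
#'
#' @return Named integer vector mapping region names to label codes.
#' @export
#' @examples
#' neoseg_scheme()
neoseg_scheme <- function() {
  c(background = 0L,
    csf = 1L, gm = 2L, wm = 3L, wmsa = 4L,
    brain_stem = 10L, cerebellum = 11L, amygdalae = 12L, hippocampi = 13L,
    corpus_callosum = 14L, accumbens = 15L, caudate = 16L, thalamus = 17L,
    lenticular = 18L)
}

#' @rdname neoseg_scheme
#' @export
tissue_codes <- function() {
  s <- neoseg_scheme()
  s[c("csf", "gm", "wm", "wmsa")]
}

#' @rdname neoseg_scheme
#' @export
structural_codes <- function() {
  s <- neoseg_scheme()
  s[s >= 10L]
}

validate_scheme <- function(scheme) {
  if (is.null(names(scheme)) || anyDuplicated(scheme) || anyDuplicated(names(scheme))) {
    neo_stop("label scheme must be a named vector with unique codes and names",
             "neoseg_scheme_error")
  }
  stats::setNames(as.integer(scheme), names(scheme))
}

code_names <- function(codes, scheme = neoseg_scheme()) {
  names(scheme)[match(codes, scheme)]
}
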