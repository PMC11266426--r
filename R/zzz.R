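#' memBAR: membrane interaction and geometry analysis for BAR domains
#'
#' See the package DESCRIPTION and the methods vignette for an overview.
#'
#' @useDynLib memBAR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"
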