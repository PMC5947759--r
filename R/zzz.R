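#' @useDynLib mrforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dist rnorm setNames complete.cases
#' @importFrom utils combn head write.table
NULL
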