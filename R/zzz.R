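#' @keywords internal
#' @aliases huzembed-package
#' @useDynLib huzembed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate optim dist
#' @importFrom utils modifyList
"_PACKAGE"
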