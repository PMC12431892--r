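#' @importFrom rlang %||% .data abort warn
#' @importFrom stats sd var quantile rnorm runif
#' @importFrom utils combn
NULL
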