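#' @import methods
#' @importFrom stats predict sd var quantile median rnorm runif dnorm setNames
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname stageLabels
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @rdname reconstruct
#' @export
setGeneric("reconstruct", function(object, ...) standardGeneric("reconstruct"))

#' @rdname approxCoefs
#' @export
setGeneric("approxCoefs", function(object) standardGeneric("approxCoefs"))

#' @rdname detailCoefs
#' @export
setGeneric("detailCoefs", function(object, level) standardGeneric("detailCoefs"))

#' @rdname stageFractions
#' @export
setGeneric("stageFractions", function(object) standardGeneric("stageFractions"))
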