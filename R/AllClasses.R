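#' Storage-stage levels
#'
#' The three modelling stages plus \code{"TRANSITIONAL"}, which is only a
#' whole-sample label (samples in transition are discarded before modelling
#' and never appear in pixel maps).
#'
#' @return Character vector of the four stage names in progression order.
#' @export
#' @examples
#' stageLevels()
stageLevels <- function() c("RIGOR", "AGED", "SPOILED", "TRANSITIONAL")

# stages that may appear in models and aging maps
.modelStages <- function() c("RIGOR", "AGED", "SPOILED")

#' Hypercube: a hyperspectral reflectance cube
#'
#' A rows x cols x bands reflectance array with its wavelength axis (nm,
#' strictly increasing) and free-form header metadata. The spatial convention
#' is row-major with row 1 rendered at the top.
#'
#' @slot data Three-dimensional numeric array (rows, cols, bands), finite.
#' @slot wavelengths Numeric vector, nm, one per band, strictly increasing.
#' @slot metadata Named list of header key-value pairs.
#' @export
setClass("Hypercube",
  representation(data = "array", wavelengths = "numeric", metadata = "list"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a rows x cols x bands array")
    if (length(object@wavelengths) != d[3L])
      return("length(wavelengths) must equal the number of bands")
    if (any(!is.finite(object@data))) return("reflectance values must be finite")
    if (any(diff(object@wavelengths) <= 0))
      return("wavelengths must be strictly increasing")
    TRUE
  })

#' Construct a Hypercube
#'
#' @param data rows x cols x bands numeric array of reflectance.
#' @param wavelengths Strictly increasing numeric vector of band centres (nm).
#' @param metadata Optional named list of header fields.
#' @return A \linkS4class{Hypercube}.
#' @export
#' @examples
#' cube <- Hypercube(array(0.5, c(4, 4, 8)), wavelengths = seq(400, 470, by = 10))
#' dim(cube)
Hypercube <- function(data, wavelengths, metadata = list()) {
  new("Hypercube", data = data, wavelengths = as.numeric(wavelengths),
      metadata = metadata)
}

#' SpectraSet: labelled sample spectra
#'
#' A \linkS4class{SummarizedExperiment} holding one reflectance spectrum per
#' sample (assay \code{"reflectance"}, bands x samples), the wavelength grid in
#' \code{rowData()$wavelength}, and per-sample annotation (at least a
#' \code{stage} column) in \code{colData()}.
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

#' Construct a SpectraSet
#'
#' @param values Numeric matrix, bands x samples.
#' @param wavelengths Numeric vector of band centres (nm), one per row.
#' @param stage Factor or character of stage labels, one per sample.
#' @param ... Further per-sample columns for \code{colData}.
#' @return A \linkS4class{SpectraSet}.
#' @export
#' @examples
#' ss <- SpectraSet(matrix(runif(20), 10, 2), seq(400, 445, by = 5),
#'                  stage = c("RIGOR", "AGED"))
#' stageLabels(ss)
SpectraSet <- function(values, wavelengths, stage, ...) {
  values <- as.matrix(values)
  stopifnot(length(wavelengths) == nrow(values),
            length(stage) == ncol(values))
  stage <- factor(as.character(stage), levels = stageLevels())
  if (anyNA(stage)) stop("unknown stage label")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = values),
    rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelengths)),
    colData = S4Vectors::DataFrame(stage = stage, ...))
  new("SpectraSet", se)
}

#' WaveletDecomposition: multilevel DWT of one spectrum
#'
#' Ordered coefficient sets from a stepwise discrete wavelet transform that
#' recurses on the approximation branch only: the level-k approximation
#' \code{cA} plus every detail vector \code{cD_1..cD_k}.
#'
#' @slot wavelet Mother-wavelet name.
#' @slot mode Boundary extension mode, \code{"symmetric"} (half-point) or
#'   \code{"periodization"}.
#' @slot cA Numeric vector of level-k approximation coefficients.
#' @slot cD List of numeric vectors, detail coefficients for levels 1..k.
#' @slot inputLengths Integer vector: signal length entering each step
#'   (element 1 is the original length).
#' @export
setClass("WaveletDecomposition",
  representation(wavelet = "character", mode = "character", cA = "numeric",
                 cD = "list", inputLengths = "integer"),
  validity = function(object) {
    k <- length(object@cD)
    if (k < 1L) return("at least one decomposition level required")
    if (length(object@inputLengths) != k)
      return("inputLengths must record one length per level")
    L <- filterLength(object@wavelet)
    for (j in seq_len(k)) {
      expect <- .coeffLengthOne(object@inputLengths[j], L, object@mode)
      if (length(object@cD[[j]]) != expect)
        return(sprintf("cD_%d has length %d, expected %d", j,
                       length(object@cD[[j]]), expect))
    }
    if (length(object@cA) != length(object@cD[[k]]))
      return("cA must match the deepest cD in length")
    TRUE
  })

#' StageModel: a trained stage classifier
#'
#' Radial-basis SVM over wavelet features with its feature scaler and a
#' fingerprint (wavelet, level, extension mode, wavelength grid) that input
#' cubes/spectra must match at prediction time.
#'
#' @slot fit The underlying \code{e1071::svm} fit.
#' @slot center,scale Per-feature z-score statistics fitted on training data.
#' @slot wavelet,mode Mother wavelet and extension mode of the features.
#' @slot level Decomposition level.
#' @slot wavelengths Wavelength grid (nm) the model expects.
#' @slot hyperparams Named numeric: \code{C} and \code{sigma} (RBF width,
#'   \code{gamma = 1/(2 sigma^2)}).
#' @slot classes Stage names the model predicts.
#' @export
setClass("StageModel",
  representation(fit = "ANY", center = "numeric", scale = "numeric",
                 wavelet = "character", mode = "character", level = "integer",
                 wavelengths = "numeric", hyperparams = "numeric",
                 classes = "character"))

#' AgingMap: per-pixel stage labels for one cube
#'
#' @slot labels Integer matrix (rows x cols): \code{NA} = background, otherwise
#'   an index into \code{stages}.
#' @slot stages Character vector naming the label codes (modelling stages).
#' @slot fractions Named numeric, percentage of ROI pixels per stage (sums to
#'   100).
#' @slot provenance List: model fingerprint and cube identifier.
#' @export
setClass("AgingMap",
  representation(labels = "matrix", stages = "character",
                 fractions = "numeric", provenance = "list"),
  validity = function(object) {
    if (!all(object@labels[!is.na(object@labels)] %in%
             seq_along(object@stages)))
      return("labels must index into stages")
    if ("TRANSITIONAL" %in% object@stages)
      return("TRANSITIONAL is not a renderable map stage")
    if (sum(!is.na(object@labels)) > 0 &&
        abs(sum(object@fractions) - 100) > 1e-6)
      return("stage fractions must sum to 100% over the ROI")
    TRUE
  })

#' @describeIn Hypercube-class Dimensions (rows, cols, bands).
#' @param x A \code{Hypercube}.
#' @export
setMethod("dim", "Hypercube", function(x) dim(x@data))

#' Wavelength axis
#'
#' @param x A \linkS4class{Hypercube} or \linkS4class{SpectraSet}.
#' @return Numeric vector of band centres in nm.
#' @export
#' @name wavelengths
setMethod("wavelengths", "Hypercube", function(x) x@wavelengths)

#' @rdname wavelengths
setMethod("wavelengths", "SpectraSet",
          function(x) SummarizedExperiment::rowData(x)$wavelength)

#' Per-sample stage labels
#'
#' @param x A \linkS4class{SpectraSet}.
#' @return Factor of stage labels.
#' @export
#' @name stageLabels
setMethod("stageLabels", "SpectraSet",
          function(x) SummarizedExperiment::colData(x)$stage)

#' Reflectance matrix of a SpectraSet
#'
#' @param x A \linkS4class{SpectraSet}.
#' @return Numeric matrix, bands x samples.
#' @export
spectra <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  SummarizedExperiment::assay(x, "reflectance")
}

#' @describeIn WaveletDecomposition-class Level-k approximation coefficients.
#' @param object A \code{WaveletDecomposition}.
#' @export
setMethod("approxCoefs", "WaveletDecomposition", function(object) object@cA)

#' @describeIn WaveletDecomposition-class Detail coefficients at \code{level}
#'   (defaults to the deepest level).
#' @param level Integer decomposition level.
#' @export
setMethod("detailCoefs", "WaveletDecomposition",
  function(object, level) {
    if (missing(level)) level <- length(object@cD)
    if (level < 1L || level > length(object@cD))
      stop("level exceeds decomposition depth")
    object@cD[[level]]
  })

#' @describeIn AgingMap-class Stage percentages over the ROI.
#' @param object An \code{AgingMap}.
#' @export
setMethod("stageFractions", "AgingMap", function(object) object@fractions)

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@data)
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
})

setMethod("show", "WaveletDecomposition", function(object) {
  k <- length(object@cD)
  cat(sprintf("WaveletDecomposition: '%s' (%s), level %d, n = %d\n",
              object@wavelet, object@mode, k, object@inputLengths[1]))
  cat("  cD lengths:", paste(vapply(object@cD, length, 1L), collapse = ", "),
      "| cA length:", length(object@cA), "\n")
})

setMethod("show", "StageModel", function(object) {
  cat(sprintf(
    "StageModel: RBF SVM on '%s' level-%d features (%s mode), %d bands\n",
    object@wavelet, object@level, object@mode, length(object@wavelengths)))
  cat(sprintf("  C = %.4g, sigma = %.4g; classes: %s\n",
              object@hyperparams["C"], object@hyperparams["sigma"],
              paste(object@classes, collapse = ", ")))
})

setMethod("show", "AgingMap", function(object) {
  cat(sprintf("AgingMap: %d x %d, %d ROI pixels\n", nrow(object@labels),
              ncol(object@labels), sum(!is.na(object@labels))))
  fr <- paste(sprintf("%s %.1f%%", names(object@fractions), object@fractions),
              collapse = ", ")
  cat(" ", fr, "\n")
})
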