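# Background segmentation and spectrum extraction. The sample is separated
# from the dark background by thresholding an intensity image (mean over
# bands by default); the threshold maximises between-class variance over the
# empirical histogram (Otsu's criterion, computed by exact exhaustive scan).

#' Histogram (Otsu) threshold
#'
#' Exhaustive scan over every cut point between consecutive distinct values,
#' returning the threshold that maximises the between-class variance
#' \eqn{w_1 w_2 (\mu_1 - \mu_2)^2}; the returned value is the midpoint of the
#' optimal gap, so strict comparison against it reproduces the optimal
#' partition.
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @return The threshold value.
#' @export
#' @examples
#' histogramThreshold(c(rep(0.02, 50), rep(0.5, 50)))
histogramThreshold <- function(image) {
  v <- sort(as.numeric(image))
  u <- unique(v)
  if (length(u) < 2L)
    stop("degenerate histogram: image has fewer than two distinct values")
  cnt <- tabulate(match(v, u))
  n <- length(v)
  csum <- cumsum(cnt * u)
  ccnt <- cumsum(cnt)
  k <- seq_len(length(u) - 1L)          # cut after distinct value k
  w1 <- ccnt[k] / n
  w2 <- 1 - w1
  m1 <- csum[k] / ccnt[k]
  m2 <- (csum[length(u)] - csum[k]) / (n - ccnt[k])
  bcv <- w1 * w2 * (m1 - m2)^2
  best <- which.max(bcv)
  (u[best] + u[best + 1L]) / 2
}

#' Segment the sample region of a cube
#'
#' Thresholds an intensity image at \code{\link{histogramThreshold}} (or a
#' fixed override), labels connected foreground components and keeps the
#' largest one, provided it reaches \code{min_region_px} pixels.
#'
#' @param cube A \linkS4class{Hypercube}.
#' @param band_selector \code{NULL} for the mean over all bands (default), an
#'   integer band index, or a function mapping the cube's data array to an
#'   intensity matrix.
#' @param min_region_px Smallest acceptable region size in pixels.
#' @param threshold Optional fixed threshold overriding the histogram rule.
#' @return Logical mask matrix (\code{TRUE} = sample/ROI pixel).
#' @export
#' @examples
#' sim <- simulateCube(simConfig(cube_shape = c(16L, 16L), n_bands = 32L), seed = 1)
#' mask <- segmentCube(sim$cube)
#' sum(mask)
segmentCube <- function(cube, band_selector = NULL, min_region_px = 16L,
                        threshold = NULL) {
  stopifnot(is(cube, "Hypercube"))
  intensity <- if (is.null(band_selector)) {
    rowMeans(matrix(cube@data, prod(dim(cube@data)[1:2]), dim(cube@data)[3]))
  } else if (is.function(band_selector)) {
    band_selector(cube@data)
  } else {
    cube@data[, , as.integer(band_selector)]
  }
  intensity <- matrix(intensity, dim(cube@data)[1], dim(cube@data)[2])
  if (is.null(threshold)) threshold <- histogramThreshold(intensity)
  fg <- intensity > threshold
  if (!any(fg)) stop("segmentation failure: no foreground pixels")
  comp <- EBImage::bwlabel(fg * 1L)
  sizes <- tabulate(comp[comp > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_region_px)
    stop("segmentation failure: largest region below min_region_px")
  mask <- comp == big
  mask
}

#' Mean ROI spectrum
#'
#' Per-band arithmetic mean over the masked pixels — the whole-sample
#' spectrum used for calibration modelling.
#'
#' @param cube A \linkS4class{Hypercube}.
#' @param mask Logical matrix matching the cube's spatial grid.
#' @return Numeric spectrum with a \code{"wavelengths"} attribute.
#' @export
meanSpectrum <- function(cube, mask) {
  .checkMask(cube, mask)
  flat <- matrix(cube@data, prod(dim(cube@data)[1:2]), dim(cube@data)[3])
  out <- colMeans(flat[as.vector(mask), , drop = FALSE])
  attr(out, "wavelengths") <- cube@wavelengths
  out
}

#' Per-pixel spectra of the ROI
#'
#' Yields every masked pixel with its full band vector in deterministic
#' row-major order (row 1 left-to-right, then row 2, ...).
#'
#' @param cube A \linkS4class{Hypercube}.
#' @param mask Logical matrix matching the cube's spatial grid.
#' @return List with \code{coords} (n x 2 integer matrix of (row, col)) and
#'   \code{values} (bands x n matrix, one column per pixel).
#' @export
pixelSpectra <- function(cube, mask) {
  .checkMask(cube, mask)
  ind <- which(mask, arr.ind = TRUE)
  ord <- order(ind[, 1L], ind[, 2L])
  ind <- ind[ord, , drop = FALSE]
  flat <- matrix(cube@data, prod(dim(cube@data)[1:2]), dim(cube@data)[3])
  lin <- ind[, 1L] + (ind[, 2L] - 1L) * dim(cube@data)[1L]
  colnames(ind) <- c("row", "col")
  list(coords = ind, values = t(flat[lin, , drop = FALSE]))
}

.checkMask <- function(cube, mask) {
  if (!is.logical(mask) || !all(dim(mask) == dim(cube@data)[1:2]))
    stop("mask must be a logical matrix matching the cube's spatial grid")
  if (!any(mask)) stop("empty mask: no ROI pixels")
}

#' Write a mask as PNG (0/255) or CSV
#'
#' @param mask Logical matrix.
#' @param path Output path; the extension selects the format.
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  if (grepl("\\.png$", path)) {
    png::writePNG(mask * 1, path)
  } else {
    write.csv(mask * 1L, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a spectrum as a two-column CSV (wavelength, value)
#'
#' @param spectrum Numeric spectrum with a \code{"wavelengths"} attribute (as
#'   returned by \code{\link{meanSpectrum}}), or a plain numeric vector with
#'   \code{wavelengths} supplied.
#' @param path Output path.
#' @param wavelengths Optional wavelength vector.
#' @return The path, invisibly.
#' @export
writeSpectrumCSV <- function(spectrum, path, wavelengths = NULL) {
  wl <- if (is.null(wavelengths)) attr(spectrum, "wavelengths") else wavelengths
  if (is.null(wl)) stop("no wavelengths available")
  write.csv(data.frame(wavelength = wl, value = as.numeric(spectrum)), path,
            row.names = FALSE)
  invisible(path)
}
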