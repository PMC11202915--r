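# End-to-end orchestration: per-pixel staging of a cube, pseudo-colour map
# rendering, and day-series monitoring.

.stageColors <- c(RIGOR = "green", AGED = "blue", SPOILED = "red")

#' Stage every ROI pixel of a cube
#'
#' Crops the cube to the model's band window, checks the band-grid
#' fingerprint, segments the sample from the background, and substitutes each
#' ROI pixel's spectrum into the wavelet + SVM model; background pixels carry
#' a sentinel (\code{NA}).
#'
#' @param model A \linkS4class{StageModel}.
#' @param cube A \linkS4class{Hypercube}.
#' @param smooth_bands Odd moving-average window applied to each pixel
#'   spectrum before decomposition (1 = no smoothing, the default).
#' @param ... Passed to \code{\link{segmentCube}}.
#' @return An \linkS4class{AgingMap}.
#' @export
predictCube <- function(model, cube, smooth_bands = 1L, ...) {
  stopifnot(is(model, "StageModel"), is(cube, "Hypercube"))
  if (length(model@wavelengths)) {
    cube <- cropBands(cube, min(model@wavelengths), max(model@wavelengths))
    if (length(cube@wavelengths) != length(model@wavelengths) ||
        max(abs(cube@wavelengths - model@wavelengths)) > 1e-6)
      stop("cube band grid does not match the model fingerprint")
  }
  mask <- segmentCube(cube, ...)
  px <- pixelSpectra(cube, mask)
  vals <- px$values
  if (smooth_bands > 1L) {
    kw <- rep(1 / smooth_bands, smooth_bands)
    pad <- (smooth_bands - 1L) %/% 2L
    nb <- nrow(vals)
    ext <- vals[c(rep(1L, pad), seq_len(nb), rep(nb, pad)), , drop = FALSE]
    sm <- matrix(0, nb, ncol(vals))
    for (j in seq_len(smooth_bands))
      sm <- sm + kw[j] * ext[j:(j + nb - 1L), , drop = FALSE]
    vals <- sm
  }
  feats <- featureMatrix(vals, model@wavelet, model@level, model@mode)
  pred <- as.character(predictStages(model, feats))

  stages <- .modelStages()[.modelStages() %in% model@classes]
  labels <- matrix(NA_integer_, nrow(mask), ncol(mask))
  labels[px$coords] <- match(pred, stages)
  counts <- tabulate(match(pred, stages), length(stages))
  fractions <- setNames(100 * counts / sum(counts), stages)
  new("AgingMap", labels = labels, stages = stages, fractions = fractions,
      provenance = list(wavelet = model@wavelet, level = model@level,
                        mode = model@mode,
                        hyperparams = model@hyperparams,
                        cube = cube@metadata))
}

#' Render an aging map as a pseudo-colour PNG
#'
#' Rigor-mortis pixels are green, aged pixels blue, spoiled pixels red and
#' background black; bytes are deterministic for a fixed map.
#'
#' @param map An \linkS4class{AgingMap}.
#' @param out_path PNG output path.
#' @return \code{out_path}, invisibly.
#' @export
renderMap <- function(map, out_path) {
  stopifnot(is(map, "AgingMap"))
  if (!any(!is.na(map@labels))) stop("cannot render a map with an empty ROI")
  rgb <- array(0, c(nrow(map@labels), ncol(map@labels), 3L))
  chan <- c(RIGOR = 2L, AGED = 3L, SPOILED = 1L)  # G, B, R
  for (s in seq_along(map@stages)) {
    sel <- !is.na(map@labels) & map@labels == s
    plane <- matrix(0, nrow(map@labels), ncol(map@labels))
    plane[sel] <- 1
    rgb[, , chan[[map@stages[s]]]] <-
      rgb[, , chan[[map@stages[s]]]] + plane
  }
  png::writePNG(rgb, out_path)
  invisible(out_path)
}

#' Monitor a day series of cubes
#'
#' Predicts an aging map per cube, tabulates the stage fractions over days,
#' and flags the first day whose spoiled fraction exceeds the alarm
#' threshold.
#'
#' @param model A \linkS4class{StageModel}.
#' @param cubes List of \linkS4class{Hypercube}s, one per day.
#' @param days Numeric day index, one per cube.
#' @param alarm_threshold Spoiled-fraction alarm level in percent of ROI
#'   (default 5).
#' @param ... Passed to \code{\link{predictCube}}.
#' @return List with \code{maps} (per-day \linkS4class{AgingMap}s),
#'   \code{fractions} (data frame day x stage percentages) and
#'   \code{alarm_day} (\code{NA} when never exceeded).
#' @export
runMonitoring <- function(model, cubes, days = seq_along(cubes),
                          alarm_threshold = 5, ...) {
  if (length(cubes) < 1L) stop("need at least one cube")
  if (length(days) != length(cubes))
    stop("days must align with cubes")
  maps <- lapply(cubes, function(cb) predictCube(model, cb, ...))
  fr <- do.call(rbind, lapply(maps, function(m) as.data.frame(t(m@fractions))))
  fr <- cbind(day = days, fr)
  rownames(fr) <- NULL
  spo <- if ("SPOILED" %in% names(fr)) fr$SPOILED else rep(0, nrow(fr))
  hit <- which(spo > alarm_threshold)
  list(maps = maps, fractions = fr,
       alarm_day = if (length(hit)) days[min(hit)] else NA_real_)
}

#' Write a feature matrix as CSV with a JSON sidecar
#'
#' One row per sample (label first, then features); the sidecar records the
#' wavelet, level, extension mode and dimension so a model consumer can check
#' the fingerprint.
#'
#' @param features Samples x dims feature matrix.
#' @param labels Stage labels, one per row.
#' @param path CSV path; the sidecar is written to \code{<path>.json}.
#' @param wavelet,level,mode Fingerprint fields.
#' @return The CSV path, invisibly.
#' @export
writeFeatureCSV <- function(features, labels, path, wavelet = "db5",
                            level = 4L, mode = "symmetric") {
  df <- data.frame(label = as.character(labels), features,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(wavelet = wavelet, level = level, mode = mode,
         dimension = ncol(features)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
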