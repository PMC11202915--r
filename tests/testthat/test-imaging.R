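# ENVI I/O, band cropping, histogram segmentation and spectrum extraction.

test_that("ENVI round-trips are bit-exact for all three interleaves", {
  set.seed(41)
  cube <- Hypercube(array(runif(10 * 12 * 20), c(10, 12, 20)),
                    seq(400, 590, by = 10))
  for (il in c("bsq", "bil", "bip")) {
    stem <- file.path(tempdir(), paste0("rt_", il))
    hdr <- writeENVI(cube, stem, interleave = il)
    back <- readENVI(hdr)
    expect_identical(back@data, cube@data)
    expect_equal(back@wavelengths, cube@wavelengths, tolerance = 1e-12)
  }
})

test_that("synthetic cube survives an ENVI round-trip with its grid", {
  sim <- simulateCube(smallConfig(), seed = 2)
  stem <- file.path(tempdir(), "synth")
  back <- readENVI(writeENVI(sim$cube, stem))
  expect_identical(back@data, sim$cube@data)
  expect_equal(range(back@wavelengths), c(400, 1100))
})

test_that("malformed ENVI inputs are rejected", {
  set.seed(42)
  cube <- Hypercube(array(runif(6 * 6 * 8), c(6, 6, 8)), seq(400, 470, 10))
  stem <- file.path(tempdir(), "bad")
  hdr <- writeENVI(cube, stem)

  # truncate the binary by one band plane: size mismatch must be caught
  dat <- file.path(tempdir(), "bad.dat")
  sz <- file.size(dat)
  raw <- readBin(dat, "raw", n = sz)
  writeBin(raw[seq_len(sz - 6 * 6 * 8)], dat)
  expect_error(readENVI(hdr), "size mismatch")

  # missing wavelength list
  writeENVI(cube, stem)
  lines <- readLines(hdr)
  writeLines(lines[!grepl("^wavelength =", lines)], hdr)
  expect_error(readENVI(hdr), "wavelength")

  expect_error(writeENVI(Hypercube(array(numeric(0), c(0, 0, 0)),
                                   numeric(0)), stem), "empty")
})

test_that("band cropping keeps the closed wavelength interval", {
  grid1 <- seq(400, 1100, by = 1)
  cube <- Hypercube(array(0.3, c(4, 4, length(grid1))), grid1)
  expect_identical(dim(cropBands(cube, 500, 600))[3], 101L)
  expect_identical(dim(cropBands(cube, 400, 1100)), dim(cube))

  grid438 <- seq(400, 1100, length.out = 438)
  cube438 <- Hypercube(array(0.3, c(4, 4, 438)), grid438)
  expect_identical(dim(cropBands(cube438))[3], 438L)
  expect_error(cropBands(cube, 2000, 2200), "no bands")
})

test_that("the histogram threshold maximises between-class variance", {
  # bimodal toy image
  th <- histogramThreshold(c(rep(0.02, 60), rep(0.5, 40)))
  expect_gt(th, 0.02)
  expect_lt(th, 0.5)

  # brute-force oracle: double loop over all cut points
  set.seed(51)
  img <- c(rnorm(40, 0.1, 0.02), rnorm(60, 0.6, 0.05))
  bruteOtsu <- function(v) {
    u <- sort(unique(v))
    best <- -Inf; cut <- NA
    for (k in seq_len(length(u) - 1)) {
      g1 <- v[v <= u[k]]; g2 <- v[v > u[k]]
      bcv <- (length(g1) / length(v)) * (length(g2) / length(v)) *
        (mean(g1) - mean(g2))^2
      if (bcv > best) { best <- bcv; cut <- (u[k] + u[k + 1]) / 2 }
    }
    cut
  }
  expect_equal(histogramThreshold(img), bruteOtsu(img), tolerance = 1e-12)

  # independent implementation (EBImage's binned Otsu) lands in the same gap
  m <- matrix(img, 10, 10)
  thBinned <- EBImage::otsu(EBImage::Image(m), range = range(m), levels = 256)
  expect_lt(abs(histogramThreshold(m) - thBinned), 0.02)

  expect_error(histogramThreshold(rep(0.5, 10)), "degenerate")
})

test_that("segmentation recovers the elliptical sample region", {
  sim <- simulateCube(simConfig(), seed = 7)
  mask <- segmentCube(sim$cube)
  truth <- sim$labels > 0
  expect_gte(mean(mask == truth), 0.99)
  # one connected component
  comp <- EBImage::bwlabel(mask * 1L)
  expect_equal(max(comp), 1)
  # pixel count within 2% of the analytic ellipse area (pi * 0.4 nr * 0.4 nc)
  area <- pi * (0.4 * 64)^2
  expect_lt(abs(sum(mask) - area) / area, 0.02)

  # an all-background cube cannot be segmented: nothing clears the threshold
  flat <- Hypercube(array(0.02, c(16, 16, 8)) +
                      array(rnorm(16 * 16 * 8, sd = 1e-4), c(16, 16, 8)),
                    seq(400, 470, 10))
  expect_error(segmentCube(flat, threshold = 0.5), "segmentation failure")
  # a constant cube has no histogram structure at all
  const <- Hypercube(array(0.02, c(16, 16, 8)), seq(400, 470, 10))
  expect_error(segmentCube(const), "degenerate")
})

test_that("mean and per-pixel spectra are consistent", {
  sim <- simulateCube(smallConfig(), seed = 4)
  mask <- segmentCube(sim$cube)
  ms <- meanSpectrum(sim$cube, mask)
  px <- pixelSpectra(sim$cube, mask)
  expect_identical(ncol(px$values), sum(mask))
  expect_lt(max(abs(rowMeans(px$values) - ms)), 1e-10)

  # stated order: row-major, first pixel is the top-left true pixel
  ind <- which(mask, arr.ind = TRUE)
  first <- ind[order(ind[, 1], ind[, 2])[1], ]
  expect_identical(unname(px$coords[1, ]), unname(first))

  # reassembly reproduces the masked cube exactly
  rebuilt <- array(NA_real_, dim(sim$cube))
  for (i in seq_len(nrow(px$coords))) {
    rebuilt[px$coords[i, 1], px$coords[i, 2], ] <- px$values[, i]
  }
  flatMask <- array(rep(mask, dim(sim$cube)[3]), dim(sim$cube))
  expect_identical(rebuilt[flatMask], sim$cube@data[flatMask])

  # single-pixel mask returns that pixel's spectrum
  one <- matrix(FALSE, 24, 24); one[12, 13] <- TRUE
  expect_equal(as.numeric(meanSpectrum(sim$cube, one)),
               as.numeric(sim$cube@data[12, 13, ]))

  # uniform cube: the mean is the uniform spectrum for any mask
  uni <- Hypercube(array(rep(seq(0.1, 0.8, length.out = 8),
                             each = 24 * 24), c(24, 24, 8)),
                   seq(400, 470, 10))
  expect_equal(as.numeric(meanSpectrum(uni, mask[1:24, 1:24])),
               seq(0.1, 0.8, length.out = 8))

  empty <- matrix(FALSE, 24, 24)
  expect_error(meanSpectrum(sim$cube, empty), "empty mask")
  expect_error(pixelSpectra(sim$cube, empty), "empty mask")
})

test_that("noiseless single-stage cube returns the prototype exactly", {
  cfg <- smallConfig(noise_sd = 0, edge_fraction = 0)
  sim <- simulateCube(cfg, stages = c("AGED", "SPOILED"), seed = 1)
  mask <- sim$labels > 0
  ms <- meanSpectrum(sim$cube, mask)
  expect_equal(as.numeric(ms), makePrototypes(cfg)$AGED, tolerance = 1e-12)
})

test_that("segmentation agrees with ground truth across seeds", {
  agree <- vapply(1:20, function(seed) {
    sim <- simulateCube(smallConfig(), seed = seed)
    mean(segmentCube(sim$cube) == (sim$labels > 0))
  }, numeric(1))
  expect_true(all(agree >= 0.99))
})
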