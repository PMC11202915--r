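# Synthetic-data generators. No public hyperspectral pork dataset accompanies
# the staging problem, so every downstream stage is exercised on simulated
# data that reproduces the qualitative structure of real measurements: spoiled
# meat reflects more in the visible range than non-spoiled; rigor and aged
# meat share the same gross spectral shape and differ only in localized
# detail; spoilage advances inward from the sample edge; and the
# physicochemical indices follow their characteristic storage-time curves.

#' Simulation configuration
#'
#' Bundles the knobs shared by the spectral and cube generators.
#'
#' @param n_bands Number of spectral bands (default 438, the visible/short-NIR
#'   analysis grid).
#' @param wavelength_min,wavelength_max Grid end points in nm (default
#'   400-1100).
#' @param n_per_class Named counts of rigor/aged/spoiled samples (defaults
#'   30/40/30, the 100-sample design).
#' @param noise_sd Marginal standard deviation of the band-correlated
#'   reflectance noise (default 0.01).
#' @param class_separation Amplitude (reflectance units) of the localized
#'   detail features separating rigor from aged prototypes (default 0.04); 0
#'   makes the two identical while spoiled keeps its fixed visible offset.
#' @param cube_shape Integer (rows, cols) of simulated cubes (default 64x64).
#' @param edge_fraction Fraction of the sample-ellipse radius occupied by the
#'   more advanced stage ring (default 0.25).
#' @param background_reflectance Background level (default 0.02).
#' @return A list of class \code{"simConfig"}.
#' @export
#' @examples
#' cfg <- simConfig()
#' cfg$n_bands
simConfig <- function(n_bands = 438L, wavelength_min = 400, wavelength_max = 1100,
                      n_per_class = c(RIGOR = 30L, AGED = 40L, SPOILED = 30L),
                      noise_sd = 0.01, class_separation = 0.04,
                      cube_shape = c(64L, 64L), edge_fraction = 0.25,
                      background_reflectance = 0.02) {
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 16L)
    stop("n_bands must be a positive integer >= 16")
  if (wavelength_max <= wavelength_min)
    stop("wavelength_max must exceed wavelength_min")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (edge_fraction < 0 || edge_fraction > 1)
    stop("edge_fraction must lie in [0, 1]")
  structure(list(
    n_bands = n_bands, wavelength_min = wavelength_min,
    wavelength_max = wavelength_max, n_per_class = n_per_class,
    noise_sd = noise_sd, class_separation = class_separation,
    cube_shape = as.integer(cube_shape), edge_fraction = edge_fraction,
    background_reflectance = background_reflectance), class = "simConfig")
}

.simGrid <- function(config) {
  seq(config$wavelength_min, config$wavelength_max,
      length.out = config$n_bands)
}

#' Class prototype spectra
#'
#' Three smooth noiseless prototypes on the configured wavelength grid. The
#' shared base curve is a sigmoidal red-edge rise with oxymyoglobin absorption
#' dips near 545/575 nm and a water dip near 970 nm. The spoiled prototype
#' adds a fixed broad visible offset (+0.08, tapering into the NIR), so its
#' visible-range mean exceeds both others. Rigor and aged differ only by
#' localized detail features of amplitude \code{class_separation}: narrow
#' (8 nm) alternating-sign peaks across the visible range plus a slight NIR
#' depression for the later stage — gross shape is shared, the discriminating
#' signal lives in the detail scales.
#'
#' @param config A \code{\link{simConfig}}.
#' @return Named list of numeric prototype spectra (\code{RIGOR},
#'   \code{AGED}, \code{SPOILED}).
#' @export
#' @examples
#' p <- makePrototypes(simConfig())
#' mean(p$SPOILED) > mean(p$AGED)
makePrototypes <- function(config = simConfig()) {
  wl <- .simGrid(config)
  base <- 0.08 + 0.38 / (1 + exp(-(wl - 620) / 45)) -
    0.05 * exp(-((wl - 545) / 12)^2) -
    0.05 * exp(-((wl - 575) / 12)^2) -
    0.03 * exp(-((wl - 970) / 25)^2)

  # localized detail: narrow alternating bumps (visible) + mild NIR shelf
  centers <- c(430, 470, 510, 555, 605, 655, 705)
  signs <- rep_len(c(1, -1), length(centers))
  detail <- rowSums(vapply(seq_along(centers), function(i) {
    signs[i] * exp(-((wl - centers[i]) / 8)^2)
  }, numeric(length(wl))))
  nirShelf <- -0.1 / (1 + exp(-(wl - 800) / 30))

  sep <- config$class_separation
  rigor <- base
  aged <- base + sep * (detail + nirShelf)
  spoiledOffset <- 0.08 * (1 - 0.8 / (1 + exp(-(wl - 780) / 40)))
  spoiled <- base + spoiledOffset + sep * 1.5 * nirShelf
  list(RIGOR = rigor, AGED = aged, SPOILED = spoiled)
}

#' Simulate labelled spectra
#'
#' Prototype plus smooth band-correlated Gaussian noise (marginal standard
#' deviation \code{noise_sd} per band).
#'
#' @param config A \code{\link{simConfig}}.
#' @param label One modelling stage (\code{"RIGOR"}, \code{"AGED"} or
#'   \code{"SPOILED"}); transitional samples are not simulated.
#' @param n Number of spectra (positive).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A \linkS4class{SpectraSet} with \code{n} columns.
#' @export
#' @examples
#' ss <- simulateSpectra(simConfig(), "RIGOR", n = 5, seed = 1)
#' dim(spectra(ss))
simulateSpectra <- function(config = simConfig(), label, n, seed = 1L) {
  label <- match.arg(label, .modelStages())
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  proto <- makePrototypes(config)[[label]]
  vals <- .withSeed(seed, {
    proto + .correlatedNoise(config$n_bands, n, config$noise_sd)
  })
  SpectraSet(vals, .simGrid(config), stage = rep(label, n))
}

#' Simulate the default labelled cohort of spectra
#'
#' Draws \code{n_per_class} spectra per stage (30/40/30 by default, the
#' 100-sample modelling design) with per-class seeds derived from \code{seed}.
#'
#' @param config A \code{\link{simConfig}}.
#' @param seed Integer seed.
#' @return A \linkS4class{SpectraSet} with \code{sum(n_per_class)} columns.
#' @export
#' @examples
#' coh <- simulateCohort(seed = 1)
#' table(stageLabels(coh))
simulateCohort <- function(config = simConfig(), seed = 1L) {
  sets <- lapply(seq_along(config$n_per_class), function(i) {
    st <- names(config$n_per_class)[i]
    simulateSpectra(config, st, config$n_per_class[[i]],
                    seed = as.integer(seed) + i * 1000L)
  })
  vals <- do.call(cbind, lapply(sets, spectra))
  SpectraSet(vals, .simGrid(config),
             stage = unlist(lapply(sets, function(s) as.character(stageLabels(s)))))
}

#' Simulate a hypercube with edge-first aging geometry
#'
#' The sample is an axis-aligned ellipse on a dark background; within it, an
#' edge annulus of relative width \code{edge_fraction} carries the more
#' advanced stage (aging and spoilage advance inward from the edge). Each
#' pixel's spectrum is its stage prototype plus band-correlated noise;
#' background pixels sit at \code{background_reflectance} with small noise.
#'
#' @param config A \code{\link{simConfig}}.
#' @param stages Length-2 character: core stage then ring stage, in
#'   progression order (defaults \code{c("AGED", "SPOILED")}).
#' @param seed Integer seed.
#' @return List with \code{cube} (a \linkS4class{Hypercube}) and
#'   \code{labels}, the ground-truth integer label image (0 = background,
#'   otherwise an index into \code{attr(labels, "stages")}).
#' @export
#' @examples
#' sim <- simulateCube(simConfig(cube_shape = c(16L, 16L), n_bands = 32L), seed = 1)
#' table(sim$labels)
simulateCube <- function(config = simConfig(),
                         stages = c("AGED", "SPOILED"), seed = 1L) {
  stages <- match.arg(stages, .modelStages(), several.ok = TRUE)
  if (length(stages) != 2L) stop("stages must name a core and a ring stage")
  shp <- config$cube_shape
  if (any(shp < 8L)) stop("cube_shape must be at least 8 x 8")
  nr <- shp[1]; nc <- shp[2]
  proto <- makePrototypes(config)

  # elliptical sample region; normalised radius r in [0, 1] at the boundary
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ry <- 0.4 * nr; rx <- 0.4 * nc
  rr <- outer(seq_len(nr), seq_len(nc), function(i, j) {
    sqrt(((i - cy) / ry)^2 + ((j - cx) / rx)^2)
  })
  inside <- rr <= 1
  ring <- inside & rr > (1 - config$edge_fraction)
  labels <- matrix(0L, nr, nc)
  labels[inside] <- 1L
  labels[ring] <- 2L

  nb <- config$n_bands
  npx <- nr * nc
  dat <- .withSeed(seed, {
    flat <- matrix(config$background_reflectance, nb, npx) +
      .correlatedNoise(nb, npx, config$noise_sd / 5)
    corePix <- which(labels == 1L)
    ringPix <- which(labels == 2L)
    flat[, corePix] <- proto[[stages[1]]] +
      .correlatedNoise(nb, length(corePix), config$noise_sd)
    flat[, ringPix] <- proto[[stages[2]]] +
      .correlatedNoise(nb, length(ringPix), config$noise_sd)
    aperm(array(flat, c(nb, nr, nc)), c(2, 3, 1))
  })
  attr(labels, "stages") <- stages
  list(cube = Hypercube(dat, .simGrid(config),
                        metadata = list(source = "synthetic", seed = seed)),
       labels = labels)
}

#' Simulate per-day physicochemical trajectories
#'
#' One row per animal per storage day with the characteristic curve shapes:
#' pH falls to a trough on day 2 and then rises (accelerating once spoilage
#' sets in); WBSF climbs to its maximum on day 2 and decays exponentially to
#' a basic-hardness plateau; MFI rises monotonically and saturates; TVB-N
#' follows a monotone logistic rise; TVC dips over the first two days before
#' logistic microbial growth takes over. Between-animal variation enters
#' through smooth per-animal rate/level parameters, so spoilage onset differs
#' across animals while every trajectory keeps the canonical shape.
#'
#' @param n_animals Number of animals.
#' @param n_days Number of storage days (>= 3; days are 1..n_days).
#' @param seed Integer seed.
#' @return Data frame with columns \code{animal}, \code{day}, \code{pH},
#'   \code{WBSF}, \code{MFI}, \code{TVBN}, \code{TVC_log}.
#' @export
#' @examples
#' tr <- simulateTrajectories(2, seed = 1)
#' head(tr)
simulateTrajectories <- function(n_animals, n_days = 12L, seed = 1L) {
  n_animals <- as.integer(n_animals)
  n_days <- as.integer(n_days)
  if (n_animals < 1L) stop("n_animals must be positive")
  if (n_days < 3L) stop("need at least three storage days")
  d <- seq_len(n_days)
  .withSeed(seed, {
    rows <- lapply(seq_len(n_animals), function(a) {
      pH0 <- rnorm(1, 6.7, 0.06); pHmin <- rnorm(1, 5.45, 0.04)
      pHrise <- runif(1, 0.05, 0.07); pHspoil <- runif(1, 0.012, 0.02)
      W1 <- rnorm(1, 62, 3); Wp <- rnorm(1, 32, 1.5)
      Wfrac <- runif(1, 0.955, 0.985); Wk <- runif(1, 0.5, 0.7)
      M0 <- rnorm(1, 30, 2); Mmax <- rnorm(1, 95, 4); Mk <- runif(1, 0.2, 0.3)
      T0 <- rnorm(1, 6, 0.6); TA <- rnorm(1, 28, 2)
      Tk <- runif(1, 0.7, 1.0); Td0 <- runif(1, 9.5, 11.5)
      V0 <- rnorm(1, 4.0, 0.2); Vdip <- rnorm(1, 0.5, 0.06)
      VB <- rnorm(1, 4.5, 0.3); Vk <- runif(1, 0.8, 1.1)
      Vd0 <- runif(1, 10.5, 12)

      TVBN <- T0 + TA / (1 + exp(-Tk * (d - Td0)))
      TVC <- {
        nu <- pmin(d, 2) * (4 - pmin(d, 2)) / 4
        V0 - Vdip * nu + VB / (1 + exp(-Vk * (d - Vd0)))
      }
      spoilDay <- suppressWarnings(min(d[TVBN > 20 | TVC > 7]))
      pH <- ifelse(d <= 2,
                   pHmin + (pH0 - pHmin) * ((2 - d) / 2)^3,
                   pHmin + pHrise * (d - 2) +
                     pHspoil * pmax(0, d - min(spoilDay, n_days))^2)
      WBSF <- ifelse(d < 2, W1 * (Wfrac + (1 - Wfrac) * (d - 1)),
                     Wp + (W1 - Wp) * exp(-Wk * (d - 2)))
      MFI <- M0 + (Mmax - M0) * (1 - exp(-Mk * d))
      data.frame(animal = a, day = d, pH = pH, WBSF = WBSF, MFI = MFI,
                 TVBN = TVBN, TVC_log = TVC)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write / read the trajectory CSV dialect
#'
#' Plain CSV with columns \code{animal, day, pH, WBSF, MFI, TVBN, TVC_log}
#' (plus \code{label} when present).
#'
#' @param traj Trajectory data frame.
#' @param path File path.
#' @return \code{readTrajectoryCSV} returns the data frame (restoring the
#'   \code{label} factor when the column is present).
#' @export
writeTrajectoryCSV <- function(traj, path) {
  write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  out <- read.csv(path)
  if ("label" %in% names(out))
    out$label <- factor(out$label, levels = stageLevels())
  out
}
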