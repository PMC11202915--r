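# Stage classification: RBF-kernel support vector machine over wavelet
# features, with the (C, sigma) pair tuned by particle swarm optimisation
# against cross-validated accuracy on the calibration set. The kernel width
# follows the sigma parameterisation, gamma = 1/(2 sigma^2). Multi-class
# reduction is libsvm's native one-vs-one voting.

#' Particle swarm search settings
#'
#' @param swarm Swarm size (>= 2).
#' @param iterations Number of velocity/position updates (>= 1).
#' @param inertia Inertia weight.
#' @param cognitive,social Acceleration coefficients toward the particle and
#'   swarm bests.
#' @param logC,logSigma Search box for \code{log10(C)} and
#'   \code{log10(sigma)}.
#' @param seed Integer seed for swarm initialisation, velocity randomness and
#'   cross-validation folds.
#' @return A list of class \code{"psoConfig"}.
#' @export
psoConfig <- function(swarm = 20L, iterations = 30L, inertia = 0.72,
                      cognitive = 1.49, social = 1.49,
                      logC = c(-2, 4), logSigma = c(-3, 2), seed = 1L) {
  if (swarm < 2L) stop("swarm size must be at least 2")
  if (iterations < 1L) stop("need at least one iteration")
  if (logC[1] >= logC[2] || logSigma[1] >= logSigma[2])
    stop("search box bounds must satisfy min < max")
  structure(list(swarm = as.integer(swarm),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social, logC = logC,
                 logSigma = logSigma, seed = as.integer(seed)),
            class = "psoConfig")
}

#' Stratified calibration/verification split
#'
#' Splits sample indices into disjoint, exhaustive calibration and
#' verification sets (66/34 by default, matching the 100-sample design),
#' stratified by label as evenly as integer counts allow (largest-remainder
#' apportionment of the verification quota).
#'
#' @param labels Factor of stage labels, length \code{n_train + n_test}.
#' @param n_train,n_test Set sizes.
#' @param seed Integer seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
#' @examples
#' sp <- splitDataset(factor(rep(c("RIGOR", "AGED"), 50)), seed = 1)
#' length(sp$train); length(sp$test)
splitDataset <- function(labels, n_train = 66L, n_test = 34L, seed = 1L) {
  labels <- droplevels(factor(labels))
  n <- length(labels)
  if (n != n_train + n_test)
    stop(sprintf("expected %d samples, got %d", n_train + n_test, n))
  quota <- n_test * table(labels) / n
  nTestClass <- floor(quota)
  rem <- n_test - sum(nTestClass)
  if (rem > 0) {
    extra <- order(quota - nTestClass, decreasing = TRUE)[seq_len(rem)]
    nTestClass[extra] <- nTestClass[extra] + 1L
  }
  .withSeed(seed, {
    test <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, nTestClass[[cl]])
    }))
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

# stratified fold assignment for cross-validation
.cvFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# cross-validated accuracy of an (C, sigma) pair; scaling is fitted on each
# training fold only
.cvAccuracy <- function(features, labels, C, sigma, fold) {
  k <- max(fold)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    ctr <- colMeans(features[tr, , drop = FALSE])
    sdev <- apply(features[tr, , drop = FALSE], 2, sd)
    sdev[sdev == 0] <- 1
    Xtr <- scale(features[tr, , drop = FALSE], ctr, sdev)
    Xte <- scale(features[!tr, , drop = FALSE], ctr, sdev)
    fit <- e1071::svm(Xtr, labels[tr], kernel = "radial", cost = C,
                      gamma = 1 / (2 * sigma^2), scale = FALSE)
    correct <- correct + sum(predict(fit, Xte) == labels[!tr])
  }
  correct / length(labels)
}

#' PSO search for SVM hyperparameters
#'
#' Global-best particle swarm over \code{(log10 C, log10 sigma)}; fitness is
#' k-fold cross-validated accuracy on the calibration samples. The best-so-far
#' fitness trace is non-decreasing by construction.
#'
#' @param features Calibration feature matrix (samples x dims), unscaled.
#' @param labels Factor of stage labels (at least two classes present).
#' @param pso A \code{\link{psoConfig}}.
#' @param cv_folds Number of cross-validation folds.
#' @return List with \code{C}, \code{sigma}, \code{fitness} (CV accuracy of
#'   the returned pair) and \code{trace} (best-so-far fitness per iteration).
#' @export
psoSearch <- function(features, labels, pso = psoConfig(), cv_folds = 5L) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L)
    stop("degenerate data: need at least two classes to tune a classifier")
  features <- as.matrix(features)
  .withSeed(pso$seed, {
    fold <- .cvFolds(labels, cv_folds)
    ns <- pso$swarm
    lo <- c(pso$logC[1], pso$logSigma[1])
    hi <- c(pso$logC[2], pso$logSigma[2])
    pos <- cbind(runif(ns, lo[1], hi[1]), runif(ns, lo[2], hi[2]))
    vel <- matrix(0, ns, 2)
    evalPos <- function(p) .cvAccuracy(features, labels, 10^p[1], 10^p[2], fold)
    fit <- apply(pos, 1, evalPos)
    pbest <- pos; pbestFit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]; gbestFit <- fit[g]
    trace <- numeric(pso$iterations)
    for (it in seq_len(pso$iterations)) {
      r1 <- matrix(runif(ns * 2), ns, 2)
      r2 <- matrix(runif(ns * 2), ns, 2)
      vel <- pso$inertia * vel +
        pso$cognitive * r1 * (pbest - pos) +
        pso$social * r2 * (gbest[col(pos)] - pos)
      pos <- pos + vel
      pos[, 1] <- pmin(pmax(pos[, 1], lo[1]), hi[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lo[2]), hi[2])
      fit <- apply(pos, 1, evalPos)
      better <- fit > pbestFit
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbestFit[better] <- fit[better]
      g <- which.max(pbestFit)
      if (pbestFit[g] > gbestFit) {
        gbestFit <- pbestFit[g]; gbest <- pbest[g, ]
      }
      trace[it] <- gbestFit
    }
    list(C = 10^gbest[1], sigma = 10^gbest[2], fitness = gbestFit,
         trace = trace)
  })
}

#' Train the stage SVM
#'
#' Z-score standardises the features (statistics from these calibration
#' samples only) and fits a radial-basis SVM with one-vs-one multi-class
#' voting.
#'
#' @param features Calibration feature matrix (samples x dims).
#' @param labels Factor of stage labels.
#' @param params Named list or vector with \code{C} and \code{sigma}.
#' @param wavelet,level,mode,wavelengths Feature fingerprint stored in the
#'   model and enforced at prediction time.
#' @return A \linkS4class{StageModel}.
#' @export
trainStageSVM <- function(features, labels, params, wavelet = "db5",
                          level = 4L, mode = "symmetric",
                          wavelengths = numeric()) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need at least two classes")
  features <- as.matrix(features)
  ctr <- colMeans(features)
  sdev <- apply(features, 2, sd)
  sdev[sdev == 0] <- 1
  X <- scale(features, ctr, sdev)
  C <- unname(unlist(params)["C"]); sigma <- unname(unlist(params)["sigma"])
  fit <- e1071::svm(X, labels, kernel = "radial", cost = C,
                    gamma = 1 / (2 * sigma^2), scale = FALSE)
  new("StageModel", fit = fit, center = ctr, scale = sdev,
      wavelet = wavelet, mode = mode, level = as.integer(level),
      wavelengths = as.numeric(wavelengths),
      hyperparams = c(C = C, sigma = sigma), classes = levels(labels))
}

#' Predict stages for a feature matrix
#'
#' @param model A \linkS4class{StageModel}.
#' @param features Feature matrix (samples x dims) on the model's feature
#'   scale conventions (raw, unscaled).
#' @return Factor of predicted stages.
#' @export
predictStages <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model@center))
    stop(sprintf("feature dimension %d does not match the model's %d",
                 ncol(features), length(model@center)))
  X <- scale(features, model@center, model@scale)
  predict(model@fit, X)
}

#' Classification accuracy (%)
#'
#' @param model A \linkS4class{StageModel}.
#' @param features Feature matrix of the evaluation set.
#' @param labels True stage labels.
#' @return Accuracy as a percentage, rounded to two decimals (33/34 correct
#'   gives 97.06).
#' @export
evaluateAccuracy <- function(model, features, labels) {
  if (length(labels) == 0L) stop("empty evaluation set")
  pred <- predictStages(model, features)
  round(100 * mean(pred == as.character(labels)), 2)
}

#' Save / load a stage model
#'
#' Serialises the model (SVM fit, scaler, hyperparameters and feature
#' fingerprint) as a single archive.
#'
#' @param model A \linkS4class{StageModel}.
#' @param path Archive path (\code{.rds}).
#' @return \code{readStageModel} returns the \linkS4class{StageModel}.
#' @export
saveStageModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveStageModel
#' @export
readStageModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "StageModel"))
  model
}

#' Decomposition-level sweep
#'
#' Reproduces the level-sweep experiment: for each decomposition depth,
#' extract \code{[cA_k, cD_k]} features, split 66/34 stratified, tune
#' \code{(C, sigma)} by PSO on the calibration set, train, and evaluate both
#' sets. Rows whose feature dimension exceeds \code{dim_cap} (the raw
#' spectrum and, by default, the level-1 decomposition) are reported as
#' infeasible rather than fitted, mirroring the memory blow-up such input
#' widths cause at full scale; lift the cap to run them.
#'
#' @param samples A \linkS4class{SpectraSet} of labelled spectra.
#' @param wavelet Mother-wavelet name.
#' @param levels Integer vector of decomposition depths (default 2:7).
#' @param pso A \code{\link{psoConfig}}.
#' @param split_seed Seed for the calibration/verification split.
#' @param n_train,n_test Split sizes.
#' @param dim_cap Feature-width cap above which a row is marked infeasible
#'   (\code{Inf} lifts the cap).
#' @param include_raw Also report the raw-spectrum and level-1 rows.
#' @return Data frame with one row per configuration: \code{decomposition},
#'   \code{dimension}, \code{train_acc}, \code{test_acc} (percent),
#'   \code{test_correct}, \code{test_n} (the exact fraction behind
#'   \code{test_acc}), \code{seconds}, \code{feasible}.
#' @export
levelSweep <- function(samples, wavelet = "db5", levels = 2:7,
                       pso = psoConfig(), split_seed = 1L, n_train = 66L,
                       n_test = 34L, dim_cap = 300, include_raw = TRUE) {
  stopifnot(is(samples, "SpectraSet"))
  labels <- droplevels(stageLabels(samples))
  X <- spectra(samples)
  configs <- list()
  if (include_raw) {
    configs[["original"]] <- list(name = "original spectra", level = 0L,
                                  dim = nrow(X))
    configs[["1-level"]] <- list(name = "1-level", level = 1L,
                                 dim = 2L * coeffLength(nrow(X), wavelet))
  }
  for (k in levels) {
    nlen <- nrow(X)
    for (j in seq_len(k)) nlen <- coeffLength(nlen, wavelet)
    configs[[sprintf("%d-level", k)]] <-
      list(name = sprintf("%d-level", k), level = as.integer(k),
           dim = 2L * nlen)
  }
  split <- splitDataset(labels, n_train, n_test, seed = split_seed)
  rows <- lapply(configs, function(cf) {
    if (cf$dim > dim_cap) {
      return(data.frame(decomposition = cf$name, dimension = cf$dim,
                        train_acc = NA_real_, test_acc = NA_real_,
                        test_correct = NA_integer_, test_n = n_test,
                        seconds = NA_real_, feasible = FALSE))
    }
    t0 <- proc.time()[["elapsed"]]
    feats <- if (cf$level == 0L) t(X) else
      featureMatrix(X, wavelet, cf$level)
    best <- psoSearch(feats[split$train, , drop = FALSE],
                      labels[split$train], pso = pso)
    model <- trainStageSVM(feats[split$train, , drop = FALSE],
                           labels[split$train], best, wavelet = wavelet,
                           level = cf$level)
    trainAcc <- evaluateAccuracy(model, feats[split$train, , drop = FALSE],
                                 labels[split$train])
    testAcc <- evaluateAccuracy(model, feats[split$test, , drop = FALSE],
                                labels[split$test])
    nCorrect <- as.integer(round(testAcc / 100 * length(split$test)))
    data.frame(decomposition = cf$name, dimension = cf$dim,
               train_acc = trainAcc, test_acc = testAcc,
               test_correct = nCorrect, test_n = length(split$test),
               seconds = proc.time()[["elapsed"]] - t0, feasible = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
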