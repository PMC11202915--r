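# Physicochemical freshness indices and the storage-stage labelling rules
# built on them. Thresholds are strict: TVB-N > 20 mg/100 g or TVC > 7
# log10 CFU/g marks spoilage regardless of any other classification.

#' Myofibrillar fragmentation index
#'
#' Turbidity-based index of myofibril breakdown: absorbance of the adjusted
#' myofibril suspension at 540 nm scaled by 200.
#'
#' @param od540 Non-negative absorbance at 540 nm.
#' @return \code{od540 * 200}.
#' @export
#' @examples
#' mfi(0.5)  # 100
mfi <- function(od540) {
  if (!is.numeric(od540) || any(od540 < 0))
    stop("od540 must be a non-negative absorbance")
  od540 * 200
}

#' Total volatile basic nitrogen from a titration
#'
#' Semi-micro Kjeldahl titration: the HCl consumed by the sample above the
#' blank, converted to mg nitrogen per 100 g of sample
#' (\code{(V1 - V2) * c * 14 * 100 / (m * 10/100)}).
#'
#' @param V1 Sample titration volume (mL).
#' @param V2 Blank titration volume (mL), \code{V2 <= V1}.
#' @param c HCl concentration (mol/L), positive.
#' @param m Sample mass (g), positive.
#' @return TVB-N in mg/100 g.
#' @export
#' @examples
#' tvbn(V1 = 2.0, V2 = 0.1, c = 0.01, m = 10)  # 26.6
tvbn <- function(V1, V2, c, m) {
  if (any(V2 < 0) || any(V1 < V2))
    stop("titration volumes must satisfy V1 >= V2 >= 0")
  if (any(c <= 0) || any(m <= 0))
    stop("acid concentration and sample mass must be positive")
  (V1 - V2) * c * 14 * 100 / (m * 10 / 100)
}

#' Total viable count from plate counts
#'
#' Aggregates colony counts over suitable plates of two dilutions:
#' \code{N = sum(C) / ((n1 - n2) * d)}.
#'
#' @param C_sum Total colonies across the suitable plates (non-negative).
#' @param n1 Number of lower-dilution plates.
#' @param n2 Number of higher-dilution plates, \code{n2 < n1}.
#' @param d Dilution factor (e.g. \code{1e-4}), positive.
#' @return List with \code{N} (CFU/g) and \code{log10N} (\code{NA} when no
#'   colonies were counted).
#' @export
#' @examples
#' tvc(C_sum = 300, n1 = 2, n2 = 1, d = 1e-4)  # N = 3e6, log10N ~ 6.477
tvc <- function(C_sum, n1, n2, d) {
  if (C_sum < 0) stop("colony count must be non-negative")
  if (n2 < 0 || n1 <= n2)
    stop("invalid plate design: need n1 > n2 >= 0")
  if (d <= 0) stop("dilution factor must be positive")
  N <- C_sum / ((n1 - n2) * d)
  list(N = N, log10N = if (N > 0) log10(N) else NA_real_)
}

#' Spoilage rule
#'
#' A sample is spoiled once TVB-N exceeds 20 mg/100 g or TVC exceeds
#' 7 log10 CFU/g; both comparisons are strict, so equality at either
#' threshold is not spoilage.
#'
#' @param TVBN TVB-N in mg/100 g.
#' @param TVC_log TVC in log10 CFU/g.
#' @return Logical.
#' @export
#' @examples
#' isSpoiled(TVBN = 20, TVC_log = 7)    # FALSE (strict thresholds)
#' isSpoiled(TVBN = 25, TVC_log = 5)    # TRUE
isSpoiled <- function(TVBN, TVC_log) {
  if (missing(TVBN) || missing(TVC_log) || anyNA(TVBN) || anyNA(TVC_log))
    stop("both TVBN and TVC_log are required")
  TVBN > 20 | TVC_log > 7
}

#' Stage-label a physicochemical trajectory
#'
#' Assigns per-day stages to one animal's index trajectory:
#' \enumerate{
#'   \item spoilage first — any day with \code{TVBN > 20} or \code{TVC_log
#'     > 7} is \code{SPOILED}, overriding everything else;
#'   \item \code{RIGOR} on days where WBSF is within \code{plateau_rel_tol}
#'     (relative) of its maximum \emph{and} pH within the same tolerance of
#'     its minimum — the hardness peak coinciding with the acid trough;
#'   \item \code{AGED} from the first day after the WBSF maximum whose
#'     day-over-day relative WBSF decrease falls below
#'     \code{plateau_rel_tol} (tenderisation has plateaued), through to
#'     spoilage;
#'   \item remaining days are \code{TRANSITIONAL}.
#' }
#'
#' @param traj Data frame with columns \code{day} (strictly increasing
#'   integers), \code{pH}, \code{WBSF}, \code{TVBN}, \code{TVC_log}; at least
#'   three days.
#' @param plateau_rel_tol Relative tolerance operationalising "no longer
#'   significantly reduced" (default 0.05).
#' @return Factor of stage labels, one per row of \code{traj}.
#' @export
#' @examples
#' tr <- simulateTrajectories(1, seed = 1)
#' table(labelTrajectory(tr))
labelTrajectory <- function(traj, plateau_rel_tol = 0.05) {
  need <- c("day", "pH", "WBSF", "TVBN", "TVC_log")
  if (!all(need %in% names(traj))) stop("missing trajectory columns")
  if (nrow(traj) < 3L) stop("need at least three days of records")
  if (any(diff(traj$day) <= 0)) stop("day index must be strictly increasing")
  n <- nrow(traj)
  lab <- rep("TRANSITIONAL", n)

  wmax <- max(traj$WBSF)
  pmin_ <- min(traj$pH)
  rigor <- abs(traj$WBSF - wmax) <= plateau_rel_tol * wmax &
    abs(traj$pH - pmin_) <= plateau_rel_tol * pmin_
  lab[rigor] <- "RIGOR"

  ipeak <- which.max(traj$WBSF)
  if (ipeak < n) {
    relDec <- (traj$WBSF[-n] - traj$WBSF[-1]) / traj$WBSF[-n]  # day i -> i+1
    agedFrom <- NA_integer_
    for (i in (ipeak + 1L):n) {
      if (relDec[i - 1L] < plateau_rel_tol) { agedFrom <- i; break }
    }
    if (!is.na(agedFrom)) lab[agedFrom:n] <- "AGED"
  }

  lab[isSpoiled(traj$TVBN, traj$TVC_log)] <- "SPOILED"
  factor(lab, levels = stageLevels())
}

#' Label a multi-animal cohort
#'
#' Applies \code{\link{labelTrajectory}} per animal and returns the table with
#' a \code{label} column appended.
#'
#' @param cohort Data frame as produced by \code{\link{simulateTrajectories}}
#'   (columns \code{animal}, \code{day}, \code{pH}, \code{WBSF}, \code{MFI},
#'   \code{TVBN}, \code{TVC_log}).
#' @param plateau_rel_tol Passed to \code{\link{labelTrajectory}}.
#' @return The cohort data frame with a \code{label} factor column.
#' @export
labelCohort <- function(cohort, plateau_rel_tol = 0.05) {
  parts <- split(cohort, cohort$animal)
  labelled <- lapply(parts, function(tr) {
    tr$label <- labelTrajectory(tr, plateau_rel_tol)
    tr
  })
  out <- do.call(rbind, labelled)
  rownames(out) <- NULL
  out
}

#' Select a fixed class design from a labelled cohort
#'
#' Draws the requested number of sample-days per modelling stage (default
#' 30 rigor / 40 aged / 30 spoiled) from a labelled cohort; transitional
#' sample-days are never selected.
#'
#' @param labelled Data frame with a \code{label} column
#'   (\code{\link{labelCohort}} output).
#' @param n Named integer vector of per-stage sample counts.
#' @param seed Integer seed for the within-stage draw.
#' @return Subset of \code{labelled} with \code{sum(n)} rows.
#' @export
selectDesign <- function(labelled, n = c(RIGOR = 30, AGED = 40, SPOILED = 30),
                         seed = 1L) {
  .withSeed(seed, {
    picks <- lapply(names(n), function(st) {
      idx <- which(labelled$label == st)
      if (length(idx) < n[[st]])
        stop(sprintf("only %d %s sample-days available, %d requested",
                     length(idx), st, n[[st]]))
      sort(sample(idx, n[[st]]))
    })
    labelled[unlist(picks), , drop = FALSE]
  })
}
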