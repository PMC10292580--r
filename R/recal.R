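# MS1 mass recalibration against internal calibrants: confidently assigned
# precursor-fragment groups supply (observed, theoretical) m/z pairs, a
# least-squares curve in the sqrt(m) basis is fitted per instrument model,
# and all precursor m/z are corrected before the pseudo-spectra are written.

#' Select internal calibrants from accepted precursor-fragment groups
#'
#' Keeps groups passing the confidence filters and deduplicates by peptide
#' (best hyperscore wins). When an engine-supplied expectation value is
#' present (column `expect`), the `maxExpect` threshold applies; otherwise a
#' hyperscore-based surrogate (`minHyperscore`) stands in for it.
#'
#' @param groups data.frame of accepted groups with columns `peptide`,
#'   `observedMz`, `theoreticalMz`, `hyperscore`, optionally `expect`.
#' @param maxExpect expectation-value threshold (default 0.001).
#' @param minHyperscore hyperscore floor used when no expect value exists.
#' @return data.frame of calibrant pairs (columns `peptide`, `observedMz`,
#'   `theoreticalMz`, `hyperscore`), possibly empty.
#' @export
selectCalibrants <- function(groups, maxExpect = 0.001, minHyperscore = 2) {
  if (nrow(groups) == 0L)
    return(data.frame(peptide = character(), observedMz = numeric(),
                      theoreticalMz = numeric(), hyperscore = numeric()))
  keep <- if ("expect" %in% names(groups) && !all(is.na(groups$expect)))
    !is.na(groups$expect) & groups$expect < maxExpect
  else groups$hyperscore >= minHyperscore
  g <- groups[keep, , drop = FALSE]
  if (nrow(g) == 0L) return(g[, c("peptide", "observedMz", "theoreticalMz",
                                  "hyperscore")])
  g <- g[order(-g$hyperscore), , drop = FALSE]
  g <- g[!duplicated(g$peptide), , drop = FALSE]
  g[, c("peptide", "observedMz", "theoreticalMz", "hyperscore")]
}

#' Fit an MS1 recalibration curve
#'
#' Least-squares fit of `m' = A m + B sqrt(m) + C` (time-of-flight;
#' three parameters) or `m' = A m + B sqrt(m)` (orbitrap; two parameters),
#' mapping observed to theoretical m/z.
#'
#' @param calibrants data.frame with columns `observedMz`, `theoreticalMz`
#'   (at least as many rows as fit parameters).
#' @param model "tof" or "orbitrap".
#' @return An [MzCalibration-class]; the post-fit RMS residual (ppm) never
#'   exceeds the pre-fit RMS.
#' @export
fitCalibration <- function(calibrants, model = c("tof", "orbitrap")) {
  model <- match.arg(model)
  m <- calibrants$observedMz
  y <- calibrants$theoreticalMz
  stopifnot(all(m > 0), all(y > 0))
  npar <- if (model == "tof") 3L else 2L
  if (length(m) < npar)
    stop("need at least ", npar, " calibrants for the ", model, " model")
  Xd <- if (model == "tof") cbind(m, sqrt(m), 1) else cbind(m, sqrt(m))
  qrX <- qr(Xd)
  if (qrX$rank < npar) stop("degenerate calibrant design (collinear m/z)")
  beta <- qr.coef(qrX, y)
  co <- c(A = beta[1], B = beta[2], C = if (npar == 3L) beta[3] else 0)
  names(co) <- c("A", "B", "C")
  fitted <- Xd %*% beta
  post <- sqrt(mean(((fitted - y) / y * 1e6)^2))
  pre <- sqrt(mean(((m - y) / y * 1e6)^2))
  stopifnot(post <= pre + 1e-9)
  new("MzCalibration", model = model, coefficients = co,
      residualPpm = post, nCalibrants = length(m))
}

#' Identity calibration (recalibration skipped)
#'
#' @return An [MzCalibration-class] that returns its input unchanged.
#' @export
identityCalibration <- function() {
  new("MzCalibration", model = "identity",
      coefficients = c(A = 1, B = 0, C = 0), residualPpm = NA_real_,
      nCalibrants = 0L)
}

#' Apply a recalibration curve to m/z values
#'
#' @param cal An [MzCalibration-class].
#' @param mz numeric vector of positive m/z values.
#' @return corrected m/z values.
#' @export
applyCalibration <- function(cal, mz) {
  stopifnot(all(mz > 0))
  co <- cal@coefficients
  unname(co["A"] * mz + co["B"] * sqrt(mz) + co["C"])
}
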