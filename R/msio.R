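# Reading DIA runs (mzML/mzXML via mzR), writing mzML for synthetic runs,
# and serializing pseudo-tandem spectra as MGF.

#' Read a DIA run from mzML or mzXML
#'
#' Loads all MS1/MS2 scans into a [DiaRun-class]. Retention times are
#' normalized to seconds. The isolation-window scheme is inferred from the
#' distinct MS2 windows of the first duty cycle. Profile and centroid data
#' are both accepted; no centroiding is performed (downstream binning
#' absorbs profile peaks).
#'
#' @param path path to an mzML or mzXML file.
#' @return A [DiaRun-class].
#' @export
readDiaRun <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (nrow(hd) == 0L) stop("no spectra in ", path)
  if (is.data.frame(pk)) pk <- list(as.matrix(pk))
  specs <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    lvl <- hd$msLevel[i]
    wl <- wu <- NA_real_
    if (lvl == 2L) {
      tgt <- hd$isolationWindowTargetMZ[i]
      lo <- hd$isolationWindowLowerOffset[i]
      uo <- hd$isolationWindowUpperOffset[i]
      if (is.na(tgt) || is.na(lo) || is.na(uo))
        stop("MS2 scan ", hd$acquisitionNum[i],
             " lacks an isolation window")
      wl <- tgt - lo; wu <- tgt + uo
    }
    m <- pk[[i]]
    specs[[i]] <- DiaSpectrum(
      scanId = hd$acquisitionNum[i], msLevel = lvl,
      rt = hd$retentionTime[i],
      mz = m[, 1], intensity = m[, 2],
      windowLower = wl, windowUpper = wu)
  }
  DiaRun(specs)
}

#' Write a DiaRun to mzML
#'
#' Serializes a run (typically from [simulateRun()]) through `mzR`, keeping
#' retention times, MS levels and isolation windows, so that runs round-trip
#' through [readDiaRun()].
#'
#' @param run a [DiaRun-class].
#' @param path output mzML path.
#' @return `path`, invisibly.
#' @export
writeMzML <- function(run, path) {
  sp <- spectra(run)
  n <- length(sp)
  stopifnot(n > 0)
  pks <- lapply(sp, function(s) cbind(mz = s@mz, intensity = s@intensity))
  lvl <- vapply(sp, function(s) s@msLevel, integer(1))
  ms2 <- lvl == 2L
  tgt <- vapply(sp, function(s)
    if (s@msLevel == 2L) (s@windowLower + s@windowUpper) / 2 else NA_real_,
    numeric(1))
  off <- vapply(sp, function(s)
    if (s@msLevel == 2L) (s@windowUpper - s@windowLower) / 2 else NA_real_,
    numeric(1))
  npk <- vapply(pks, nrow, integer(1))
  bpi <- vapply(pks, function(p)
    if (nrow(p)) max(p[, 2]) else 0, numeric(1))
  bpm <- vapply(pks, function(p)
    if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = vapply(pks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = vapply(sp, function(s) s@rt, numeric(1)),
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = ifelse(ms2, 25, NA_real_),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(pks, function(p)
      if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(p)
      if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = ifelse(ms2, 0L, NA_integer_),
    precursorMZ = ifelse(ms2, tgt, NA_real_),
    precursorCharge = ifelse(ms2, 0L, NA_integer_),
    precursorIntensity = ifelse(ms2, 0, NA_real_),
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_,
    mergedResultEndScanNum = NA_integer_,
    injectionTime = rep(0, n), filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = tgt,
    isolationWindowLowerOffset = off, isolationWindowUpperOffset = off,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}

#' Write pseudo-tandem spectra as MGF
#'
#' Standard Mascot Generic Format: one `BEGIN IONS`/`END IONS` block per
#' pseudo-spectrum with `TITLE`, `PEPMASS` (precursor m/z), signed `CHARGE`,
#' `RTINSECONDS`, then one `mz intensity` line per fragment.
#'
#' @param spectra nonempty list of [PseudoSpectrum-class] objects.
#' @param path output path.
#' @return number of blocks written, invisibly.
#' @export
writeMGF <- function(spectra, path) {
  if (length(spectra) == 0L)
    stop("no pseudo-spectra to write")
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (s in spectra) {
    stopifnot(is(s, "PseudoSpectrum"))
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s@title),
      sprintf("PEPMASS=%.5f", s@precursorMz),
      sprintf("CHARGE=%d+", s@charge),
      sprintf("RTINSECONDS=%.3f", s@rt),
      sprintf("%.5f %.6g", s@fragmentMz, s@fragmentIntensity),
      "END IONS"), con)
  }
  invisible(length(spectra))
}
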