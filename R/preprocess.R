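# Slider construction, m/z binning on the truncated grid, MS1 peak finding
# and deisotoping (candidate precursors), and the SNR filters that select
# candidate fragment XICs from MS2 data.

#' Bin one spectrum on the truncated m/z grid
#'
#' Accumulates peak intensities into a fixed-length vector: bin index =
#' `floor(mz * binsPerMz)`, vector length `ceiling(maxMz * binsPerMz)`
#' (36,000 at the defaults of 30 bins per 1 m/z and max m/z 1,200).
#' Binning starts from the zero vector; peaks at or beyond `maxMz` are
#' dropped with a warning.
#'
#' @param spectrum a [DiaSpectrum-class].
#' @param binsPerMz bins per 1 m/z unit (default 30).
#' @param maxMz truncation m/z (default 1200).
#' @return numeric intensity vector of length `ceiling(maxMz * binsPerMz)`
#'   with attributes `binsPerMz` and `maxMz`.
#' @export
binSpectrum <- function(spectrum, binsPerMz = 30, maxMz = 1200) {
  if (binsPerMz <= 0 || maxMz <= 0)
    stop("binsPerMz and maxMz must be positive")
  nbins <- as.integer(ceiling(maxMz * binsPerMz))
  v <- numeric(nbins)
  mz <- spectrum@mz
  int <- spectrum@intensity
  drop <- mz >= maxMz
  if (any(drop)) {
    warning(sum(drop), " peak(s) at m/z >= ", maxMz, " dropped")
    mz <- mz[!drop]; int <- int[!drop]
  }
  if (length(mz)) {
    idx <- floor(mz * binsPerMz) + 1L  # 1-based storage
    acc <- tapply(int, idx, sum)
    v[as.integer(names(acc))] <- as.numeric(acc)
  }
  attr(v, "binsPerMz") <- binsPerMz
  attr(v, "maxMz") <- maxMz
  v
}

# Sparse bins x scans matrix over a list of spectra (shared grid).
binSpectraMatrix <- function(spectra, binsPerMz = 30, maxMz = 1200) {
  nbins <- as.integer(ceiling(maxMz * binsPerMz))
  ii <- list(); jj <- list(); xx <- list()
  for (j in seq_along(spectra)) {
    s <- spectra[[j]]
    keep <- s@mz < maxMz
    if (!any(keep)) next
    idx <- floor(s@mz[keep] * binsPerMz) + 1L
    ii[[length(ii) + 1L]] <- idx
    jj[[length(jj) + 1L]] <- rep(j, length(idx))
    xx[[length(xx) + 1L]] <- s@intensity[keep]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nbins, length(spectra)))
}

#' Cut a run into fixed-width retention-time sliders
#'
#' Organizes the run into duty cycles (one MS1 scan plus one MS2 scan per
#' isolation window) and enumerates, for every window, all width-`width`
#' blocks of consecutive cycles at the given stride. Each slider carries the
#' binned MS1 block and the binned MS2 block of its window, drawn from the
#' same cycles.
#'
#' @param run a [DiaRun-class] with at least `width` duty cycles.
#' @param width slider width in cycles; also the XIC length (default 20).
#' @param stride cycle step between consecutive sliders (default 1).
#' @param binsPerMz,maxMz binning grid passed to the internal binning.
#' @return list of sliders; each is a list with `window` (index into the
#'   window scheme), `start` (first cycle, 1-based), `cycles`, `rt` (MS1 scan
#'   times, seconds), `ms1Block` and `ms2Block` (sparse bins x width
#'   matrices). Returns an empty list with a warning when the run has fewer
#'   cycles than `width`. Blocks of the same window share one binned matrix,
#'   so memory stays linear in run size.
#' @export
makeSliders <- function(run, width = 20, stride = 1,
                        binsPerMz = 30, maxMz = 1200) {
  cyc <- dutyCycles(run)
  ncyc <- length(cyc$ms1)
  if (ncyc < width) {
    warning("run has ", ncyc, " duty cycles, fewer than width ", width)
    return(list())
  }
  nwin <- nrow(windowScheme(run))
  sp <- spectra(run)
  ms1M <- binSpectraMatrix(sp[cyc$ms1], binsPerMz, maxMz)
  rtMs1 <- vapply(sp[cyc$ms1], function(s) s@rt, numeric(1))
  starts <- seq(1L, ncyc - width + 1L, by = stride)
  out <- vector("list", nwin * length(starts))
  oi <- 0L
  for (w in seq_len(nwin)) {
    ms2M <- binSpectraMatrix(sp[cyc$ms2[[w]]], binsPerMz, maxMz)
    for (s0 in starts) {
      oi <- oi + 1L
      cols <- s0:(s0 + width - 1L)
      out[[oi]] <- list(window = w, start = s0, cycles = cols,
                        rt = rtMs1[cols],
                        ms1Block = ms1M[, cols, drop = FALSE],
                        ms2Block = ms2M[, cols, drop = FALSE])
    }
  }
  out
}

# Group scans into duty cycles: each MS1 scan opens a cycle; the following
# MS2 scans are assigned to scheme windows by matching isolation bounds.
dutyCycles <- function(run) {
  sp <- spectra(run)
  ws <- windowScheme(run)
  lvl <- vapply(sp, function(s) s@msLevel, integer(1))
  ms1 <- which(lvl == 1L)
  nwin <- nrow(ws)
  ms2 <- replicate(nwin, integer(), simplify = FALSE)
  cur <- 0L
  slots <- matrix(NA_integer_, nrow = length(ms1), ncol = nwin)
  for (i in seq_along(sp)) {
    if (lvl[i] == 1L) {
      cur <- which(ms1 == i)
    } else if (cur > 0L) {
      w <- which(abs(ws$lower - sp[[i]]@windowLower) < 1e-6 &
                 abs(ws$upper - sp[[i]]@windowUpper) < 1e-6)
      if (length(w) != 1L)
        stop("MS2 scan ", sp[[i]]@scanId,
             " isolation window not in the run scheme")
      slots[cur, w] <- i
    }
  }
  # keep only complete cycles
  complete <- stats::complete.cases(slots)
  list(ms1 = ms1[complete],
       ms2 = lapply(seq_len(nwin), function(w) slots[complete, w]))
}

#' Find high-SNR peaks in the m/z dimension of an MS1 block
#'
#' Sums the block across its scans and reports local maxima of the summed
#' profile whose apex-to-baseline ratio reaches `snrMin`. The local baseline
#' is the median of the nonzero profile values within +-`halfWindow` bins,
#' excluding the apex +-1 bins and values above half the apex -- the latter
#' are peak-like (typically isotope companions of the same envelope) and
#' would otherwise mask genuine peaks. A peak with no remaining nonzero
#' neighborhood has infinite SNR.
#'
#' @param ms1Block bins x width matrix (sparse or dense) of binned MS1
#'   spectra.
#' @param snrMin minimum apex/baseline ratio (default 3).
#' @param halfWindow baseline neighborhood half-width in bins (default 15).
#' @param binRange optional c(lo, hi) restricting the search to a bin range
#'   (1-based), e.g. the isolation window of the slider.
#' @return sorted integer vector of peak bin indexes (1-based); empty for an
#'   all-zero block.
#' @export
findMs1Peaks <- function(ms1Block, snrMin = 3, halfWindow = 15,
                         binRange = NULL) {
  prof <- Matrix::rowSums(ms1Block)
  n <- length(prof)
  lo <- 1L; hi <- n
  if (!is.null(binRange)) {
    lo <- max(1L, binRange[1]); hi <- min(n, binRange[2])
  }
  nz <- which(prof > 0)
  nz <- nz[nz >= lo & nz <= hi]
  if (!length(nz)) return(integer())
  isMax <- vapply(nz, function(i) {
    if (i == 1L || i == n) return(FALSE)   # boundary bins are not peaks
    prof[i] > prof[i - 1L] && prof[i] >= prof[i + 1L]
  }, logical(1))
  cand <- nz[isMax]
  keep <- vapply(cand, function(i) {
    nb <- max(1L, i - halfWindow):min(n, i + halfWindow)
    nb <- setdiff(nb, (i - 1L):(i + 1L))
    base <- prof[nb][prof[nb] > 0 & prof[nb] <= prof[i] / 2]
    snr <- if (length(base)) prof[i] / stats::median(base) else Inf
    snr >= snrMin
  }, logical(1))
  sort(cand[keep])
}

#' Deisotope MS1 peaks and determine precursor charges
#'
#' For every detected peak, tests charges `1..maxCharge` by looking for
#' companion isotope peaks at +1.003355/z Th spacings on the binned grid.
#' An isotope companion must have a nonzero XIC that correlates with the
#' monoisotopic XIC (Pearson >= `corMin`) and a plausible envelope (apex at
#' most twice the previous isotope's). Peaks supporting at least `minIso`
#' consecutive isotopes become candidate precursors with the charge that
#' maximizes the isotope count (ties to the higher charge); peaks whose
#' charge cannot be determined are dropped.
#'
#' @param ms1Block bins x width matrix of binned MS1 spectra.
#' @param peakBins peak bin indexes from [findMs1Peaks()].
#' @param binsPerMz grid resolution used to build the block.
#' @param maxCharge maximum charge tested (default 5).
#' @param minIso minimum number of consecutive isotopes incl. the
#'   monoisotopic peak (default 2).
#' @param corMin minimum XIC Pearson correlation between isotopes.
#' @param minXicPoints minimum nonzero cycles of the monoisotopic XIC
#'   (default 3): a chromatographic peak spans several cycles, whereas
#'   background spikes hit single cycles and would otherwise correlate
#'   perfectly with a coincident spike at an isotope spacing.
#' @return list of candidate precursors: `bin` (1-based), `mz` (bin center,
#'   Th), `charge`, `xic` (length-width numeric).
#' @export
deisotope <- function(ms1Block, peakBins, binsPerMz = 30, maxCharge = 5,
                      minIso = 2, corMin = 0.6, minXicPoints = 3) {
  out <- list()
  n <- nrow(ms1Block)
  for (b in peakBins) {
    xic0 <- as.numeric(ms1Block[b, ])
    if (sum(xic0 > 0) < minXicPoints) next
    bestZ <- 0L; bestIso <- minIso - 1L
    for (z in seq_len(maxCharge)) {
      spacing <- .ISOTOPE_SPACING * binsPerMz / z
      niso <- 1L
      prevApex <- max(xic0)
      repeat {
        off <- niso * spacing
        cands <- unique(c(floor(off), ceiling(off))) + b
        cands <- cands[cands >= 1 & cands <= n]
        found <- FALSE
        for (bb in cands) {
          xic <- as.numeric(ms1Block[bb, ])
          if (sum(xic > 0) < 2L) next
          if (max(xic) > 2 * prevApex) next
          if (stats::sd(xic) == 0 || stats::sd(xic0) == 0) next
          if (stats::cor(xic, xic0) < corMin) next
          found <- TRUE
          prevApex <- max(xic)
          break
        }
        if (!found) break
        niso <- niso + 1L
        if (niso > 6L) break
      }
      if (niso > bestIso) { bestIso <- niso; bestZ <- z }
    }
    if (bestZ >= 1L && bestIso >= minIso) {
      out[[length(out) + 1L]] <- list(
        bin = b, mz = (b - 0.5) / binsPerMz, charge = bestZ, xic = xic0)
    }
  }
  out
}

#' Extract the XIC of one bin across a block
#'
#' @param block bins x width matrix of binned spectra.
#' @param binIndex 1-based bin index.
#' @return numeric vector of length `ncol(block)` in RT order.
#' @export
extractXic <- function(block, binIndex) {
  if (binIndex < 1 || binIndex > nrow(block))
    stop("bin index ", binIndex, " out of range")
  as.numeric(block[binIndex, ])
}

#' Select candidate fragments from an MS2 block by XIC SNR filters
#'
#' Keeps exactly the fragment XICs satisfying both background filters: the
#' number of nonzero XIC values must be greater than 5 (strict), and the
#' ratio of the maximum to the nonzero minimum must be larger than 4
#' (strict).
#'
#' @param ms2Block bins x width matrix of binned MS2 spectra.
#' @param binsPerMz grid resolution (for reporting bin-center m/z).
#' @param minNonzero nonzero-count threshold (default 5, exclusive).
#' @param minDynamicRatio max/min-nonzero threshold (default 4, exclusive).
#' @return list of candidate fragments: `bin`, `mz` (bin center), `xic`.
#' @export
filterFragmentXics <- function(ms2Block, binsPerMz = 30,
                               minNonzero = 5, minDynamicRatio = 4) {
  nnz <- Matrix::rowSums(ms2Block > 0)
  rows <- which(nnz > minNonzero)
  out <- list()
  for (b in rows) {
    xic <- as.numeric(ms2Block[b, ])
    nzv <- xic[xic > 0]
    if (max(nzv) / min(nzv) <= minDynamicRatio) next
    out[[length(out) + 1L]] <- list(bin = b, mz = (b - 0.5) / binsPerMz,
                                    xic = xic)
  }
  out
}
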