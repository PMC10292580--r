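#' @import methods
#' @importFrom stats rnorm runif rlnorm rpois median sd cor dpois setNames
#' @importFrom utils head tail
NULL

#' DiaSpectrum: a single MS scan
#'
#' One mass spectrum of a DIA run: scan number, MS level, retention time
#' (always seconds), an m/z-sorted peak list, and -- for MS2 scans -- the
#' precursor isolation window that was co-fragmented.
#'
#' @slot scanId integer scan number.
#' @slot msLevel integer, 1 or 2.
#' @slot rt retention time in seconds.
#' @slot mz strictly increasing numeric vector of m/z values (Th).
#' @slot intensity nonnegative numeric vector, same length as `mz`.
#' @slot windowLower,windowUpper isolation window bounds (Th) for MS2 scans;
#'   `NA` for MS1.
#'
#' @exportClass DiaSpectrum
setClass("DiaSpectrum",
  representation(
    scanId = "integer",
    msLevel = "integer",
    rt = "numeric",
    mz = "numeric",
    intensity = "numeric",
    windowLower = "numeric",
    windowUpper = "numeric"
  ),
  prototype(windowLower = NA_real_, windowUpper = NA_real_)
)

setValidity("DiaSpectrum", function(object) {
  msgs <- character()
  if (length(object@msLevel) != 1L || !object@msLevel %in% c(1L, 2L))
    msgs <- c(msgs, "msLevel must be 1 or 2")
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msgs <- c(msgs, "mz must be strictly increasing")
  if (any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be nonnegative")
  if (identical(object@msLevel, 2L) &&
      (is.na(object@windowLower) || is.na(object@windowUpper)))
    msgs <- c(msgs, "MS2 spectrum must carry an isolation window")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DiaSpectrum
#'
#' @param scanId scan number.
#' @param msLevel 1 or 2.
#' @param rt retention time in seconds.
#' @param mz numeric vector of m/z values; sorted internally.
#' @param intensity matching intensity vector.
#' @param windowLower,windowUpper isolation window bounds for MS2 scans.
#' @return A [DiaSpectrum-class] object.
#' @export
DiaSpectrum <- function(scanId, msLevel, rt, mz, intensity,
                        windowLower = NA_real_, windowUpper = NA_real_) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  # merge coincident m/z so the strictly-increasing invariant holds
  if (length(mz) > 1L && any(diff(mz) == 0)) {
    key <- cumsum(c(TRUE, diff(mz) > 0))
    intensity <- as.numeric(tapply(intensity, key, sum))
    mz <- mz[!duplicated(key)]
  }
  new("DiaSpectrum", scanId = as.integer(scanId),
      msLevel = as.integer(msLevel), rt = as.numeric(rt),
      mz = as.numeric(mz), intensity = as.numeric(intensity),
      windowLower = as.numeric(windowLower),
      windowUpper = as.numeric(windowUpper))
}

#' DiaRun: an RT-ordered collection of DIA scans
#'
#' @slot spectra list of [DiaSpectrum-class], nondecreasing in retention time.
#' @slot windowScheme data.frame with columns `lower`, `upper`: the ordered
#'   isolation-window scheme of one duty cycle.
#'
#' @exportClass DiaRun
setClass("DiaRun",
  representation(spectra = "list", windowScheme = "data.frame")
)

setValidity("DiaRun", function(object) {
  msgs <- character()
  if (!all(vapply(object@spectra, is, logical(1), "DiaSpectrum")))
    msgs <- c(msgs, "spectra must all be DiaSpectrum objects")
  rts <- vapply(object@spectra, function(s) s@rt, numeric(1))
  if (length(rts) > 1L && any(diff(rts) < 0))
    msgs <- c(msgs, "spectra must be ordered by nondecreasing RT")
  if (nrow(object@windowScheme) &&
      !all(c("lower", "upper") %in% names(object@windowScheme)))
    msgs <- c(msgs, "windowScheme needs columns lower and upper")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DiaRun
#' @param spectra list of [DiaSpectrum-class] objects (any order; sorted by RT).
#' @param windowScheme optional data.frame(lower, upper); inferred from the
#'   first duty cycle when omitted.
#' @return A [DiaRun-class].
#' @export
DiaRun <- function(spectra, windowScheme = NULL) {
  rts <- vapply(spectra, function(s) s@rt, numeric(1))
  spectra <- spectra[order(rts)]
  if (is.null(windowScheme)) windowScheme <- inferWindowScheme(spectra)
  new("DiaRun", spectra = spectra, windowScheme = windowScheme)
}

# Distinct MS2 windows of the first duty cycle, in order of appearance.
inferWindowScheme <- function(spectra) {
  lows <- ups <- numeric()
  started <- FALSE
  for (s in spectra) {
    if (s@msLevel == 1L) {
      if (started) break
      started <- TRUE
    } else if (started) {
      if (length(lows) && any(abs(lows - s@windowLower) < 1e-6 &
                              abs(ups - s@windowUpper) < 1e-6)) break
      lows <- c(lows, s@windowLower)
      ups <- c(ups, s@windowUpper)
    }
  }
  data.frame(lower = lows, upper = ups)
}

#' PseudoSpectrum: a deconvolved precursor with its fragment peaks
#'
#' The end product of the deconvolution: one precursor (recalibrated m/z,
#' charge, apex retention time) together with the fragment peaks accepted
#' for it, serializable as one MGF `BEGIN IONS` block.
#'
#' @slot title character identifier, `<run>.<window>.<slider>.<rank>`.
#' @slot precursorMz precursor m/z in Th (after recalibration).
#' @slot charge integer precursor charge, >= 1.
#' @slot rt apex retention time in seconds.
#' @slot fragmentMz,fragmentIntensity parallel numeric vectors (nonempty,
#'   intensities > 0).
#'
#' @exportClass PseudoSpectrum
setClass("PseudoSpectrum",
  representation(
    title = "character",
    precursorMz = "numeric",
    charge = "integer",
    rt = "numeric",
    fragmentMz = "numeric",
    fragmentIntensity = "numeric"
  )
)

setValidity("PseudoSpectrum", function(object) {
  msgs <- character()
  if (length(object@fragmentMz) == 0L)
    msgs <- c(msgs, "fragment list must be nonempty")
  if (length(object@fragmentMz) != length(object@fragmentIntensity))
    msgs <- c(msgs, "fragment mz/intensity length mismatch")
  if (any(object@fragmentIntensity <= 0))
    msgs <- c(msgs, "fragment intensities must be > 0")
  if (object@charge < 1L) msgs <- c(msgs, "charge must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PseudoSpectrum
#' @param title text identifier.
#' @param precursorMz precursor m/z (Th).
#' @param charge precursor charge.
#' @param rt apex RT in seconds.
#' @param fragmentMz,fragmentIntensity fragment peak list.
#' @return A [PseudoSpectrum-class].
#' @export
PseudoSpectrum <- function(title, precursorMz, charge, rt,
                           fragmentMz, fragmentIntensity) {
  o <- order(fragmentMz)
  new("PseudoSpectrum", title = title, precursorMz = precursorMz,
      charge = as.integer(charge), rt = rt,
      fragmentMz = fragmentMz[o], fragmentIntensity = fragmentIntensity[o])
}

#' PeptideIndex: in-silico digest plus inverted query tables
#'
#' Holds the digested peptide entries (one row per peptide/modification/charge
#' combination) and the two inverted-index tables: precursor (m/z bin, charge)
#' -> peptide index set, and fragment m/z bin -> peptide index set.
#'
#' @slot entries data.frame of peptide entries; columns `index`, `sequence`,
#'   `mods`, `charge`, `precursorMz` plus list-columns `fragMz` and `fragType`.
#' @slot precursorTable,fragmentTable environments used as hash maps.
#' @slot binsPerMz integer binning resolution shared with the query functions.
#'
#' @exportClass PeptideIndex
setClass("PeptideIndex",
  representation(
    entries = "data.frame",
    precursorTable = "environment",
    fragmentTable = "environment",
    binsPerMz = "integer"
  )
)

#' MzCalibration: fitted MS1 mass-recalibration curve
#'
#' @slot model "tof" (m' = A m + B sqrt(m) + C), "orbitrap"
#'   (m' = A m + B sqrt(m)) or "identity".
#' @slot coefficients named numeric vector (A, B, C).
#' @slot residualPpm post-fit root-mean-square residual in ppm.
#' @slot nCalibrants number of calibrant pairs used.
#'
#' @exportClass MzCalibration
setClass("MzCalibration",
  representation(
    model = "character",
    coefficients = "numeric",
    residualPpm = "numeric",
    nCalibrants = "integer"
  )
)

#' VaeModel: trained triplet-loss variational autoencoder
#'
#' @slot params named list of weight/bias matrices for the 4-branch encoder
#'   and mirrored decoder.
#' @slot arch architecture description (branch widths, latent dim, input dim).
#' @slot config training configuration (normalization, sampling mode, dropout).
#' @slot history numeric vector of per-epoch mean total losses.
#'
#' @exportClass VaeModel
setClass("VaeModel",
  representation(params = "list", arch = "list", config = "list",
                 history = "numeric")
)

#' CnnModel: trained co-elution similarity classifier
#'
#' @slot params named list of convolution and fully connected weights.
#' @slot config training configuration.
#' @slot history numeric vector of per-epoch mean BCE losses.
#'
#' @exportClass CnnModel
setClass("CnnModel",
  representation(params = "list", config = "list", history = "numeric")
)

## ---- show methods ----

setMethod("show", "DiaSpectrum", function(object) {
  cat(sprintf("DiaSpectrum scan %d | MS%d | RT %.2f s | %d peaks",
              object@scanId, object@msLevel, object@rt, length(object@mz)))
  if (object@msLevel == 2L)
    cat(sprintf(" | window [%.2f, %.2f]", object@windowLower,
                object@windowUpper))
  cat("\n")
})

setMethod("show", "DiaRun", function(object) {
  lv <- vapply(object@spectra, function(s) s@msLevel, integer(1))
  cat(sprintf("DiaRun: %d spectra (%d MS1, %d MS2), %d isolation windows\n",
              length(lv), sum(lv == 1L), sum(lv == 2L),
              nrow(object@windowScheme)))
})

setMethod("show", "PseudoSpectrum", function(object) {
  cat(sprintf(
    "PseudoSpectrum '%s': %.4f Th (%d+), RT %.1f s, %d fragments\n",
    object@title, object@precursorMz, object@charge, object@rt,
    length(object@fragmentMz)))
})

setMethod("show", "PeptideIndex", function(object) {
  cat(sprintf(
    "PeptideIndex: %d peptide entries, %d precursor keys, %d fragment keys\n",
    nrow(object@entries), length(ls(object@precursorTable)),
    length(ls(object@fragmentTable))))
})

setMethod("show", "MzCalibration", function(object) {
  co <- object@coefficients
  cat(sprintf(
    "MzCalibration (%s): A=%.8g B=%.4g C=%.4g | RMS %.3f ppm | n=%d\n",
    object@model, co["A"], co["B"], co["C"], object@residualPpm,
    object@nCalibrants))
})

setMethod("show", "VaeModel", function(object) {
  cat(sprintf("VaeModel: input %d -> latent %d, %d epochs trained\n",
              object@arch$input, object@arch$latent, length(object@history)))
})

setMethod("show", "CnnModel", function(object) {
  cat(sprintf("CnnModel: 6x20 co-elution classifier, %d epochs trained\n",
              length(object@history)))
})

## ---- accessors ----

#' Accessors for DIAdeconv S4 objects
#'
#' Small generics in place of direct slot access.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))
#' @rdname accessors
#' @export
setMethod("spectra", "DiaRun", function(object) object@spectra)

#' @rdname accessors
#' @export
setGeneric("windowScheme", function(object) standardGeneric("windowScheme"))
#' @rdname accessors
#' @export
setMethod("windowScheme", "DiaRun", function(object) object@windowScheme)

#' @rdname accessors
#' @export
setGeneric("msLevel", function(object) standardGeneric("msLevel"))
#' @rdname accessors
#' @export
setMethod("msLevel", "DiaSpectrum", function(object) object@msLevel)

#' @rdname accessors
#' @export
setGeneric("rtime", function(object) standardGeneric("rtime"))
#' @rdname accessors
#' @export
setMethod("rtime", "DiaSpectrum", function(object) object@rt)
#' @rdname accessors
#' @export
setMethod("rtime", "PseudoSpectrum", function(object) object@rt)

#' @rdname accessors
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))
#' @rdname accessors
#' @export
setMethod("peakTable", "DiaSpectrum", function(object)
  data.frame(mz = object@mz, intensity = object@intensity))
#' @rdname accessors
#' @export
setMethod("peakTable", "PseudoSpectrum", function(object)
  data.frame(mz = object@fragmentMz, intensity = object@fragmentIntensity))

#' @rdname accessors
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
#' @rdname accessors
#' @export
setMethod("precursorMz", "PseudoSpectrum", function(object) object@precursorMz)

#' @rdname accessors
#' @export
setGeneric("precursorCharge",
           function(object) standardGeneric("precursorCharge"))
#' @rdname accessors
#' @export
setMethod("precursorCharge", "PseudoSpectrum",
          function(object) object@charge)

#' @rdname accessors
#' @export
setGeneric("peptideEntries", function(object) standardGeneric("peptideEntries"))
#' @rdname accessors
#' @export
setMethod("peptideEntries", "PeptideIndex", function(object) object@entries)

#' @rdname accessors
#' @export
setGeneric("calCoefficients",
           function(object) standardGeneric("calCoefficients"))
#' @rdname accessors
#' @export
setMethod("calCoefficients", "MzCalibration",
          function(object) object@coefficients)

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setMethod("lossHistory", "VaeModel", function(object) object@history)
#' @rdname accessors
#' @export
setMethod("lossHistory", "CnnModel", function(object) object@history)

#' @rdname accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setMethod("modelParams", "VaeModel", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("modelParams", "CnnModel", function(object) object@params)
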