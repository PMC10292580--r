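# End-to-end orchestration per slider and per run: preprocess -> embed ->
# cluster -> inverted-index match -> CNN co-elution gate -> second
# clustering pass -> deduplicate across overlapping sliders -> recalibrate
# precursor m/z -> write MGF.

#' Pipeline configuration
#'
#' @param width,stride slider geometry (defaults 20 / 1).
#' @param binsPerMz,maxMz binning grid (defaults 30 / 1200).
#' @param snrMin MS1 peak-finding SNR threshold (default 3).
#' @param maxCharge deisotoping charge cap (default 5).
#' @param theta CNN acceptance threshold (default 0.5, strict).
#' @param minMatched minimum matched fragments for an acceptable group.
#' @param tolPpm precursor match tolerance in ppm.
#' @param tolMzPrecursor absolute precursor tolerance floor in Th; the
#'   default of one bin width reflects that candidate precursor m/z are
#'   read off the binned grid.
#' @param tolMzFragment fragment match tolerance in Th.
#' @param recalModel instrument model for recalibration ("tof",
#'   "orbitrap", or "none").
#' @param minCalibrants skip recalibration below this many calibrants.
#' @param minHyperscoreCalibrant hyperscore floor for calibrant selection.
#' @param seed master seed; all per-slider clustering seeds derive from it.
#' @param runName prefix of pseudo-spectrum titles.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(width = 20, stride = 1, binsPerMz = 30,
                           maxMz = 1200, snrMin = 3, maxCharge = 5,
                           theta = 0.5, minMatched = 3, tolPpm = 20,
                           tolMzPrecursor = 1 / binsPerMz,
                           tolMzFragment = 0.03, recalModel = "tof",
                           minCalibrants = 5, minHyperscoreCalibrant = 2,
                           seed = 1, runName = "run") {
  structure(as.list(environment()), class = "PipelineConfig")
}

# One matching/gating stage over a set of fragments and unassigned
# precursors. Returns accepted groups (list) and the ids of fragments and
# precursors they consumed.
matchStage <- function(fragments, fragIds, precursors, precIds, embeddings,
                       index, cnn, config, seed) {
  n <- length(fragIds)
  k <- max(1L, min(length(precIds), n))
  cl <- kmeansCluster(embeddings[fragIds, , drop = FALSE], k, seed = seed)
  groups <- list()
  usedFrag <- integer()
  usedPrec <- integer()
  for (c in seq_len(k)) {
    member <- fragIds[cl$labels == c]
    if (!length(member)) next
    clFrags <- fragments[member]
    best <- NULL; bestPrec <- NA_integer_
    for (pi in precIds) {
      m <- matchCluster(index, precursors[[pi]], clFrags,
                        tolPpm = config$tolPpm,
                        tolMzPrecursor = config$tolMzPrecursor,
                        tolMzFragment = config$tolMzFragment)
      if (!nrow(m)) next
      if (is.null(best) || m$hyperscore[1] > best$hyperscore[1]) {
        best <- m[1, , drop = FALSE]; bestPrec <- pi
      }
    }
    if (is.null(best)) next
    if (length(best$matchedFrag[[1]]) < config$minMatched) next
    mfLocal <- best$matchedFrag[[1]]
    mfIds <- member[mfLocal]
    xics <- do.call(rbind, lapply(fragments[mfIds], `[[`, "xic"))
    score <- scoreGroup(buildGroupMatrix(xics), cnn)
    if (!acceptGroup(score, config$theta)) next
    groups[[length(groups) + 1L]] <- list(
      precursor = bestPrec, peptideIndex = best$index,
      sequence = best$sequence, mods = best$mods,
      hyperscore = best$hyperscore, Nb = best$Nb, Ny = best$Ny,
      cnnScore = score, fragIds = mfIds)
    usedFrag <- c(usedFrag, mfIds)
    usedPrec <- c(usedPrec, bestPrec)
  }
  list(groups = groups, usedFrag = usedFrag, usedPrec = unique(usedPrec),
       nClusters = k)
}

#' Deconvolve one slider
#'
#' Stage 1: detect candidate precursors (MS1 peak finding + deisotoping
#' inside the slider's isolation window) and candidate fragments (SNR
#' filters), embed the fragment XICs, cluster with k = number of candidate
#' precursors, assign each cluster to its best-scoring peptide via the
#' inverted index, and gate by CNN co-elution similarity. Stage 2: remove
#' the fragments of accepted groups, re-cluster the remainder with k2 =
#' number of unmatched precursors, and repeat matching/gating once.
#'
#' @param slider one slider from [makeSliders()].
#' @param index a [PeptideIndex-class].
#' @param vae trained [VaeModel-class].
#' @param cnn trained [CnnModel-class].
#' @param config a `PipelineConfig`.
#' @param windowBounds c(lower, upper) of the slider's isolation window.
#' @param seed clustering seed for this slider.
#' @return list with `groups` (accepted precursor-fragment groups carrying
#'   peptide assignment, hyperscore, CNN score, apex cycle/RT and matched
#'   fragment peaks) and stage counts; empty groups when the slider has no
#'   candidates.
#' @export
processSlider <- function(slider, index, vae, cnn, config = pipelineConfig(),
                          windowBounds = NULL, seed = config$seed) {
  binRange <- NULL
  if (!is.null(windowBounds))
    binRange <- c(floor(windowBounds[1] * config$binsPerMz) + 1L,
                  floor(windowBounds[2] * config$binsPerMz) + 1L)
  peaks <- findMs1Peaks(slider$ms1Block, snrMin = config$snrMin,
                        binRange = binRange)
  precursors <- deisotope(slider$ms1Block, peaks,
                          binsPerMz = config$binsPerMz,
                          maxCharge = config$maxCharge)
  fragments <- filterFragmentXics(slider$ms2Block,
                                  binsPerMz = config$binsPerMz)
  empty <- list(groups = list(), nPrecursors = length(precursors),
                nFragments = length(fragments), nClusters = 0L,
                nClusters2 = 0L)
  if (!length(precursors) || !length(fragments)) return(empty)

  emb <- embedXics(do.call(rbind, lapply(fragments, `[[`, "xic")), vae)
  st1 <- matchStage(fragments, seq_along(fragments), precursors,
                    seq_along(precursors), emb, index, cnn, config, seed)
  groups <- st1$groups
  nClusters2 <- 0L
  remFrag <- setdiff(seq_along(fragments), st1$usedFrag)
  remPrec <- setdiff(seq_along(precursors), st1$usedPrec)
  if (length(remFrag) && length(remPrec)) {
    st2 <- matchStage(fragments, remFrag, precursors, remPrec, emb, index,
                      cnn, config, seed + 1L)
    groups <- c(groups, st2$groups)
    nClusters2 <- st2$nClusters
    stopifnot(nClusters2 <= length(remFrag))
  }
  # annotate groups with slider context
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    prec <- precursors[[g$precursor]]
    apexIdx <- which.max(prec$xic)
    groups[[i]]$observedMz <- prec$mz
    groups[[i]]$charge <- prec$charge
    groups[[i]]$apexCycle <- slider$start + apexIdx - 1L
    groups[[i]]$apexRt <- slider$rt[apexIdx]
    groups[[i]]$fragmentMz <- vapply(fragments[g$fragIds], `[[`,
                                     numeric(1), "mz")
    groups[[i]]$fragmentIntensity <- vapply(fragments[g$fragIds],
                                            function(f) max(f$xic),
                                            numeric(1))
  }
  # fragment-disjointness and per-stage count monotonicity invariants
  allIds <- unlist(lapply(groups, `[[`, "fragIds"))
  stopifnot(!anyDuplicated(allIds),
            length(groups) <= st1$nClusters + nClusters2,
            st1$nClusters <= length(fragments))
  list(groups = groups, nPrecursors = length(precursors),
       nFragments = length(fragments), nClusters = st1$nClusters,
       nClusters2 = nClusters2)
}

#' Run the full deconvolution pipeline on a DIA run
#'
#' @param run a [DiaRun-class] or a path to an mzML/mzXML file.
#' @param index a [PeptideIndex-class], a FASTA path, or a named vector of
#'   protein sequences (digested and indexed on the fly).
#' @param vae trained [VaeModel-class].
#' @param cnn trained [CnnModel-class].
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param mgfPath optional output MGF path; written when given.
#' @return list (run report) with `pseudoSpectra` (list of
#'   [PseudoSpectrum-class]), `groups` (data.frame of accepted groups after
#'   deduplication), `calibration` (an [MzCalibration-class]), per-stage
#'   `counts`, and `mgfPath`.
#' @export
runPipeline <- function(run, index, vae, cnn, config = pipelineConfig(),
                        mgfPath = NULL) {
  if (is.character(run)) run <- readDiaRun(run)
  ws <- windowScheme(run)
  if (!is(index, "PeptideIndex")) {
    entries <- digestFasta(index, charges = seq_len(config$maxCharge),
                           mzRange = c(min(ws$lower) - 1, max(ws$upper) + 1))
    index <- buildInvertedIndex(entries, binsPerMz = config$binsPerMz)
  }
  sliders <- makeSliders(run, width = config$width, stride = config$stride,
                         binsPerMz = config$binsPerMz, maxMz = config$maxMz)
  rows <- list()
  counts <- c(precursors = 0, fragments = 0, clusters = 0, accepted = 0)
  for (sl in sliders) {
    seed <- (config$seed * 7L + sl$window * 7919L + sl$start) %%
      .Machine$integer.max
    res <- processSlider(sl, index, vae, cnn, config,
                         windowBounds = c(ws$lower[sl$window],
                                          ws$upper[sl$window]),
                         seed = seed)
    counts <- counts + c(res$nPrecursors, res$nFragments,
                         res$nClusters + res$nClusters2,
                         length(res$groups))
    for (g in res$groups) {
      rows[[length(rows) + 1L]] <- data.frame(
        window = sl$window, slider = sl$start,
        peptideIndex = g$peptideIndex, peptide = g$sequence,
        mods = g$mods, charge = g$charge, observedMz = g$observedMz,
        apexCycle = g$apexCycle, apexRt = g$apexRt,
        hyperscore = g$hyperscore, cnnScore = g$cnnScore,
        nFragments = length(g$fragmentMz))
      rows[[length(rows)]]$fragmentMz <- list(g$fragmentMz)
      rows[[length(rows)]]$fragmentIntensity <- list(g$fragmentIntensity)
    }
  }
  stopifnot(counts["accepted"] <= counts["clusters"] ||
              counts["clusters"] == 0)

  if (!length(rows)) {
    warning("no precursor-fragment groups accepted; empty output")
    if (!is.null(mgfPath)) file.create(mgfPath)
    return(list(pseudoSpectra = list(),
                groups = data.frame(), calibration = identityCalibration(),
                counts = counts, mgfPath = mgfPath))
  }
  groups <- do.call(rbind, rows)

  # consolidate the same peptide elution seen in overlapping sliders:
  # same peptide entry within width/2 cycles keeps the best hyperscore
  groups <- groups[order(-groups$hyperscore), , drop = FALSE]
  keep <- rep(TRUE, nrow(groups))
  for (i in seq_len(nrow(groups))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(groups)) > i &
                   groups$peptideIndex == groups$peptideIndex[i] &
                   abs(groups$apexCycle - groups$apexCycle[i]) <=
                     config$width / 2)
    keep[later] <- FALSE
  }
  groups <- groups[keep, , drop = FALSE]

  # internal calibrants -> global recalibration of precursor m/z
  calibration <- identityCalibration()
  if (config$recalModel %in% c("tof", "orbitrap")) {
    theo <- index@entries$precursorMz[match(groups$peptideIndex,
                                            index@entries$index)]
    calInput <- data.frame(peptide = groups$peptide,
                           observedMz = groups$observedMz,
                           theoreticalMz = theo,
                           hyperscore = groups$hyperscore)
    cal <- selectCalibrants(calInput,
                            minHyperscore = config$minHyperscoreCalibrant)
    if (nrow(cal) >= max(config$minCalibrants,
                         if (config$recalModel == "tof") 3L else 2L)) {
      calibration <- fitCalibration(cal, model = config$recalModel)
    } else {
      warning("too few calibrants (", nrow(cal), "); recalibration skipped")
    }
  }
  groups$precursorMz <- applyCalibration(calibration, groups$observedMz)

  groups <- groups[order(groups$window, groups$slider,
                         -groups$hyperscore), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(groups)),
                     paste(groups$window, groups$slider),
                     FUN = seq_along)
  pseudo <- lapply(seq_len(nrow(groups)), function(i) {
    PseudoSpectrum(
      title = sprintf("%s.%d.%d.%d", config$runName, groups$window[i],
                      groups$slider[i], rank[i]),
      precursorMz = groups$precursorMz[i], charge = groups$charge[i],
      rt = groups$apexRt[i], fragmentMz = groups$fragmentMz[[i]],
      fragmentIntensity = groups$fragmentIntensity[[i]])
  })
  if (!is.null(mgfPath)) writeMGF(pseudo, mgfPath)
  list(pseudoSpectra = pseudo, groups = groups, calibration = calibration,
       counts = counts, config = config, mgfPath = mgfPath)
}
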