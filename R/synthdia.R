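# Synthetic SWATH run generator with full ground truth. Emulates the
# acquisition geometry of a SWATH experiment -- interleaved duty cycles of
# one MS1 scan plus one MS2 scan per isolation window -- with Gaussian
# elution profiles shared between each precursor and its fragments, isotope
# envelopes at 1.003355/z spacing, charge states, per-peak intensity
# jitter, and Poisson-placed background noise ions. Used to train the VAE
# and CNN and to validate the whole pipeline against known truth.

#' Configuration of the synthetic SWATH run generator
#'
#' Defaults describe a compact but realistic single-run experiment: three
#' 200-Th isolation windows covering 400-1000 Th, 60 duty cycles, peptides
#' of charge 2-3 eluting as Gaussians of 1.5-4 cycles s.d. (so one peak
#' fits inside a width-20 slider and is recorded once), >= 6 observable
#' fragments per peptide with log-normal relative intensities, apex
#' signal-to-noise drawn from 10-100 against a log-normal(log 50, 0.5)
#' background, and Poisson background ion counts of 30 (MS1) and 50 (MS2)
#' per scan. 5% log-normal jitter models shot noise on every peak.
#'
#' @param nPeptides number of ground-truth peptides (default 20).
#' @param windows data.frame(lower, upper) isolation window scheme.
#' @param nCycles number of duty cycles (default 60).
#' @param cycleTime duty cycle duration in seconds (default 1).
#' @param charges precursor charge states sampled (default 2:3).
#' @param nFragments range of observable fragments per peptide.
#' @param sigmaCycles range of elution peak s.d. in cycles.
#' @param snrRange apex signal-to-noise range relative to the median
#'   background intensity.
#' @param noiseMs1,noiseMs2 mean background ion count per MS1/MS2 scan.
#' @param noiseMeanlog,noiseSdlog log-normal background intensity
#'   parameters.
#' @param intensityCv per-peak multiplicative jitter (log-normal sd).
#' @param fragmentRange m/z range of fragment ions.
#' @param seed RNG seed; the same seed reproduces the run exactly.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(nPeptides = 20,
                      windows = data.frame(lower = c(400, 600, 800),
                                           upper = c(600, 800, 1000)),
                      nCycles = 60, cycleTime = 1, charges = 2:3,
                      nFragments = c(6, 10), sigmaCycles = c(1.5, 4),
                      snrRange = c(10, 100), noiseMs1 = 30, noiseMs2 = 50,
                      noiseMeanlog = log(50), noiseSdlog = 0.5,
                      intensityCv = 0.05, fragmentRange = c(150, 1195),
                      seed = 1) {
  structure(as.list(environment()), class = "SimConfig")
}

# Random tryptic-like peptide sequences whose precursor m/z falls inside
# one of the isolation windows.
randomPeptides <- function(sim) {
  res <- names(.RESIDUE_MASS)
  res <- setdiff(res, c("K", "R"))
  out <- list()
  guard <- 0L
  while (length(out) < sim$nPeptides && guard < 20000L) {
    guard <- guard + 1L
    len <- sample(8:14, 1L)
    s <- paste0(paste(sample(res, len - 1L, replace = TRUE), collapse = ""),
                sample(c("K", "R"), 1L))
    z <- sample(sim$charges, 1L)
    nC <- sum(strsplit(s, "")[[1]] == "C")
    mz <- peptideMz(s, z, modMass = nC * .MOD_CARBAMIDOMETHYL)
    if (!any(mz > sim$windows$lower & mz < sim$windows$upper)) next
    if (any(vapply(out, function(o) o$sequence == s, logical(1)))) next
    out[[length(out) + 1L]] <- list(sequence = s, charge = z, mz = mz)
  }
  out
}

#' Simulate a SWATH run with known ground truth
#'
#' @param sim a `SimConfig` from [simConfig()].
#' @param fasta optional FASTA path or named sequence vector; when given,
#'   ground-truth peptides are drawn from its tryptic digest (entries whose
#'   precursor falls inside an isolation window and that have enough
#'   fragments in range); otherwise random tryptic-like sequences are
#'   generated. Peptides with m/z outside all windows are skipped with a
#'   warning.
#' @return list with `run` (a [DiaRun-class]) and `truth` (data.frame:
#'   `peptide`, `sequence`, `charge`, `precursorMz`, `window`, `apexCycle`,
#'   `apexRt`, `sigmaCycles`, `apexIntensity`, plus list-columns
#'   `fragmentMz` and `fragmentRel`). Fragments of one peptide share its
#'   Gaussian elution profile (same apex and width) scaled by their
#'   relative intensities.
#' @export
simulateRun <- function(sim = simConfig(), fasta = NULL) {
  stopifnot(inherits(sim, "SimConfig"))
  if (sim$nCycles < 20)
    stop("need at least as many cycles as the slider width")
  set.seed(sim$seed)
  nWin <- nrow(sim$windows)

  if (!is.null(fasta)) {
    entries <- digestFasta(fasta, charges = sim$charges,
                           variableMods = FALSE)
    ok <- vapply(seq_len(nrow(entries)), function(i) {
      mz <- entries$precursorMz[i]
      fr <- entries$fragMz[[i]]
      inWin <- any(mz > sim$windows$lower & mz < sim$windows$upper)
      inWin && sum(fr > sim$fragmentRange[1] &
                   fr < sim$fragmentRange[2]) >= sim$nFragments[1]
    }, logical(1))
    if (sum(!ok)) warning(sum(!ok), " digest entries outside the window ",
                          "scheme or with too few fragments skipped")
    pool <- entries[ok, , drop = FALSE]
    pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
    stopifnot(nrow(pool) >= sim$nPeptides)
    pick <- sort(sample.int(nrow(pool), sim$nPeptides))
    peps <- lapply(pick, function(i)
      list(sequence = pool$sequence[i], charge = pool$charge[i],
           mz = pool$precursorMz[i], fragMz = pool$fragMz[[i]]))
  } else {
    peps <- randomPeptides(sim)
    stopifnot(length(peps) == sim$nPeptides)
    for (i in seq_along(peps)) {
      aa <- strsplit(peps[[i]]$sequence, "")[[1]]
      fr <- fragmentIons(peps[[i]]$sequence,
                         residueMods = ifelse(aa == "C",
                                              .MOD_CARBAMIDOMETHYL, 0))
      peps[[i]]$fragMz <- fr$mz
    }
  }

  W <- 20L
  truthRows <- vector("list", length(peps))
  for (i in seq_along(peps)) {
    p <- peps[[i]]
    frInRange <- p$fragMz[p$fragMz > sim$fragmentRange[1] &
                          p$fragMz < sim$fragmentRange[2]]
    nf <- min(sample(sim$nFragments[1]:sim$nFragments[2], 1L),
              length(frInRange))
    fmz <- sort(sample(frInRange, nf))
    rel <- rlnorm(nf, 0, 0.5)
    rel <- pmax(rel / max(rel), 0.15)
    # apex anywhere a width-W slider can cover the peak core
    apex <- runif(1, W / 2, max(sim$nCycles - W / 2, W / 2))
    sig <- runif(1, sim$sigmaCycles[1], sim$sigmaCycles[2])
    snr <- runif(1, sim$snrRange[1], sim$snrRange[2])
    apexInt <- snr * exp(sim$noiseMeanlog)
    win <- which(p$mz > sim$windows$lower & p$mz < sim$windows$upper)[1]
    lam <- p$mz * p$charge / 1800
    iso <- dpois(0:2, lam) / dpois(0, lam)
    truthRows[[i]] <- list(peptide = i, sequence = p$sequence,
                           charge = p$charge, precursorMz = p$mz,
                           window = win, apexCycle = apex,
                           sigmaCycles = sig, apexIntensity = apexInt,
                           fragmentMz = fmz, fragmentRel = rel, iso = iso)
  }

  jitter <- function(n) if (sim$intensityCv > 0)
    rlnorm(n, 0, sim$intensityCv) else rep(1, n)
  gauss <- function(tr, c) tr$apexIntensity *
    exp(-(c - tr$apexCycle)^2 / (2 * tr$sigmaCycles^2))

  specs <- vector("list", sim$nCycles * (nWin + 1L))
  si <- 0L
  for (c in seq_len(sim$nCycles)) {
    rt0 <- (c - 1) * sim$cycleTime
    # MS1 scan: isotope envelopes of all peptides + background
    mz <- numeric(); int <- numeric()
    for (tr in truthRows) {
      h <- gauss(tr, c)
      if (h < 1 || abs(c - tr$apexCycle) > 3.5 * tr$sigmaCycles) next
      imz <- tr$precursorMz + (0:2) * .ISOTOPE_SPACING / tr$charge
      iint <- h * tr$iso * jitter(3)
      keep <- iint > 1
      mz <- c(mz, imz[keep]); int <- c(int, iint[keep])
    }
    nn <- rpois(1, sim$noiseMs1)
    if (nn > 0) {
      mz <- c(mz, runif(nn, min(sim$windows$lower) - 10,
                        max(sim$windows$upper) + 10))
      int <- c(int, rlnorm(nn, sim$noiseMeanlog, sim$noiseSdlog))
    }
    si <- si + 1L
    specs[[si]] <- DiaSpectrum(si, 1L, rt0, mz, int)
    # MS2 scans per window
    for (w in seq_len(nWin)) {
      mz <- numeric(); int <- numeric()
      for (tr in truthRows) {
        if (tr$window != w) next
        h <- gauss(tr, c)
        if (h < 1 || abs(c - tr$apexCycle) > 3.5 * tr$sigmaCycles) next
        fint <- h * tr$fragmentRel * jitter(length(tr$fragmentRel))
        keep <- fint > 1
        mz <- c(mz, tr$fragmentMz[keep]); int <- c(int, fint[keep])
      }
      nn <- rpois(1, sim$noiseMs2)
      if (nn > 0) {
        mz <- c(mz, runif(nn, sim$fragmentRange[1], sim$fragmentRange[2]))
        int <- c(int, rlnorm(nn, sim$noiseMeanlog, sim$noiseSdlog))
      }
      si <- si + 1L
      specs[[si]] <- DiaSpectrum(si, 2L,
                                 rt0 + w * sim$cycleTime / (nWin + 1),
                                 mz, int,
                                 windowLower = sim$windows$lower[w],
                                 windowUpper = sim$windows$upper[w])
    }
  }
  truth <- data.frame(
    peptide = vapply(truthRows, `[[`, numeric(1), "peptide"),
    sequence = vapply(truthRows, `[[`, character(1), "sequence"),
    charge = vapply(truthRows, `[[`, numeric(1), "charge"),
    precursorMz = vapply(truthRows, `[[`, numeric(1), "precursorMz"),
    window = vapply(truthRows, `[[`, numeric(1), "window"),
    apexCycle = vapply(truthRows, `[[`, numeric(1), "apexCycle"),
    apexRt = vapply(truthRows, function(t)
      (t$apexCycle - 1) * sim$cycleTime, numeric(1)),
    sigmaCycles = vapply(truthRows, `[[`, numeric(1), "sigmaCycles"),
    apexIntensity = vapply(truthRows, `[[`, numeric(1), "apexIntensity")
  )
  truth$fragmentMz <- lapply(truthRows, `[[`, "fragmentMz")
  truth$fragmentRel <- lapply(truthRows, `[[`, "fragmentRel")
  list(run = DiaRun(specs, windowScheme = sim$windows), truth = truth)
}

#' Ground-truth fragment XICs of a simulated run
#'
#' Extracts, for every truth peptide, the binned XICs of its fragments over
#' the width-20 slider centered on the peptide's apex cycle.
#'
#' @param run a [DiaRun-class] from [simulateRun()].
#' @param truth matching truth data.frame.
#' @param width slider width (default 20).
#' @param binsPerMz,maxMz binning grid.
#' @return list, one matrix (fragments x width) per peptide.
#' @export
truthFragmentXics <- function(run, truth, width = 20, binsPerMz = 30,
                              maxMz = 1200) {
  cyc <- dutyCycles(run)
  ncyc <- length(cyc$ms1)
  sp <- spectra(run)
  out <- vector("list", nrow(truth))
  for (w in sort(unique(truth$window))) {
    ms2M <- binSpectraMatrix(sp[cyc$ms2[[w]]], binsPerMz, maxMz)
    for (i in which(truth$window == w)) {
      s0 <- max(1L, min(round(truth$apexCycle[i]) - width %/% 2L,
                        ncyc - width + 1L))
      cols <- s0:(s0 + width - 1L)
      bins <- floor(truth$fragmentMz[[i]] * binsPerMz) + 1L
      out[[i]] <- as.matrix(ms2M[bins, cols, drop = FALSE])
    }
  }
  out
}

#' Sample labeled triplets from ground-truth fragment XICs
#'
#' Anchor and positive are two distinct fragment XICs of one peptide; the
#' negative is a fragment XIC of a different peptide.
#'
#' @param xicsByPeptide list of fragment-XIC matrices from
#'   [truthFragmentXics()] (needs >= 2 peptides with >= 2 fragments).
#' @param n number of triplets.
#' @param seed RNG seed.
#' @return list with matrices `anchor`, `positive`, `negative` (n x 20) and
#'   integer vectors `anchorPeptide`, `negativePeptide` for label audits.
#' @export
makeTriplets <- function(xicsByPeptide, n, seed = 1) {
  nf <- vapply(xicsByPeptide, nrow, integer(1))
  usable <- which(nf >= 2L)
  if (length(usable) < 2L)
    stop("need >= 2 peptides with >= 2 fragments to form triplets")
  set.seed(seed)
  W <- ncol(xicsByPeptide[[usable[1]]])
  A <- P <- N <- matrix(0, n, W)
  ap <- np <- integer(n)
  if (n == 0L)
    return(list(anchor = A, positive = P, negative = N,
                anchorPeptide = ap, negativePeptide = np))
  for (i in seq_len(n)) {
    pa <- sample(usable, 1L)
    fr <- sample.int(nf[pa], 2L)
    pn <- sample(setdiff(seq_along(xicsByPeptide), pa), 1L)
    A[i, ] <- xicsByPeptide[[pa]][fr[1], ]
    P[i, ] <- xicsByPeptide[[pa]][fr[2], ]
    N[i, ] <- xicsByPeptide[[pn]][sample.int(nrow(xicsByPeptide[[pn]]), 1L), ]
    ap[i] <- pa; np[i] <- pn
  }
  list(anchor = A, positive = P, negative = N,
       anchorPeptide = ap, negativePeptide = np)
}

#' Sample labeled 6x20 fragment-group matrices
#'
#' Positive groups (label 1) take 6 fragment XICs from one peptide;
#' negative groups (label 0) mix fragments from at least two peptides.
#'
#' @param xicsByPeptide list of fragment-XIC matrices.
#' @param n total group count (half positive, half negative).
#' @param seed RNG seed.
#' @return list with `groups` (array n x 6 x 20) and `labels` (0/1).
#' @export
makeGroupMatrices <- function(xicsByPeptide, n, seed = 1) {
  nf <- vapply(xicsByPeptide, nrow, integer(1))
  usable <- which(nf >= 6L)
  stopifnot(length(usable) >= 2L)
  set.seed(seed)
  groups <- array(0, c(n, 6L, 20L))
  labels <- integer(n)
  for (i in seq_len(n)) {
    if (i %% 2L == 1L) {
      p <- sample(usable, 1L)
      rows <- xicsByPeptide[[p]][sample.int(nf[p], 6L), , drop = FALSE]
      labels[i] <- 1L
    } else {
      ps <- sample(usable, 2L)
      take <- sample(1:5, 1L)
      r1 <- xicsByPeptide[[ps[1]]][sample.int(nf[ps[1]], take), ,
                                   drop = FALSE]
      r2 <- xicsByPeptide[[ps[2]]][sample.int(nf[ps[2]], 6L - take), ,
                                   drop = FALSE]
      rows <- rbind(r1, r2)
      labels[i] <- 0L
    }
    groups[i, , ] <- buildGroupMatrix(rows)
  }
  list(groups = groups, labels = labels)
}
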