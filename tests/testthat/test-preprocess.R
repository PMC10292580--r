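# Sliders, binning, MS1 peak finding, deisotoping, and fragment XIC filters.

test_that("slider counts follow the arithmetic for width/stride", {
  run25 <- tinyRun(nCycles = 25)
  sl <- makeSliders(run25)
  expect_equal(sum(vapply(sl, `[[`, numeric(1), "window") == 1), 6L)
  run20 <- tinyRun(nCycles = 20)
  expect_equal(length(makeSliders(run20)), 3L)  # exactly 1 per window
  # counting formula property across (nCycles, width, stride)
  for (nc in c(20, 23, 31)) for (w in c(5, 20)) for (st in c(1, 2, 3)) {
    run <- tinyRun(nCycles = nc)
    got <- length(makeSliders(run, width = w, stride = st)) / 3
    expect_equal(got, floor((nc - w) / st) + 1,
                 info = sprintf("nc=%d w=%d st=%d", nc, w, st))
  }
})

test_that("a slider's MS2 block comes from the same cycles as its MS1", {
  run <- tinyRun(nCycles = 25,
                 ms1Peaks = function(c) cbind(500, c),
                 ms2Peaks = function(c, w) cbind(300 + w, 1000 * w + c))
  sl <- makeSliders(run)[[4]]  # window 1, start 4
  expect_equal(sl$start, 4L)
  b1 <- floor(500 * 30) + 1
  expect_equal(as.numeric(sl$ms1Block[b1, ]), 4:23)
  b2 <- floor(301 * 30) + 1
  expect_equal(as.numeric(sl$ms2Block[b2, ]), 1000 + 4:23)
})

test_that("fewer cycles than the width warns and returns nothing", {
  run <- tinyRun(nCycles = 5)
  expect_warning(sl <- makeSliders(run, width = 20), "fewer than width")
  expect_length(sl, 0L)
})

test_that("binning accumulates on the truncated grid", {
  s <- DiaSpectrum(1, 1, 0, c(100.005, 100.015), c(10, 5))
  v <- binSpectrum(s)
  expect_length(v, 36000L)
  # floor(100.005*30) = floor(100.015*30) = 3000 (0-based)
  expect_equal(as.numeric(v[3001]), 15)
  expect_equal(sum(v), 15)
  empty <- DiaSpectrum(1, 1, 0, numeric(), numeric())
  expect_equal(sum(binSpectrum(empty)), 0)
  expect_error(binSpectrum(s, binsPerMz = 0), "positive")
  expect_error(binSpectrum(s, maxMz = -1), "positive")
})

test_that("binning conserves in-range intensity and drops the rest", {
  set.seed(9)
  mz <- sort(runif(200, 50, 1400))
  int <- rlnorm(200, 3, 1)
  s <- DiaSpectrum(1, 1, 0, mz, int)
  expect_warning(v <- binSpectrum(s), "dropped")
  expect_equal(sum(v), sum(int[mz < 1200]), tolerance = 1e-12)
})

test_that("MS1 peak finding matches a brute-force local-maximum scan", {
  # one strong Gaussian peak over a flat baseline of 1
  nb <- 2000
  prof <- rep(1, nb)
  apex <- 700
  prof[apex + (-3:3)] <- 1 + 100 * exp(-(-3:3)^2 / 2)
  block <- cbind(prof)  # single-scan block
  pk <- findMs1Peaks(block, snrMin = 4)
  expect_equal(pk, apex)
  # flat profile: nothing
  expect_length(findMs1Peaks(cbind(rep(1, nb)), snrMin = 4), 0L)
  # SNR 10 and SNR 2 peaks; threshold 4 keeps only the first
  prof <- rep(1, nb)
  prof[300] <- 10; prof[900] <- 2
  pk <- findMs1Peaks(cbind(prof), snrMin = 4)
  expect_equal(pk, 300)
  # brute-force oracle: every reported index is a strict-left local max
  # with apex/median-baseline >= threshold
  prof <- rep(0, nb)
  set.seed(4)
  prof[sample(nb, 80)] <- rlnorm(80, 2, 1)
  got <- findMs1Peaks(cbind(prof), snrMin = 3)
  oracle <- Filter(function(i) {
    if (i == 1 || i == nb) return(FALSE)
    if (!(prof[i] > prof[i - 1] && prof[i] >= prof[i + 1] &&
          prof[i] > 0)) return(FALSE)
    nbh <- setdiff(max(1, i - 15):min(nb, i + 15), (i - 1):(i + 1))
    base <- prof[nbh][prof[nbh] > 0 & prof[nbh] <= prof[i] / 2]
    if (!length(base)) return(TRUE)
    prof[i] / median(base) >= 3
  }, which(prof > 0))
  expect_equal(got, as.integer(oracle))
})

# build an MS1 block holding isotope envelopes with Gaussian elution
envelopeBlock <- function(envelopes, width = 20, nbins = 36000) {
  M <- matrix(0, nbins, width)
  for (e in envelopes) {
    prof <- e$apex * exp(-((1:width) - e$apexCycle)^2 / (2 * e$sigma^2))
    for (k in seq_along(e$ratios)) {
      mz <- e$mz + (k - 1) * 1.003355 / e$charge
      M[floor(mz * 30) + 1, ] <- M[floor(mz * 30) + 1, ] +
        prof * e$ratios[k]
    }
  }
  M
}

test_that("deisotoping recovers charge from a 2+ envelope", {
  M <- envelopeBlock(list(list(mz = 500.25, charge = 2,
                               ratios = c(1, 0.8, 0.3),
                               apex = 1000, apexCycle = 10, sigma = 3)))
  pk <- findMs1Peaks(M, snrMin = 3)
  prec <- deisotope(M, pk)
  expect_length(prec, 1L)
  expect_equal(prec[[1]]$charge, 2L)
  expect_equal(prec[[1]]$mz, 500.25, tolerance = 1 / 30)
  expect_equal(which.max(prec[[1]]$xic), 10L)
})

test_that("an isolated peak with no isotope partner is dropped", {
  M <- matrix(0, 36000, 20)
  M[floor(640.4 * 30) + 1, ] <- 50 * exp(-((1:20) - 10)^2 / 8)
  pk <- findMs1Peaks(M, snrMin = 3)
  expect_true(length(pk) >= 1)
  expect_length(deisotope(M, pk), 0L)
})

test_that("overlapping 1+ and 2+ envelopes resolve to two precursors", {
  M <- envelopeBlock(list(
    list(mz = 700.10, charge = 1, ratios = c(1, 0.7, 0.25),
         apex = 800, apexCycle = 8, sigma = 2.5),
    list(mz = 700.60, charge = 2, ratios = c(1, 0.8, 0.3),
         apex = 600, apexCycle = 13, sigma = 3)))
  pk <- findMs1Peaks(M, snrMin = 3)
  prec <- deisotope(M, pk)
  got <- vapply(prec, function(p) p$charge, integer(1))
  names(got) <- sprintf("%.2f", vapply(prec, function(p) p$mz, numeric(1)))
  expect_equal(sort(unique(got)), c(1L, 2L))
  expect_equal(unname(got[abs(as.numeric(names(got)) - 700.10) < 0.05]), 1L)
  expect_equal(unname(got[abs(as.numeric(names(got)) - 700.60) < 0.05]), 2L)
})

test_that("XIC extraction reads one bin across the block in RT order", {
  M <- matrix(0, 100, 20)
  M[7, ] <- 5
  expect_equal(extractXic(M, 7), rep(5, 20))
  expect_equal(extractXic(M, 8), rep(0, 20))
  expect_error(extractXic(M, 101), "out of range")
  prof <- 80 * exp(-((1:20) - 11)^2 / (2 * 2.5^2))
  M[33, ] <- prof
  expect_equal(extractXic(M, 33), prof)
})

test_that("fragment XIC filters apply both thresholds strictly", {
  mk <- function(xic) {
    M <- matrix(0, 50, 20)
    M[10, ] <- xic
    M
  }
  # exactly 5 nonzero points: rejected ("greater than 5" is strict)
  x5 <- c(rep(10, 4), 100, rep(0, 15))
  expect_length(filterFragmentXics(mk(x5)), 0L)
  # 8 nonzero, max 8, min nonzero 2 (ratio exactly 4): rejected
  x8 <- c(rep(2, 7), 8, rep(0, 12))
  expect_length(filterFragmentXics(mk(x8)), 0L)
  # 10 nonzero, max 100, min nonzero 1: kept
  xk <- c(rep(1, 9), 100, rep(0, 10))
  got <- filterFragmentXics(mk(xk))
  expect_length(got, 1L)
  expect_equal(got[[1]]$bin, 10L)
  expect_equal(got[[1]]$xic, xk)
})

test_that("every selected fragment re-passes both predicates post hoc", {
  set.seed(12)
  M <- matrix(rbinom(200 * 20, 1, 0.3) * rlnorm(200 * 20, 2, 1), 200, 20)
  got <- filterFragmentXics(M)
  expect_gt(length(got), 0L)
  for (f in got) {
    nz <- f$xic[f$xic > 0]
    expect_gt(length(nz), 5)
    expect_gt(max(nz) / min(nz), 4)
  }
  # and nothing passing was left out
  oracle <- sum(apply(M, 1, function(x) {
    nz <- x[x > 0]
    length(nz) > 5 && max(nz) / min(nz) > 4
  }))
  expect_equal(length(got), oracle)
})

test_that("deisotoping recovers >= 90% of injected precursors at SNR >= 10", {
  sim <- simConfig(nPeptides = 15, nCycles = 40, seed = 77)
  sr <- simulateRun(sim)
  sl <- makeSliders(sr$run)
  ws <- windowScheme(sr$run)
  found <- 0L
  for (i in seq_len(nrow(sr$truth))) {
    tr <- sr$truth[i, ]
    cand <- Filter(function(s) s$window == tr$window &&
                     abs(tr$apexCycle - (s$start + 9.5)) < 4, sl)
    hit <- FALSE
    for (s in cand) {
      br <- c(floor(ws$lower[tr$window] * 30) + 1,
              floor(ws$upper[tr$window] * 30) + 1)
      pk <- findMs1Peaks(s$ms1Block, snrMin = 3, binRange = br)
      prec <- deisotope(s$ms1Block, pk)
      pm <- vapply(prec, `[[`, numeric(1), "mz")
      pz <- vapply(prec, function(p) p$charge, integer(1))
      if (any(abs(pm - tr$precursorMz) <= 1 / 30 & pz == tr$charge)) {
        hit <- TRUE; break
      }
    }
    found <- found + hit
  }
  expect_gte(found / nrow(sr$truth), 0.9)
})
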