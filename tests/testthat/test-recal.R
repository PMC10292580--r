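# MS1 recalibration: calibrant selection, curve fitting, application.

test_that("calibrant selection filters and deduplicates", {
  g <- data.frame(peptide = c("A", "A", "B", "C"),
                  observedMz = c(500.1, 500.2, 600, 700),
                  theoreticalMz = c(500.11, 500.21, 600.01, 700.01),
                  hyperscore = c(3, 5, 4, 1))
  cal <- selectCalibrants(g, minHyperscore = 2)
  expect_equal(nrow(cal), 2L)                       # C below floor, A deduped
  expect_equal(cal$observedMz[cal$peptide == "A"], 500.2)  # best score kept
  # expect column takes precedence when present
  g$expect <- c(1e-4, 0.5, 1e-5, 1e-6)
  cal2 <- selectCalibrants(g, maxExpect = 0.001)
  expect_setequal(cal2$peptide, c("A", "B", "C"))
  expect_equal(cal2$observedMz[cal2$peptide == "A"], 500.1)
  # nothing passes -> empty set (skip path)
  expect_equal(nrow(selectCalibrants(g[g$hyperscore > 10, ])), 0L)
})

test_that("a perfect calibrant set fits the identity", {
  m <- seq(400, 1200, length.out = 20)
  cal <- fitCalibration(data.frame(observedMz = m, theoreticalMz = m),
                        model = "tof")
  co <- calCoefficients(cal)
  expect_equal(unname(co["A"]), 1, tolerance = 1e-10)
  expect_equal(unname(co["B"]), 0, tolerance = 1e-8)
  expect_equal(unname(co["C"]), 0, tolerance = 1e-7)
  expect_lt(cal@residualPpm, 1e-6)
})

test_that("three non-collinear calibrants interpolate exactly (tof)", {
  m <- c(400, 700, 1100)
  y <- c(400.01, 700.02, 1100.005)
  cal <- fitCalibration(data.frame(observedMz = m, theoreticalMz = y),
                        model = "tof")
  expect_equal(as.numeric(applyCalibration(cal, m)), y, tolerance = 1e-9)
  expect_lt(cal@residualPpm, 1e-6)
})

test_that("an injected multiplicative drift is recovered to 0.1 ppm", {
  set.seed(1)
  mTrue <- sort(runif(20, 400, 1200))
  mObs <- mTrue / 1.0001
  cal <- fitCalibration(data.frame(observedMz = mObs,
                                   theoreticalMz = mTrue), model = "tof")
  rec <- applyCalibration(cal, mObs)
  expect_true(all(abs((rec - mTrue) / mTrue) < 1e-7))
})

test_that("injected (A, B, C) coefficients are recovered to 1e-5 relative", {
  set.seed(2)
  mTrue <- sort(runif(20, 400, 1200))
  A <- 1.00004; B <- -0.003; C <- 0.4
  # observed masses drift such that the tof curve maps them back
  mObs <- vapply(mTrue, function(y)
    uniroot(function(m) A * m + B * sqrt(m) + C - y,
            c(y - 5, y + 5), tol = 1e-12)$root, numeric(1))
  cal <- fitCalibration(data.frame(observedMz = mObs,
                                   theoreticalMz = mTrue), model = "tof")
  co <- calCoefficients(cal)
  expect_equal(unname(co["A"]), A, tolerance = 1e-5)
  expect_equal(unname(co["B"]), B, tolerance = 1e-5 * abs(B) / abs(B))
  expect_equal(unname(co["C"]), C, tolerance = 1e-4)
  expect_true(all(abs((applyCalibration(cal, mObs) - mTrue) / mTrue)
                  < 1e-7))
})

test_that("the two-parameter orbitrap form fits in the sqrt basis", {
  mTrue <- sort(runif(15, 300, 1500))
  mObs <- (mTrue - 0.02 * sqrt(mTrue)) / 1.00005
  cal <- fitCalibration(data.frame(observedMz = mObs,
                                   theoreticalMz = mTrue),
                        model = "orbitrap")
  expect_equal(unname(calCoefficients(cal)["C"]), 0)
  expect_true(all(abs((applyCalibration(cal, mObs) - mTrue) / mTrue)
                  < 1e-6))
})

test_that("degenerate designs and direct evaluation behave as specified", {
  same <- data.frame(observedMz = rep(500, 5),
                     theoreticalMz = rep(500.01, 5))
  expect_error(fitCalibration(same, model = "tof"), "degenerate")
  idc <- identityCalibration()
  expect_equal(applyCalibration(idc, c(123.4, 999)), c(123.4, 999))
  manual <- new("MzCalibration", model = "tof",
                coefficients = c(A = 1.0001, B = 0, C = 0),
                residualPpm = 0, nCalibrants = 3L)
  expect_equal(applyCalibration(manual, 1000), 1000.1)
  expect_error(applyCalibration(idc, -5))
})

test_that("post-fit residual never exceeds pre-fit; correction monotone", {
  set.seed(3)
  for (i in 1:10) {
    mTrue <- sort(runif(15, 400, 1200))
    mObs <- mTrue * (1 + rnorm(1, 0, 2e-5)) + rnorm(15, 0, 0.002)
    cal <- fitCalibration(data.frame(observedMz = mObs,
                                     theoreticalMz = mTrue), model = "tof")
    pre <- sqrt(mean(((mObs - mTrue) / mTrue * 1e6)^2))
    expect_lte(cal@residualPpm, pre + 1e-9)
    # monotone over the instrument range for realistic drifts
    grid <- seq(100, 2000, by = 10)
    expect_true(all(diff(applyCalibration(cal, grid)) > 0))
  }
})
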