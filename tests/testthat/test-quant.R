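# Peak integration, calibration fitting/inversion, and detection limits.

test_that("integration recovers the closed-form Gaussian area", {
  t <- seq(13, 16, by = 0.005)
  ch <- chromatogram("x", t, dnorm(t, 14.4, 0.05) * 0.05 * sqrt(2 * pi))
  # unit-height Gaussian with sd 0.05: area = sigma * sqrt(2*pi)
  got <- integratePeak(ch, c(14.0, 14.8), "none")
  expect_equal(got$area, 0.05 * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(got$apex_rt, 14.4, tolerance = 0.006)
})

test_that("degenerate traces integrate to zero", {
  t <- seq(0, 2, by = 0.01)
  zero <- chromatogram("z", t, rep(0, length(t)))
  expect_equal(integratePeak(zero, c(0.5, 1.5), "none")$area, 0)
  # constant trace: the flanking-median baseline equals the signal
  const <- chromatogram("c", t, rep(7, length(t)))
  got <- integratePeak(const, c(0.5, 1.5), "flanking_median")
  expect_equal(got$area, 0)
  expect_identical(got$flag, "")
})

test_that("integration is additive over disjoint windows", {
  t <- seq(0, 4, by = 0.002)
  ch <- chromatogram("x", t, dnorm(t, 2, 0.3))
  whole <- integratePeak(ch, c(0.5, 3.5), "none")$area
  left <- integratePeak(ch, c(0.5, 2.0), "none")$area
  right <- integratePeak(ch, c(2.0, 3.5), "none")$area
  expect_equal(left + right, whole, tolerance = 1e-10)
})

test_that("integration rejects bad windows and clips negative areas", {
  t <- seq(0, 2, by = 0.01)
  ch <- chromatogram("x", t, rep(1, length(t)))
  expect_error(integratePeak(ch, c(1.5, 2.5), "none"), "outside")
  expect_error(integratePeak(ch, c(1.5, 0.5), "none"), "before")
  # a dip below the flanking baseline clips to zero with a flag
  dip <- chromatogram("d", t, c(rep(10, 80), rep(0, 41), rep(10, 80)))
  got <- integratePeak(dip, c(0.7, 1.3), "flanking_median")
  expect_equal(got$area, 0)
  expect_identical(got$flag, "negative_area_clipped")
})

test_that("exact data are fitted exactly, both model kinds", {
  lin <- fitCalibration(c(1, 2, 4, 8), 2 * c(1, 2, 4, 8) + 1, "linear")
  expect_equal(lin@coefficients[["slope"]], 2, tolerance = 1e-12)
  expect_equal(lin@coefficients[["intercept"]], 1, tolerance = 1e-12)
  expect_equal(lin@r2, 1)

  lg <- fitCalibration(c(0.1, 1, 10, 100), 3 * log(c(0.1, 1, 10, 100)) + 5,
                       "log")
  expect_equal(lg@coefficients[["a"]], 3, tolerance = 1e-12)
  expect_equal(lg@coefficients[["b"]], 5, tolerance = 1e-12)
  expect_equal(lg@r2, 1)

  expect_error(fitCalibration(c(1, 1, 2), c(1, 1, 2), "linear"), "distinct")
  expect_error(fitCalibration(c(0, 1, 2), c(1, 2, 3), "log"), "positive")
})

test_that("noisy calibration recovers the generating slope within 2%", {
  set.seed(21)
  conc <- c(0.5, 1, 2, 5, 10, 20)
  resp <- 1000 * conc + rnorm(6, 0, 0.01 * 1000 * 20)
  fit <- fitCalibration(conc, resp, "linear")
  expect_equal(fit@coefficients[["slope"]], 1000, tolerance = 0.02)
  expect_gt(fit@r2, 0.99)
})

test_that("inversion is the exact inverse on the calibrated range", {
  lin <- fitCalibration(c(1, 2, 4, 8), 2 * c(1, 2, 4, 8) + 1, "linear")
  expect_equal(as.numeric(invertCalibration(lin, 5)), 2, tolerance = 1e-12)
  lg <- fitCalibration(c(0.1, 1, 10), 3 * log(c(0.1, 1, 10)) + 5, "log")
  expect_equal(as.numeric(invertCalibration(lg, 5)), 1, tolerance = 1e-12)
  for (c0 in c(1.3, 2.7, 7.9)) {
    pred <- 2 * c0 + 1
    expect_equal(as.numeric(invertCalibration(lin, pred)), c0,
                 tolerance = 1e-12)
  }
  # responses outside the fitted range are flagged, not refused
  got <- invertCalibration(lin, 100)
  expect_true(attr(got, "extrapolated"))
  expect_false(attr(invertCalibration(lin, 5), "extrapolated"))

  flat <- new("CalibrationCurve", analyteId = "flat", modelKind = "linear",
              coefficients = c(slope = 0, intercept = 4), r2 = 0,
              concRange = c(1, 3), responseRange = c(4, 4),
              lod = NA_real_, loq = NA_real_)
  expect_error(invertCalibration(flat, 4), "slope")
})

test_that("pure noise cannot improve the goodness of fit", {
  set.seed(31)
  conc <- c(0.5, 1, 2, 5, 10, 20)
  clean <- 1000 * conc
  r2clean <- fitCalibration(conc, clean, "linear")@r2
  for (sd in c(100, 1000)) {
    noisy <- clean + rnorm(6, 0, sd)
    expect_lte(fitCalibration(conc, noisy, "linear")@r2, r2clean)
  }
})

test_that("LOD and LOQ follow the blank mean + 3/10 sd rule", {
  expect_equal(lodLoq(c(10, 10, 10)), c(lod = 10, loq = 10))
  # mean 10, sample sd 2
  blanks <- c(8, 10, 12)
  s <- sd(blanks)
  expect_equal(lodLoq(blanks), c(lod = 10 + 3 * s, loq = 10 + 10 * s))
  expect_error(lodLoq(5), "at least 2")
  set.seed(41)
  for (rep in 1:5) {
    b <- rnorm(4, 10, 3)
    ll <- lodLoq(b)
    expect_lte(ll[["lod"]], ll[["loq"]])
  }
})

test_that("quantified concentrations match generating truth on clean runs", {
  tl <- tinyTransitionList()
  model <- tinySignalModel()
  series <- simulateStandardSeries(model, tl,
    list(pep = c(0.5, 1, 2, 5, 10, 20),
         peg = c(0.005, 0.01, 0.05, 0.1, 0.5, 1)), nBlanks = 0L)
  points <- lapply(series$standards, function(s) {
    resp <- analyteResponses(s$run, tl, "none")
    cbind(resp, conc = s$concentrations[resp$analyte_id])
  })
  points <- do.call(rbind, points)
  curves <- list(
    pep = fitCalibration(points$conc[points$analyte_id == "pep"],
                         points$area[points$analyte_id == "pep"],
                         "linear", "pep"),
    peg = fitCalibration(points$conc[points$analyte_id == "peg"],
                         points$area[points$analyte_id == "peg"],
                         "log", "peg"))
  # quantify an independent run at an off-grid concentration
  run <- simulateRun(c(pep = 3.3, peg = 0.07), model, tl)
  q <- quantifyRun(run, tl, curves, "none")
  expect_equal(q$conc[q$analyte_id == "pep"], 3.3, tolerance = 5e-3)
  expect_equal(q$conc[q$analyte_id == "peg"], 0.07, tolerance = 5e-3)
})
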