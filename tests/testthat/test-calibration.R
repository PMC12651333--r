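test_that("calibration recovers exact polynomial ladders", {
  ## identity ladder
  lad <- buildLadder(c(10, 20, 40, 60, 80), c(10, 20, 40, 60, 80))
  g <- fitCalibration(lad)
  expect_equal(g@a0, 0, tolerance = 1e-9)
  expect_equal(g@a1, 1, tolerance = 1e-9)
  ## affine ladder R = 5 + 2 I
  I <- c(0.1, 0.2, 0.4, 0.6, 0.8)
  g2 <- fitCalibration(buildLadder(I, 5 + 2 * I))
  expect_equal(g2@a0, 5, tolerance = 1e-9)
  expect_equal(g2@a1, 2, tolerance = 1e-9)
  expect_lt(g2@residRMS, 1e-9)
  ## quadratic ladder R = I^2
  I3 <- c(1, 2, 3, 4, 5)
  g3 <- fitCalibration(buildLadder(I3, I3^2), degree = 2)
  expect_equal(g3@a0, 0, tolerance = 1e-6)
  expect_equal(g3@a1, 0, tolerance = 1e-6)
  expect_equal(g3@a2, 1, tolerance = 1e-6)
  expect_equal(evalCalibration(g3, 2.5), 6.25, tolerance = 1e-6)
})

test_that("inverted ladders are rejected as non-increasing", {
  I <- c(0.8, 0.6, 0.4, 0.2, 0.1)           # intensity decreasing in R
  expect_error(fitCalibration(buildLadder(I, c(10, 20, 40, 60, 80))),
               "not strictly increasing")
})

test_that("standardization maps through g and guards the control signal", {
  ident <- fitCalibration(buildLadder(c(10, 20, 40, 60, 80),
                                      c(10, 20, 40, 60, 80)))
  s <- standardize(ident, 0.4, 0.4)
  expect_equal(s$sTC, 1.0, tolerance = 1e-9)
  ## g(I) = 2 I
  I <- c(0.1, 0.2, 0.4, 0.6, 0.8)
  g2 <- fitCalibration(buildLadder(I, 2 * I))
  s2 <- standardize(g2, 0.3, 0.6)
  expect_equal(s2$sT, 0.6, tolerance = 1e-9)
  expect_equal(s2$sC, 1.2, tolerance = 1e-9)
  expect_equal(s2$sTC, 0.5, tolerance = 1e-9)
  ## control signal at or below zero is invalid
  gneg <- fitCalibration(buildLadder(I, -1 + 2 * I))
  expect_error(standardize(gneg, 0.3, 0.2), "control signal invalid")
})

test_that("concentration regression recovers an exact generating line", {
  sTC <- seq(0.05, 0.8, length.out = 8)
  conc <- 120 * sTC - 4
  sig <- lapply(seq_along(sTC), function(i)
    list(sT = sTC[i], sC = 1, sTC = sTC[i]))
  cm <- fitConcentrationModel(sig, conc)
  expect_equal(cm@alpha, 120, tolerance = 1e-6)
  expect_equal(cm@beta, -4, tolerance = 1e-6)
  ## two distinct concentrations: the line passes through the level means
  sig2 <- list(list(sT = 0.1, sC = 1, sTC = 0.1),
               list(sT = 0.1, sC = 1, sTC = 0.1),
               list(sT = 0.5, sC = 1, sTC = 0.5))
  cm2 <- fitConcentrationModel(sig2, c(10, 12, 60))
  expect_equal(cm2@alpha * 0.1 + cm2@beta, 11, tolerance = 1e-9)
  expect_equal(cm2@alpha * 0.5 + cm2@beta, 60, tolerance = 1e-9)
  ## degenerate predictor
  sig3 <- rep(list(list(sT = 0.2, sC = 1, sTC = 0.2)), 4)
  expect_error(fitConcentrationModel(sig3, c(10, 20, 30, 40)),
               "zero variance")
})

test_that("classification follows the 20/30 thresholds with closed middle", {
  expect_identical(classifyLevel(c(19.9, 20, 25, 30, 30.1, 45)),
                   c(1L, 2L, 2L, 2L, 3L, 3L))
  unit <- new("ConcentrationModel", mode = "ST_over_SC", alpha = 1, beta = 0,
              rangeLow = 5, rangeHigh = 100, residRMS = 0)
  mk <- function(v) list(sT = v, sC = 1, sTC = v)
  r <- estimateConcentration(unit, mk(19.9))
  expect_identical(r$level, 1L); expect_identical(r$label, "deficient")
  r <- estimateConcentration(unit, mk(25))
  expect_identical(r$level, 2L); expect_identical(r$label, "insufficient")
  r <- estimateConcentration(unit, mk(45))
  expect_identical(r$level, 3L); expect_identical(r$label, "sufficient")
})

test_that("out-of-range estimates are censored, not clamped", {
  unit <- new("ConcentrationModel", mode = "ST_over_SC", alpha = 1, beta = 0,
              rangeLow = 5, rangeHigh = 100, residRMS = 0)
  mk <- function(v) list(sT = v, sC = 1, sTC = v)
  lo <- estimateConcentration(unit, mk(2))
  expect_identical(lo$censored, "<5")
  expect_identical(lo$level, 1L)
  expect_true(is.na(lo$concentration))
  expect_equal(lo$raw, 2)
  hi <- estimateConcentration(unit, mk(130))
  expect_identical(hi$censored, ">100")
  expect_identical(hi$level, 3L)
})

test_that("a synthetic reference panel calibrates to within 10% at 20-100", {
  cfg <- fittedConfig()
  for (cc in c(20, 40, 60, 100)) {
    raws <- vapply(1:3, function(i) {
      s <- renderStrip(fixLayout(), cc, device = referenceDevice(),
                       seed = 7000 + 10 * cc + i)
      analyzeImage(s$image, cfg, detect = FALSE)$result$raw
    }, numeric(1))
    expect_lt(abs(mean(raws) - cc) / cc, 0.10)
  }
})

test_that("model JSON serialization round-trips with version tags", {
  path <- withr::local_tempfile(fileext = ".json")
  cm <- fittedModel()
  writeModelJSON(cm, path, modelVersion = "m-9", calibrationVersion = "c-3")
  back <- readModelJSON(path)
  expect_s4_class(back, "ConcentrationModel")
  expect_equal(back@alpha, cm@alpha)
  expect_equal(back@beta, cm@beta)
  expect_identical(attr(back, "modelVersion"), "m-9")
  expect_identical(attr(back, "calibrationVersion"), "c-3")
})
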