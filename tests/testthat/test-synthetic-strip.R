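test_that("dose-response is a saturating curve with the stated anchors", {
  dr <- DoseResponse(dMax = 1, kHalf = 50, floor = 0)
  expect_equal(doseResponseDensity(0, dr), 0)
  expect_equal(doseResponseDensity(50, dr), 0.5)       # half-saturation
  expect_lt(abs(doseResponseDensity(1e9, dr) - 1), 1e-6)  # saturation limit
  dr2 <- DoseResponse()
  expect_equal(doseResponseDensity(0, dr2), dr2@floor)
  conc <- seq(5, 100, length.out = 20)
  expect_true(all(diff(doseResponseDensity(conc, dr2)) > 0))
  expect_error(doseResponseDensity(-1, dr2), "non-negative")
})

test_that("zero-analyte test line is indistinguishable from substrate", {
  s <- renderStrip(fixLayout(), conc = 0, dr = DoseResponse(floor = 0),
                   device = identityDevice())
  w <- lineWindows(fixLayout())["T", ]
  twin <- pixels(s$image)[, w$lo:w$hi, ]
  bg <- pixels(s$image)[, (w$hi + 30):(w$hi + 50), ]
  expect_lt(max(abs(twin - mean(bg))), 1e-6)
})

test_that("test-line darkening is monotone in concentration", {
  w <- lineWindows(fixLayout())["T", ]
  g5 <- pixels(renderStrip(fixLayout(), 5, device = identityDevice())$image)[, w$lo:w$hi, 2]
  g100 <- pixels(renderStrip(fixLayout(), 100, device = identityDevice())$image)[, w$lo:w$hi, 2]
  expect_lt(mean(g100), mean(g5))
})

test_that("reference-line densities do not depend on concentration", {
  t1 <- renderStrip(fixLayout(), 5, device = identityDevice())$truth
  t2 <- renderStrip(fixLayout(), 95, device = identityDevice())$truth
  refs <- paste0("ref", 1:5)
  expect_identical(t1$lineDensities[refs], t2$lineDensities[refs])
  expect_true(all(diff(t1$lineDensities[refs]) > 0))
})

test_that("rendering is a pure function of inputs and seed", {
  dev <- referenceDevice()
  a <- renderStrip(fixLayout(), 42, device = dev, seed = 5)
  b <- renderStrip(fixLayout(), 42, device = dev, seed = 5)
  expect_identical(pixels(a$image), pixels(b$image))
  c <- renderStrip(fixLayout(), 42, device = dev, seed = 6)
  expect_false(identical(pixels(a$image), pixels(c$image)))
})

test_that("degenerate poses are rejected", {
  bad <- matrix(c(10, 10, 10, 200, 10, 390, 10, 580), 4, 2, byrow = TRUE)
  expect_error(renderStrip(fixLayout(), 10, device = identityDevice(),
                           pose = bad), "convex|degenerate")
})

test_that("paired captures share the strip and differ only as devices do", {
  ## identity devices, no noise: captures are pixel-identical
  p <- makePairedCaptures(fixLayout(), 30, deviceA = identityDevice(),
                          deviceB = identityDevice(), seed = 1)
  expect_identical(pixels(p$imageA), pixels(p$imageB))
  ## same noisy device: difference comes from independent noise only
  dev <- referenceDevice()
  p2 <- makePairedCaptures(fixLayout(), 30, deviceA = dev, deviceB = dev,
                           seed = 2)
  d <- pixels(p2$imageA) - pixels(p2$imageB)
  expect_false(all(d == 0))
  expect_lt(sd(d), 3 * dev@noiseSd)
  ## white-balance tint shows up as per-channel factors in the neutral zone
  tint <- DeviceModel(wbGains = c(1.2, 1, 0.9), gamma = "none", noiseSd = 0)
  p3 <- makePairedCaptures(fixLayout(), 30, deviceA = identityDevice(),
                           deviceB = tint, seed = 3)
  nz <- fixLayout()@neutralZone
  nzpix <- function(img) LFAreader:::neutralZonePixels(pixels(img), nz)
  ratio <- colMeans(nzpix(p3$imageA)) / colMeans(nzpix(p3$imageB))
  expect_equal(unname(ratio), c(1.2, 1, 0.9), tolerance = 1e-6)
})

test_that("validation panels honour the requested design and are reproducible", {
  lv <- data.frame(conc = c(0, 5), n = 20)
  p <- generateValidationPanel(lv, layout = fixLayout(),
                               device = referenceDevice(), seed = 4)
  expect_length(p, 40)
  concs <- vapply(p, function(e) e$truth$concentration, numeric(1))
  expect_equal(sum(concs == 0), 20)
  man <- attr(p, "manifest")
  expect_equal(nrow(man), 40)
  expect_equal(man$concentration_ng_ml, concs)
  p2 <- generateValidationPanel(lv, layout = fixLayout(),
                                device = referenceDevice(), seed = 4)
  expect_identical(lapply(p, function(e) pixels(e$image)),
                   lapply(p2, function(e) pixels(e$image)))
})

test_that("panels written to disk carry PNGs, truth sidecars and a manifest", {
  dir <- withr::local_tempdir()
  lv <- data.frame(conc = c(10, 50), n = 2)
  generateValidationPanel(lv, layout = fixLayout(),
                          device = referenceDevice(), seed = 9, dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(file.path(dir, man$path))))
  truths <- file.path(dir, sub("\\.png$", ".truth.json", man$path))
  expect_true(all(file.exists(truths)))
  tr <- jsonlite::read_json(truths[1], simplifyVector = TRUE)
  expect_equal(tr$concentration, man$concentration_ng_ml[1])
  ## a written image reads back to within 8-bit quantization
  img <- readStripImage(file.path(dir, man$path[1]))
  expect_s4_class(img, "StripImage")
})
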