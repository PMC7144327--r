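cfgLoc <- simulationConfig(seed = 7, fov_px = 64)
calLoc <- theoreticalCalibration(cfgLoc, "GLT1")

oneLocTable <- function(x, y, z, photons = 1000, frame = 0L) {
  localizationTable(data.frame(
    channel = "GLT1", frame = frame, x_nm = x, y_nm = y, z_nm = z,
    photons = photons, bg = 5, sigma_xy_nm = 10, sigma_z_nm = 25),
    list(channels = "GLT1"))
}

test_that("the Abbe limit is computed and bounded as expected", {
  expect_equal(diffractionLimit(500, 1.25), 200)
  expect_equal(diffractionLimit(600, 1.2), 250)
  nas <- seq(0.5, 1.5, 0.1)
  expect_true(all(diff(diffractionLimit(600, nas)) < 0))
  expect_error(diffractionLimit(-1, 1.2), "positive")
  expect_error(diffractionLimit(500, 0), "positive")
})

test_that("blank frames produce no candidates", {
  blank <- new("FrameStack", planeA = array(5, c(32, 32, 2)),
               planeB = array(5, c(32, 32, 2)), pixel_size_nm = 100,
               channel = "GLT1", z_planes_nm = numeric(0), meta = list())
  cands <- detectSpots(blank, 10)
  expect_true(all(vapply(cands, nrow, integer(1)) == 0L))
})

test_that("rendered spots are detected at their true pixels", {
  tb <- oneLocTable(2000.5, 3000.5, 0)
  fs <- renderFrames(tb, calLoc, cfgLoc, shot_noise = FALSE)
  cc <- detectSpots(fs, 10)[[1]]
  expect_equal(nrow(cc), 1L)
  expect_lt(abs(cc$col - 20.5), 1.1)
  expect_lt(abs(cc$row - 30.5), 1.1)
  # two spots 20 pixels apart give two candidates
  tb2 <- localizationTable(data.frame(
    channel = "GLT1", frame = 0L, x_nm = c(2000, 4000), y_nm = 3000,
    z_nm = 0, photons = 1000, bg = 5, sigma_xy_nm = 10, sigma_z_nm = 25),
    list(channels = "GLT1"))
  fs2 <- renderFrames(tb2, calLoc, cfgLoc, shot_noise = FALSE)
  expect_equal(nrow(detectSpots(fs2, 10)[[1]]), 2L)
})

test_that("a noiseless spot is fitted to sub-centipixel accuracy", {
  tb <- oneLocTable(2030, 1170, 0)  # pixel (20.3, 11.7)
  fs <- renderFrames(tb, calLoc, cfgLoc, shot_noise = FALSE)
  cc <- detectSpots(fs, 10)[[1]]
  ft <- fitSpot(fs, 1, c(cc$row[1], cc$col[1]))
  expect_true(ft$converged)
  expect_lt(abs(ft$A$x_px - 20.3), 0.02)
  expect_lt(abs(ft$A$y_px - 11.7), 0.02)
  # photon conservation: amplitude x 2 pi sigma^2 vs window sum - background
  win <- fs@planeA[(cc$row[1] - 5):(cc$row[1] + 5),
                   (cc$col[1] - 5):(cc$col[1] + 5), 1]
  expect_lt(abs(ft$A$photons - (sum(win) - 121 * ft$A$bg)) /
              ft$A$photons, 0.05)
})

test_that("a flat window does not report convergence", {
  flat <- new("FrameStack", planeA = array(7, c(32, 32, 1)),
              planeB = array(7, c(32, 32, 1)), pixel_size_nm = 100,
              channel = "GLT1", z_planes_nm = numeric(0), meta = list())
  ft <- fitSpot(flat, 1, c(16, 16))
  expect_false(ft$converged)
  # a window clipped at the border is not converged either
  tb <- oneLocTable(2000, 3000, 0)
  fs <- renderFrames(tb, calLoc, cfgLoc, shot_noise = FALSE)
  expect_false(fitSpot(fs, 1, c(2, 2))$converged)
})

test_that("fitted centre scatter follows the photon-scaling law", {
  cfgDim <- simulationConfig(seed = 7, fov_px = 64, bg_photons = 0.5)
  errs <- vapply(1:30, function(s) {
    set.seed(s)
    tb <- localizationTable(data.frame(
      channel = "GLT1", frame = 0L, x_nm = 2000.3, y_nm = 3000.1,
      z_nm = 0, photons = 500, bg = 0.5, sigma_xy_nm = 10,
      sigma_z_nm = 25), list(channels = "GLT1"))
    fs <- renderFrames(tb, calLoc, cfgDim, shot_noise = TRUE)
    loc <- suppressMessages(localizeStack(fs, calLoc, 3))
    if (nLocs(loc) != 1L) return(NA_real_)
    locData(loc)$x_nm - 2000.3
  }, numeric(1))
  rmse <- sqrt(mean(errs^2, na.rm = TRUE))
  # ~ sigma_PSF / sqrt(N) with the PSF width at focus and N = 500
  pred <- 150 * sqrt(1 + (250 / 500)^2) / sqrt(500)
  expect_lt(rmse, 2 * pred)
  expect_gt(rmse, pred / 2)
})

test_that("bead-stack calibration recovers the generative width model", {
  bs <- makeBeadStack(cfgLoc, n_beads = 2, shot_noise = FALSE)
  cal <- calibratePsf(bs$GLT1, threshold_photons = 5)
  relA <- abs(cal@widthA_nm - calLoc@widthA_nm) / calLoc@widthA_nm
  relB <- abs(cal@widthB_nm - calLoc@widthB_nm) / calLoc@widthB_nm
  expect_lt(max(relA), 0.05)
  expect_lt(max(relB), 0.05)
  expect_equal(length(cal@z_nm), 50L)
  # working range of at least 1 um
  expect_gte(diff(cal@valid_range_nm), 1000)
  # symmetric width model: equal widths at focus
  sp <- stats::splinefun(cal@z_nm, log(cal@widthA_nm / cal@widthB_nm))
  z0 <- stats::uniroot(sp, c(-500, 500))$root
  expect_lt(abs(z0), 25)
})

test_that("bead stacks have fifty planes and shared true positions", {
  bs <- makeBeadStack(cfgLoc, n_beads = 2, shot_noise = FALSE)
  for (ch in names(bs)) {
    expect_equal(dim(bs[[ch]]@planeA)[3], 50L)
    expect_equal(bs[[ch]]@meta$bead_positions_nm,
                 bs[[1]]@meta$bead_positions_nm)
  }
})

test_that("width-ratio inversion is exact on the calibration samples", {
  keep <- calLoc@z_nm >= calLoc@valid_range_nm[1] &
          calLoc@z_nm <= calLoc@valid_range_nm[2]
  lr <- log(calLoc@widthA_nm[keep] / calLoc@widthB_nm[keep])
  expect_equal(zFromLogRatio(calLoc, lr), calLoc@z_nm[keep],
               tolerance = 1e-6)
})

test_that("an empty stack localises to an empty table", {
  blank <- new("FrameStack", planeA = array(5, c(32, 32, 1)),
               planeB = array(5, c(32, 32, 1)), pixel_size_nm = 100,
               channel = "GLT1", z_planes_nm = numeric(0), meta = list())
  expect_equal(nLocs(localizeStack(blank, calLoc, 10)), 0L)
})

test_that("a noiseless emitter at z = +300 nm is recovered within 50 nm", {
  tb <- oneLocTable(3200, 3200, 300)
  fs <- renderFrames(tb, calLoc, cfgLoc, shot_noise = FALSE)
  loc <- suppressMessages(localizeStack(fs, calLoc, 8))
  expect_equal(nLocs(loc), 1L)
  expect_lt(abs(locData(loc)$z_nm - 300), 50)
})

test_that("out-of-range localisations are skipped with a logged count", {
  tb <- oneLocTable(c(2000, 3000), 3000, c(0, 4000), frame = 0:1)
  expect_message(fs <- renderFrames(tb, calLoc, cfgLoc, shot_noise = FALSE),
                 "skipped")
  expect_equal(fs@meta$skipped, 1L)
})
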