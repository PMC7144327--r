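# Biplane PSF width model and frame rendering.

# Defocus width model: w(z) = w0 * sqrt(1 + ((z - zf)/zr)^2).
psfWidth <- function(z, w0, zr, zf = 0) w0 * sqrt(1 + ((z - zf) / zr)^2)

# Maximal strictly monotone (increasing) run of the log width ratio that
# contains z = 0; returns c(lo, hi) in nm.
monotoneRange <- function(z, logratio) {
  up <- diff(logratio) > 0
  i0 <- which.min(abs(z))
  lo <- i0; hi <- i0
  while (lo > 1L && up[lo - 1L]) lo <- lo - 1L
  while (hi < length(z) && up[hi]) hi <- hi + 1L
  c(z[lo], z[hi])
}

#' Analytic biplane PSF calibration of the simulated microscope
#'
#' Builds the [PSFCalibration-class] directly from the generative defocus
#' model (in-focus width `psf_w0_nm`, axial parameter `psf_zr_nm`, detection
#' planes `biplane_offset_nm` apart, straddling z = 0), sampled on the
#' standard bead-stack grid of fifty 100 nm steps. Used to render frames
#' and as the noiseless reference for calibration recovery.
#'
#' @param cfg a [SimulationConfig-class]
#' @param channel channel label
#' @return a [PSFCalibration-class]
#' @export
theoreticalCalibration <- function(cfg, channel = "GLT1") {
  z <- ((0:49) - 24.5) * 100
  wA <- psfWidth(z, cfg@psf_w0_nm, cfg@psf_zr_nm, -cfg@biplane_offset_nm / 2)
  wB <- psfWidth(z, cfg@psf_w0_nm, cfg@psf_zr_nm, +cfg@biplane_offset_nm / 2)
  new("PSFCalibration", channel = channel, z_nm = z, widthA_nm = wA,
      widthB_nm = wB, valid_range_nm = monotoneRange(z, log(wA / wB)))
}

# Interpolated plane widths (nm) at axial positions z.
calWidths <- function(cal, z) {
  list(A = stats::splinefun(cal@z_nm, cal@widthA_nm, method = "natural")(z),
       B = stats::splinefun(cal@z_nm, cal@widthB_nm, method = "natural")(z))
}

# Add one integrated-Gaussian splat to a frame matrix (photon units).
# x/y in pixel units, width in pixels, mass = total photons.
addSplat <- function(M, x, y, width, mass) {
  ny <- nrow(M); nx <- ncol(M)
  r <- max(1L, ceiling(4 * width))
  cols <- max(1L, floor(x - r)):min(nx, ceiling(x + r))
  rows <- max(1L, floor(y - r)):min(ny, ceiling(y + r))
  if (!length(cols) || !length(rows) || x < -r || y < -r ||
      x > nx + r || y > ny + r) return(M)
  fx <- stats::pnorm(cols, x, width) - stats::pnorm(cols - 1, x, width)
  fy <- stats::pnorm(rows, y, width) - stats::pnorm(rows - 1, y, width)
  M[rows, cols] <- M[rows, cols] + mass * (fy %o% fx)
  M
}

#' Render localisations into simulated biplane camera frames
#'
#' Each localisation is splatted into its frame as an integrated 2D
#' Gaussian in both detection planes, with plane widths taken from the
#' calibration at the localisation's z and the photon count split equally
#' between the planes, plus constant background and (optionally) Poisson
#' shot noise. Localisations with z outside the calibration's sampled range
#' are skipped; the skipped count is reported in `meta$skipped` and via a
#' message.
#'
#' @param table a [LocalizationTable-class] (single channel)
#' @param cal a [PSFCalibration-class] covering the table's z range
#' @param cfg a [SimulationConfig-class] (pixel size, frame geometry,
#'   background)
#' @param shot_noise add Poisson shot noise (default TRUE)
#' @return a [FrameStack-class]
#' @export
renderFrames <- function(table, cal, cfg, shot_noise = TRUE) {
  d <- table@data
  px <- cfg@pixel_size_nm
  n_px <- cfg@fov_px
  n_frames <- if (nrow(d)) max(d$frame) + 1L else 1L
  A <- array(0, c(n_px, n_px, n_frames))
  B <- array(0, c(n_px, n_px, n_frames))
  zlim <- range(cal@z_nm)
  skip <- d$z_nm < zlim[1] | d$z_nm > zlim[2]
  if (any(skip))
    message(sum(skip), " localisation(s) outside calibration z range skipped")
  dd <- d[!skip, , drop = FALSE]
  if (nrow(dd)) {
    w <- calWidths(cal, dd$z_nm)
    for (k in seq_len(nrow(dd))) {
      f <- dd$frame[k] + 1L
      x <- dd$x_nm[k] / px; y <- dd$y_nm[k] / px
      A[, , f] <- addSplat(A[, , f], x, y, w$A[k] / px, dd$photons[k] / 2)
      B[, , f] <- addSplat(B[, , f], x, y, w$B[k] / px, dd$photons[k] / 2)
    }
  }
  A <- A + cfg@bg_photons
  B <- B + cfg@bg_photons
  if (shot_noise) {
    A[] <- stats::rpois(length(A), A)
    B[] <- stats::rpois(length(B), B)
  }
  new("FrameStack", planeA = A, planeB = B, pixel_size_nm = px,
      channel = if (nrow(d)) d$channel[1] else "unknown",
      z_planes_nm = numeric(0),
      meta = list(skipped = sum(skip)))
}

#' Simulate a multi-colour fiducial bead z stack
#'
#' Fifty axial planes at 100 nm steps; every bead is visible in every
#' channel at identical true positions before chromatic offsets. One
#' [FrameStack-class] per channel (frames = planes, stage z recorded in
#' `z_planes_nm`); bead widths follow the generative defocus model, so the
#' stack supports both PSF calibration and channel registration.
#'
#' @param cfg a [SimulationConfig-class]
#' @param n_beads number of beads (>= 1)
#' @param photons photons per bead per plane
#' @param shot_noise add Poisson shot noise (default TRUE)
#' @return named list of [FrameStack-class], one per channel;
#'   `meta$bead_positions_nm` holds the shared true positions
#' @export
makeBeadStack <- function(cfg, n_beads = 3, photons = 5000,
                          shot_noise = TRUE) {
  stopifnot(n_beads >= 1)
  withSeed(deriveSeed(cfg@seed, 4), {
    px <- cfg@pixel_size_nm
    # calibration stacks use the full camera chip: wide defocused bead
    # images need 41-px fit windows that must not clip or overlap
    n_px <- max(cfg@fov_px, 128)
    margin <- 22 * px
    min_sep <- 30 * px
    pos <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(pos) < n_beads) {
      tries <- tries + 1L
      if (tries > 1000L * n_beads)
        stop("field too small to place ", n_beads, " separated beads")
      cand <- c(stats::runif(1, margin, n_px * px - margin),
                stats::runif(1, margin, n_px * px - margin), 0)
      if (nrow(pos) == 0L ||
          min((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2) >= min_sep^2)
        pos <- rbind(pos, cand)
    }
    z <- ((0:49) - 24.5) * 100
    out <- list()
    for (ch in cfg@channels@names) {
      off <- cfg@chromatic_offset_nm[ch, ]
      A <- array(0, c(n_px, n_px, length(z)))
      B <- array(0, c(n_px, n_px, length(z)))
      for (f in seq_along(z)) {
        zap <- z[f] + off[3]  # apparent axial position in this channel
        wA <- psfWidth(zap, cfg@psf_w0_nm, cfg@psf_zr_nm,
                       -cfg@biplane_offset_nm / 2) / px
        wB <- psfWidth(zap, cfg@psf_w0_nm, cfg@psf_zr_nm,
                       +cfg@biplane_offset_nm / 2) / px
        for (b in seq_len(n_beads)) {
          x <- (pos[b, 1] + off[1]) / px
          y <- (pos[b, 2] + off[2]) / px
          A[, , f] <- addSplat(A[, , f], x, y, wA, photons / 2)
          B[, , f] <- addSplat(B[, , f], x, y, wB, photons / 2)
        }
      }
      A <- A + cfg@bg_photons
      B <- B + cfg@bg_photons
      if (shot_noise) {
        A[] <- stats::rpois(length(A), A)
        B[] <- stats::rpois(length(B), B)
      }
      out[[ch]] <- new("FrameStack", planeA = A, planeB = B,
                       pixel_size_nm = px, channel = ch, z_planes_nm = z,
                       meta = list(bead_positions_nm = pos))
    }
    out
  })
}

#' Write a frame stack to multi-page TIFF files
#'
#' One 32-bit float TIFF per detection plane.
#'
#' @param stack a [FrameStack-class]
#' @param prefix output path prefix; `<prefix>_planeA.tif` and
#'   `<prefix>_planeB.tif` are written
#' @return invisibly, the two paths
#' @export
writeFrameStack <- function(stack, prefix) {
  pA <- paste0(prefix, "_planeA.tif")
  pB <- paste0(prefix, "_planeB.tif")
  toList <- function(arr) lapply(seq_len(dim(arr)[3]), function(f)
    arr[, , f] / max(arr[, , f], 1))
  tiff::writeTIFF(toList(stack@planeA), pA, bits.per.sample = 32L)
  tiff::writeTIFF(toList(stack@planeB), pB, bits.per.sample = 32L)
  invisible(c(pA, pB))
}
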