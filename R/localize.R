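#' Abbe diffraction limit
#'
#' `d = 0.5 * lambda / NA` — the smallest resolvable distance of a
#' conventional optical microscope.
#'
#' @param wavelength_nm wavelength in nm (> 0)
#' @param na numerical aperture (> 0)
#' @return diffraction-limited distance in nm
#' @examples
#' diffractionLimit(500, 1.25)  # 200 nm
#' @export
diffractionLimit <- function(wavelength_nm, na) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  if (any(na <= 0)) stop("numerical aperture must be positive")
  0.5 * wavelength_nm / na
}

# Gaussian smoothing of a matrix (separable, zero-padded).
smoothFrame <- function(M, sigma = 1) {
  k <- stats::dnorm(-3:3, 0, sigma)
  k <- k / sum(k)
  shift <- function(A, di, dj) {
    out <- matrix(0, nrow(A), ncol(A))
    ri <- seq_len(nrow(A)); rj <- seq_len(ncol(A))
    si <- ri - di; sj <- rj - dj
    ok_i <- si >= 1 & si <= nrow(A); ok_j <- sj >= 1 & sj <= ncol(A)
    out[ri[ok_i], rj[ok_j]] <- A[si[ok_i], sj[ok_j]]
    out
  }
  R <- matrix(0, nrow(M), ncol(M))
  for (d in -3:3) R <- R + k[d + 4] * shift(M, d, 0)
  C <- matrix(0, nrow(M), ncol(M))
  for (d in -3:3) C <- C + k[d + 4] * shift(R, 0, d)
  C
}

#' Detect candidate spots in a frame stack
#'
#' Local maxima of a Gaussian-smoothed sum of the two detection planes,
#' above the frame background (median) plus `threshold_photons` (photons
#' per pixel on the smoothed frame). Maxima closer than 5 pixels are
#' suppressed, the brighter one winning (ties to the lower (row, col)
#' index).
#'
#' @param stack a [FrameStack-class]
#' @param threshold_photons detection threshold above background
#' @return list (one entry per frame) of data.frames with `row`, `col`
#'   (pixel indices) and `value` (smoothed peak height)
#' @export
detectSpots <- function(stack, threshold_photons = 10) {
  nf <- dim(stack@planeA)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    S <- smoothFrame(stack@planeA[, , f] + stack@planeB[, , f])
    bg <- stats::median(S)
    ny <- nrow(S); nx <- ncol(S)
    inner_i <- 2:(ny - 1); inner_j <- 2:(nx - 1)
    C <- S[inner_i, inner_j]
    ismax <- C > bg + threshold_photons
    # strict against later neighbours, >= against earlier: plateau ties go
    # to the lowest (row, col)
    for (d in list(c(-1, -1), c(0, -1), c(1, -1), c(-1, 0))) {
      ismax <- ismax & C >= S[inner_i + d[1], inner_j + d[2]]
    }
    for (d in list(c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
      ismax <- ismax & C > S[inner_i + d[1], inner_j + d[2]]
    }
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      out[[f]] <- data.frame(row = integer(0), col = integer(0),
                             value = numeric(0))
      next
    }
    cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                       value = C[idx])
    cand <- cand[order(-cand$value, cand$row, cand$col), , drop = FALSE]
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!any(keep)) { keep[k] <- TRUE; next }
      dk <- sqrt((cand$row[keep] - cand$row[k])^2 +
                 (cand$col[keep] - cand$col[k])^2)
      if (all(dk >= 5)) keep[k] <- TRUE
    }
    out[[f]] <- cand[keep, , drop = FALSE]
    rownames(out[[f]]) <- NULL
  }
  out
}

# Least-squares isotropic-Gaussian fit on one window.
# Returns list(amp, x_px, y_px, sigma_px, bg, photons, rss, converged).
fitWindow <- function(W, r0, c0, max_sigma = 6) {
  ny <- nrow(W)
  if (diff(range(W)) == 0)
    return(list(amp = NA_real_, x_px = NA_real_, y_px = NA_real_,
                sigma_px = NA_real_, bg = NA_real_, photons = NA_real_,
                rss = NA_real_, converged = FALSE))
  xs <- (seq_len(ncol(W)) - 0.5) + (c0 - (ncol(W) + 1) / 2)
  ys <- (seq_len(ny) - 0.5) + (r0 - (ny + 1) / 2)
  b0 <- min(W); a0 <- max(W) - b0
  Wb <- pmax(W - b0, 0)
  tot <- sum(Wb)
  x0 <- sum(Wb %*% xs) / tot
  y0 <- sum(t(Wb) %*% ys) / tot
  vx <- sum(Wb %*% (xs - x0)^2) / tot
  vy <- sum(t(Wb) %*% (ys - y0)^2) / tot
  s0 <- min(max(sqrt((vx + vy) / 2), 0.8), max_sigma - 0.2)
  model <- function(p) {
    ex <- exp(-(xs - p[2])^2 / (2 * p[4]^2))
    ey <- exp(-(ys - p[3])^2 / (2 * p[4]^2))
    p[1] * (ey %o% ex) + p[5]
  }
  obj <- function(p) sum((model(p) - W)^2)
  # analytic gradient of the squared-error objective
  grad <- function(p) {
    dx <- xs - p[2]; dy <- ys - p[3]; s2 <- p[4]^2
    ex <- exp(-dx^2 / (2 * s2)); ey <- exp(-dy^2 / (2 * s2))
    E <- ey %o% ex
    R <- 2 * (p[1] * E + p[5] - W)
    c(sum(R * E),
      sum(R * p[1] * (ey %o% (ex * dx / s2))),
      sum(R * p[1] * ((ey * dy / s2) %o% ex)),
      sum(R * p[1] * E * outer(dy^2, dx^2, "+")) / p[4]^3,
      sum(R))
  }
  fit <- stats::nlminb(c(a0, x0, y0, s0, b0), obj, gradient = grad,
                       lower = c(1e-9, min(xs), min(ys), 0.5, 0),
                       upper = c(Inf, max(xs), max(ys), max_sigma, Inf),
                       control = list(iter.max = 200, eval.max = 600))
  conv <- fit$convergence == 0 && fit$iterations < 200
  p <- fit$par
  # parameter uncertainties from the residual-scaled Gauss-Newton covariance
  dx <- xs - p[2]; dy <- ys - p[3]; s2 <- p[4]^2
  ex <- exp(-dx^2 / (2 * s2)); ey <- exp(-dy^2 / (2 * s2))
  E <- ey %o% ex
  J <- cbind(as.vector(E),
             as.vector(p[1] * (ey %o% (ex * dx / s2))),
             as.vector(p[1] * ((ey * dy / s2) %o% ex)),
             as.vector(p[1] * E * outer(dy^2, dx^2, "+")) / p[4]^3,
             1)
  sds <- rep(NA_real_, 5)
  # sandwich covariance with per-pixel Poisson variance (var = model):
  # honest precision for an unweighted LS fit of shot-noise-limited data
  cv <- tryCatch({
    JtJi <- solve(crossprod(J))
    V <- pmax(as.vector(p[1] * E + p[5]), 1e-9)
    JtJi %*% crossprod(J * V, J) %*% JtJi
  }, error = function(e) NULL)
  if (!is.null(cv)) sds <- sqrt(pmax(diag(cv), 0))
  list(amp = p[1], x_px = p[2], y_px = p[3], sigma_px = p[4], bg = p[5],
       photons = p[1] * 2 * pi * p[4]^2, rss = fit$objective,
       sd_x_px = sds[2], sd_y_px = sds[3], sd_sigma_px = sds[4],
       converged = conv)
}

#' Fit a biplane spot
#'
#' Least-squares fit of an isotropic 2D Gaussian (amplitude, centre, width,
#' constant background) on a square window around the seed position in each
#' detection plane. `converged` is FALSE when the iteration cap (100) is
#' hit, the window is clipped at the frame border, or the window is
#' degenerate (all pixels equal).
#'
#' @param stack a [FrameStack-class]
#' @param frame frame index (1-based)
#' @param seed_pos c(row, col) seed pixel
#' @param window window side length in pixels (odd; default 11)
#' @param max_sigma upper width bound in pixels
#' @return list with per-plane fits (`A`, `B`: centre in nm, width in nm,
#'   amplitude, background, photon sum), `residual` (total RSS) and
#'   `converged`
#' @export
fitSpot <- function(stack, frame, seed_pos, window = 11, max_sigma = 6) {
  r <- (window - 1) %/% 2
  px <- stack@pixel_size_nm
  ny <- dim(stack@planeA)[1]; nx <- dim(stack@planeA)[2]
  r0 <- round(seed_pos[1]); c0 <- round(seed_pos[2])
  clipped <- r0 - r < 1 || r0 + r > ny || c0 - r < 1 || c0 + r > nx
  if (clipped) {
    return(list(A = NULL, B = NULL, residual = NA_real_, converged = FALSE))
  }
  rows <- (r0 - r):(r0 + r); cols <- (c0 - r):(c0 + r)
  fa <- fitWindow(stack@planeA[rows, cols, frame], r0, c0, max_sigma)
  fb <- fitWindow(stack@planeB[rows, cols, frame], r0, c0, max_sigma)
  toNm <- function(f) if (is.null(f) || !f$converged) f else
    within_list(f, x_nm = f$x_px * px, y_nm = f$y_px * px,
                width_nm = f$sigma_px * px)
  list(A = toNm(fa), B = toNm(fb),
       residual = fa$rss + fb$rss,
       converged = isTRUE(fa$converged) && isTRUE(fb$converged))
}

# append named fields to a list
within_list <- function(l, ...) {
  extra <- list(...)
  l[names(extra)] <- extra
  l
}

# Monotone spline z -> log width ratio over the calibration's valid range,
# and its numerical inverse.
ratioSpline <- function(cal) {
  keep <- cal@z_nm >= cal@valid_range_nm[1] &
          cal@z_nm <= cal@valid_range_nm[2]
  z <- cal@z_nm[keep]
  lr <- log(cal@widthA_nm[keep] / cal@widthB_nm[keep])
  list(fun = stats::splinefun(z, lr, method = "hyman"),
       z_range = range(z), lr_range = range(lr))
}

#' Invert the biplane width ratio to an axial position
#'
#' Monotone-spline interpolation of the calibration's log width ratio,
#' inverted by root bracketing. Ratios outside the calibrated range clamp
#' to the nearest valid-range endpoint.
#'
#' @param cal a [PSFCalibration-class]
#' @param log_ratio numeric vector of `log(widthA / widthB)` values
#' @return z in nm, one per input ratio
#' @export
zFromLogRatio <- function(cal, log_ratio) {
  sp <- ratioSpline(cal)
  vapply(log_ratio, function(lr) {
    if (lr <= sp$lr_range[1]) return(sp$z_range[1])
    if (lr >= sp$lr_range[2]) return(sp$z_range[2])
    stats::uniroot(function(z) sp$fun(z) - lr, sp$z_range,
                   tol = 1e-6)$root
  }, numeric(1))
}

#' Calibrate the biplane PSF from a bead z stack
#'
#' Beads are detected on the central plane and fitted in both detection
#' planes at every z plane; widths are averaged across beads. The valid
#' range is the maximal interval around focus over which the log width
#' ratio is strictly monotone (unique inversion).
#'
#' @param bead_stack a [FrameStack-class] with `z_planes_nm` set (a bead
#'   z stack of fifty 100 nm steps)
#' @param threshold_photons bead detection threshold
#' @param window fit window in pixels (wide, to accommodate defocused
#'   beads)
#' @return a [PSFCalibration-class]
#' @export
calibratePsf <- function(bead_stack, threshold_photons = 10, window = 41) {
  z <- bead_stack@z_planes_nm
  nz <- length(z)
  if (nz < 2L) stop("bead stack carries no z-plane information")
  mid <- which.min(abs(z))
  cand <- detectSpots(stack_frame_subset(bead_stack, mid),
                      threshold_photons)[[1]]
  if (nrow(cand) == 0L) stop("no beads detected in the central plane")
  wA <- matrix(NA_real_, nz, nrow(cand))
  wB <- matrix(NA_real_, nz, nrow(cand))
  for (b in seq_len(nrow(cand))) {
    for (f in seq_len(nz)) {
      ft <- fitSpot(bead_stack, f, c(cand$row[b], cand$col[b]),
                    window = window, max_sigma = 15)
      if (ft$converged) {
        wA[f, b] <- ft$A$width_nm
        wB[f, b] <- ft$B$width_nm
      }
    }
  }
  mwA <- rowMeans(wA, na.rm = TRUE)
  mwB <- rowMeans(wB, na.rm = TRUE)
  if (anyNA(mwA) || anyNA(mwB))
    stop("bead fitting failed on ", sum(is.na(mwA) | is.na(mwB)), " plane(s)")
  vr <- monotoneRange(z, log(mwA / mwB))
  if (diff(vr) < 400)
    stop("calibration width ratio is not monotone around focus")
  new("PSFCalibration", channel = bead_stack@channel, z_nm = z,
      widthA_nm = mwA, widthB_nm = mwB, valid_range_nm = vr)
}

# single-frame view of a stack (keeps plane geometry)
stack_frame_subset <- function(stack, f) {
  new("FrameStack",
      planeA = stack@planeA[, , f, drop = FALSE],
      planeB = stack@planeB[, , f, drop = FALSE],
      pixel_size_nm = stack@pixel_size_nm, channel = stack@channel,
      z_planes_nm = stack@z_planes_nm[f], meta = stack@meta)
}

#' Localise a frame stack
#'
#' Full biplane localisation: detection, per-plane Gaussian fitting, z from
#' the width-ratio inversion. The lateral position is the photon-weighted
#' mean of the two planes' fitted centres. Localisation precisions
#' (`sigma_xy_nm`, `sigma_z_nm`) come from the fit's Poisson-sandwich
#' parameter covariance; `sigma_z` propagates the width-ratio uncertainty
#' through the local slope of the calibration curve. When the covariance is
#' unavailable the photon-scaling approximation `sigma = width / sqrt(N)`
#' is used. Unconverged fits are dropped with a logged count.
#'
#' @param stack a [FrameStack-class]
#' @param cal a [PSFCalibration-class] for the stack's channel
#' @param threshold_photons detection threshold (see [detectSpots()])
#' @return a [LocalizationTable-class]; the number of dropped fits is in
#'   `locMeta(x)$dropped`
#' @export
localizeStack <- function(stack, cal, threshold_photons = 10) {
  if (!length(cal@z_nm)) stop("empty calibration")
  sp <- ratioSpline(cal)
  slope <- function(z) {
    h <- 1
    (sp$fun(pmin(z + h, sp$z_range[2])) -
       sp$fun(pmax(z - h, sp$z_range[1]))) /
      (pmin(z + h, sp$z_range[2]) - pmax(z - h, sp$z_range[1]))
  }
  cands <- detectSpots(stack, threshold_photons)
  rows <- list()
  dropped <- 0L
  for (f in seq_along(cands)) {
    cc <- cands[[f]]
    for (k in seq_len(nrow(cc))) {
      ft <- fitSpot(stack, f, c(cc$row[k], cc$col[k]))
      if (!ft$converged) { dropped <- dropped + 1L; next }
      nA <- ft$A$photons; nB <- ft$B$photons
      N <- nA + nB
      px <- stack@pixel_size_nm
      x <- (nA * ft$A$x_nm + nB * ft$B$x_nm) / N
      y <- (nA * ft$A$y_nm + nB * ft$B$y_nm) / N
      zhat <- zFromLogRatio(cal, log(ft$A$width_nm / ft$B$width_nm))
      # precision: fit-covariance estimates when available, photon-scaling
      # fallback otherwise
      sxy <- if (is.finite(ft$A$sd_x_px) && is.finite(ft$B$sd_x_px)) {
        vx <- (nA^2 * mean(c(ft$A$sd_x_px, ft$A$sd_y_px))^2 +
               nB^2 * mean(c(ft$B$sd_x_px, ft$B$sd_y_px))^2) / N^2
        sqrt(vx) * px
      } else (ft$A$width_nm + ft$B$width_nm) / 2 / sqrt(N)
      slr <- if (is.finite(ft$A$sd_sigma_px) && is.finite(ft$B$sd_sigma_px))
        sqrt((ft$A$sd_sigma_px / ft$A$sigma_px)^2 +
             (ft$B$sd_sigma_px / ft$B$sigma_px)^2)
      else sqrt(1 / (2 * nA) + 1 / (2 * nB))
      sz <- slr / abs(slope(zhat))
      rows[[length(rows) + 1L]] <- data.frame(
        channel = stack@channel, frame = f - 1L, x_nm = x, y_nm = y,
        z_nm = zhat, photons = N,
        bg = (ft$A$bg + ft$B$bg) / 2, sigma_xy_nm = sxy, sigma_z_nm = sz)
    }
  }
  if (dropped > 0L) message(dropped, " unconverged fit(s) dropped")
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(0), frame = integer(0),
               x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
               photons = numeric(0), bg = numeric(0),
               sigma_xy_nm = numeric(0), sigma_z_nm = numeric(0))
  localizationTable(d, list(pixel_size_nm = stack@pixel_size_nm,
                            axial_range_nm = diff(range(cal@z_nm)),
                            channels = stack@channel,
                            source = "localized", dropped = dropped))
}
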