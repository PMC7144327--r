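#' Rendering configuration
#'
#' @param pixel_nm rendered pixel size (default 10)
#' @param mode one of `"gaussian"` (density-weighted Gaussian splats),
#'   `"histogram"` (2D binning), `"pointcloud"` (sphere export)
#' @param point_diameter_nm constant sphere diameter for point-cloud export
#'   (default 30)
#' @param z_range_nm z range mapped onto the colour scale (default
#'   c(-1000, 1000), a 2 um stack)
#' @param colormaps named list channel -> colour (defaults: GLT-1 blue,
#'   bassoon magenta, Homer1 green)
#' @return named list of rendering parameters
#' @export
renderConfig <- function(pixel_nm = 10, mode = "gaussian",
                         point_diameter_nm = 30,
                         z_range_nm = c(-1000, 1000),
                         colormaps = list(GLT1 = c(0, 0, 1),
                                          bassoon = c(1, 0, 1),
                                          Homer1 = c(0, 1, 0))) {
  stopifnot(pixel_nm > 0, point_diameter_nm > 0,
            mode %in% c("gaussian", "histogram", "pointcloud"))
  list(pixel_nm = pixel_nm, mode = mode,
       point_diameter_nm = point_diameter_nm, z_range_nm = z_range_nm,
       colormaps = colormaps)
}

#' Render 2D projections of a localisation table
#'
#' Per-channel intensity images (xy projection) where brightness reflects
#' accumulated localisation density: in `gaussian` mode every localisation
#' is splatted as an integrated 2D Gaussian of its own lateral precision
#' (unit mass each); in `histogram` mode localisations are binned. A merged
#' RGB image combines the channels with their configured colours.
#' Optionally the per-pixel mean z is returned for z colour-coding.
#'
#' @param table a [LocalizationTable-class]
#' @param cfg see [renderConfig()]
#' @param extent_nm c(xmin, xmax, ymin, ymax); defaults to the data (or
#'   field) bounding box
#' @return list with `channels` (named list of matrices), `merged` (RGB
#'   array), `zmean` (matrix of mean z per pixel, NA where empty) and
#'   `extent_nm`
#' @export
render2d <- function(table, cfg = renderConfig(), extent_nm = NULL) {
  d <- table@data
  if (is.null(extent_nm)) {
    if (nrow(d) == 0L) extent_nm <- c(0, 1000, 0, 1000)
    else extent_nm <- c(floor(min(d$x_nm)), ceiling(max(d$x_nm) + 1e-9),
                        floor(min(d$y_nm)), ceiling(max(d$y_nm) + 1e-9))
  }
  px <- cfg$pixel_nm
  nx <- max(1L, ceiling((extent_nm[2] - extent_nm[1]) / px))
  ny <- max(1L, ceiling((extent_nm[4] - extent_nm[3]) / px))
  chs <- table@meta$channels
  imgs <- lapply(chs, function(ch) matrix(0, ny, nx))
  names(imgs) <- chs
  zsum <- matrix(0, ny, nx); zcnt <- matrix(0, ny, nx)
  for (ch in chs) {
    dd <- d[d$channel == ch, , drop = FALSE]
    if (nrow(dd) == 0L) next
    xp <- (dd$x_nm - extent_nm[1]) / px
    yp <- (dd$y_nm - extent_nm[3]) / px
    if (cfg$mode == "histogram") {
      ix <- pmin(pmax(floor(xp), 0), nx - 1) + 1L
      iy <- pmin(pmax(floor(yp), 0), ny - 1) + 1L
      for (k in seq_along(ix)) {
        imgs[[ch]][iy[k], ix[k]] <- imgs[[ch]][iy[k], ix[k]] + 1
        zsum[iy[k], ix[k]] <- zsum[iy[k], ix[k]] + dd$z_nm[k]
        zcnt[iy[k], ix[k]] <- zcnt[iy[k], ix[k]] + 1
      }
    } else {
      for (k in seq_along(xp)) {
        imgs[[ch]] <- addSplat(imgs[[ch]], xp[k], yp[k],
                               dd$sigma_xy_nm[k] / px, 1)
        ix <- pmin(pmax(floor(xp[k]), 0), nx - 1) + 1L
        iy <- pmin(pmax(floor(yp[k]), 0), ny - 1) + 1L
        zsum[iy, ix] <- zsum[iy, ix] + dd$z_nm[k]
        zcnt[iy, ix] <- zcnt[iy, ix] + 1
      }
    }
  }
  merged <- array(0, c(ny, nx, 3))
  for (ch in chs) {
    col <- cfg$colormaps[[ch]]
    if (is.null(col)) col <- c(1, 1, 1)
    mx <- max(imgs[[ch]])
    if (mx > 0)
      for (c3 in 1:3)
        merged[, , c3] <- merged[, , c3] + col[c3] * imgs[[ch]] / mx
  }
  merged <- pmin(merged, 1)
  zmean <- ifelse(zcnt > 0, zsum / pmax(zcnt, 1), NA_real_)
  list(channels = imgs, merged = merged, zmean = zmean,
       extent_nm = extent_nm)
}

#' z-colour-coded RGB rendering
#'
#' Maps the per-pixel mean z linearly onto a blue-to-red colour scale over
#' `z_range_nm`, modulated by the density image.
#'
#' @param rend result of [render2d()]
#' @param channel channel to colour-code
#' @param cfg see [renderConfig()]
#' @return RGB array (ny x nx x 3)
#' @export
zColorImage <- function(rend, channel, cfg = renderConfig()) {
  img <- rend$channels[[channel]]
  if (is.null(img)) stop("unknown channel '", channel, "'")
  zr <- cfg$z_range_nm
  t <- (rend$zmean - zr[1]) / (zr[2] - zr[1])
  t[is.na(t)] <- 0
  t <- pmin(pmax(t, 0), 1)
  ramp <- grDevices::colorRamp(c("blue", "cyan", "green", "yellow", "red"))
  cols <- ramp(as.vector(t)) / 255
  inten <- img / max(img, 1e-12)
  out <- array(0, c(nrow(img), ncol(img), 3))
  for (c3 in 1:3)
    out[, , c3] <- matrix(cols[, c3], nrow(img), ncol(img)) * inten
  out
}

#' Export localisations as a constant-diameter sphere point cloud (PLY)
#'
#' Every localisation becomes a sphere centre of constant diameter
#' (`point_diameter_nm`, default 30) in an ASCII PLY file with per-vertex
#' colour (by channel) and radius.
#'
#' @param table a [LocalizationTable-class]
#' @param cfg see [renderConfig()]
#' @param path output `.ply` path
#' @return invisibly, the path
#' @export
exportPointCloud <- function(table, cfg = renderConfig(), path) {
  d <- table@data
  n <- nrow(d)
  cols <- t(vapply(d$channel, function(ch) {
    col <- cfg$colormaps[[ch]]
    if (is.null(col)) col <- c(1, 1, 1)
    round(col * 255)
  }, numeric(3)))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("comment constant sphere diameter %g nm",
                   cfg$point_diameter_nm),
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green",
           "property uchar blue", "property float radius", "end_header")
  body <- if (n) sprintf("%s %s %s %d %d %d %s",
                         fmt6(d$x_nm), fmt6(d$y_nm), fmt6(d$z_nm),
                         cols[, 1], cols[, 2], cols[, 3],
                         fmt6(cfg$point_diameter_nm / 2)) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Write an intensity image as 16-bit TIFF and PNG preview
#'
#' @param img numeric matrix (any non-negative scale; normalised to the
#'   maximum)
#' @param prefix output path prefix (writes `<prefix>.tif` and
#'   `<prefix>.png`)
#' @return invisibly, the two paths
#' @export
writeImage <- function(img, prefix) {
  norm <- img / max(img, 1e-12)
  tiff::writeTIFF(norm, paste0(prefix, ".tif"), bits.per.sample = 16L)
  png::writePNG(norm, paste0(prefix, ".png"))
  invisible(paste0(prefix, c(".tif", ".png")))
}
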