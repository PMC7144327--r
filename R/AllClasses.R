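#' @import methods
NULL

#' Sentinel cluster label for noise points
#'
#' DBSCAN labels points not belonging to any cluster with `NOISE` (-1).
#' An absent `cluster_id` column on a localisation table means "unset".
#' @export
NOISE <- -1L

#' Channel roles of a multi-colour experiment
#'
#' Ordered channel names plus a role for each channel: exactly one
#' `"presynaptic"` and one `"postsynaptic"` channel, any number of
#' `"perisynaptic"` channels. The defaults mirror a bassoon / Homer1 /
#' GLT-1 triple stain (presynaptic active-zone scaffold, postsynaptic
#' density scaffold, astrocytic glutamate transporter).
#'
#' @slot names ordered character vector of channel labels
#' @slot roles named character vector mapping channel to role
#' @export
setClass("ChannelSet", representation(names = "character", roles = "character"))

setValidity("ChannelSet", function(object) {
  if (!all(names(object@roles) %in% object@names))
    return("roles refer to unknown channels")
  if (!all(object@roles %in% c("presynaptic", "postsynaptic", "perisynaptic")))
    return("roles must be presynaptic, postsynaptic or perisynaptic")
  if (sum(object@roles == "presynaptic") != 1L)
    return("exactly one presynaptic channel required")
  if (sum(object@roles == "postsynaptic") != 1L)
    return("exactly one postsynaptic channel required")
  TRUE
})

#' Construct a ChannelSet
#'
#' @param names channel labels, in acquisition order
#' @param roles named character vector channel -> role
#' @return a [ChannelSet-class] object
#' @examples
#' channelSet()
#' @export
channelSet <- function(names = c("GLT1", "bassoon", "Homer1"),
                       roles = c(GLT1 = "perisynaptic",
                                 bassoon = "presynaptic",
                                 Homer1 = "postsynaptic")) {
  new("ChannelSet", names = names, roles = roles)
}

#' Table of 3D single-molecule localisations
#'
#' The pipeline's currency: one row per localisation with 3D coordinates in
#' nanometres, channel, frame, photon count, background and per-localisation
#' precision estimates. Ids are dense 0..n-1 in row order. A `cluster_id`
#' column, when present, holds DBSCAN labels (`NOISE` = -1); when absent the
#' assignment is unset. Extra columns (e.g. `orig_id`, `bead_id`) are
#' preserved untouched by all operations.
#'
#' @slot data data.frame with columns `id, channel, frame, x_nm, y_nm, z_nm,
#'   photons, bg, sigma_xy_nm, sigma_z_nm` (plus optional `cluster_id` and
#'   opaque extras)
#' @slot meta list with `pixel_size_nm`, `axial_range_nm`, `channels`,
#'   `source` and optional provenance entries
#' @export
setClass("LocalizationTable", representation(data = "data.frame", meta = "list"))

.LOC_COLS <- c("id", "channel", "frame", "x_nm", "y_nm", "z_nm",
               "photons", "bg", "sigma_xy_nm", "sigma_z_nm")
.LOC_NM_COLS <- c("x_nm", "y_nm", "z_nm", "photons", "bg",
                  "sigma_xy_nm", "sigma_z_nm")

setValidity("LocalizationTable", function(object) {
  d <- object@data
  miss <- setdiff(.LOC_COLS, names(d))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  n <- nrow(d)
  if (n > 0L) {
    if (!identical(as.integer(d$id), seq_len(n) - 1L))
      return("ids must be dense 0..n-1 in row order")
    xyz <- c(d$x_nm, d$y_nm, d$z_nm)
    if (!all(is.finite(xyz)))
      return("coordinates must be finite")
    if (any(d$frame < 0L))
      return("frame numbers must be non-negative")
    ch <- object@meta$channels
    if (!is.null(ch) && !all(d$channel %in% ch))
      return("channel labels not all drawn from meta$channels")
  }
  TRUE
})

#' Construct a LocalizationTable
#'
#' Ids are (re)assigned densely in row order. Missing metadata entries get
#' defaults; `channels` defaults to the unique channels in order of first
#' appearance.
#'
#' @param data data.frame of localisation records (see
#'   [LocalizationTable-class])
#' @param meta named list of metadata
#' @return a [LocalizationTable-class]
#' @export
localizationTable <- function(data, meta = list()) {
  data <- as.data.frame(data)
  n <- nrow(data)
  for (col in setdiff(.LOC_COLS, names(data))) {
    if (col != "id" && n > 0L)
      stop("missing mandatory column '", col, "'")
    data[[col]] <- switch(col,
      channel = character(n), frame = integer(n),
      numeric(n))
  }
  data$id <- seq_len(n) - 1L
  data$frame <- as.integer(data$frame)
  data$channel <- as.character(data$channel)
  data <- data[, c(.LOC_COLS, setdiff(names(data), .LOC_COLS)), drop = FALSE]
  rownames(data) <- NULL
  if (is.null(meta$channels))
    meta$channels <- unique(data$channel)
  if (is.null(meta$pixel_size_nm)) meta$pixel_size_nm <- 100
  if (is.null(meta$axial_range_nm)) meta$axial_range_nm <- 2000
  if (is.null(meta$source)) meta$source <- "unspecified"
  new("LocalizationTable", data = data, meta = meta)
}

#' Generative parameters of the synthetic dSTORM microscope
#'
#' All lengths in nanometres. Geometry: `n_synapses` synapses, each a pair of
#' label discs (radius `disc_radius_nm`, Gaussian thickness
#' `disc_thickness_sigma_nm`) perpendicular to a random axis with centres
#' separated by `synapse_separation_nm`, plus a perisynaptic GLT-1 spherical
#' shell (`glt1_inner_nm`..`glt1_outer_nm`, shifted `glt1_post_shift_nm`
#' toward the postsynaptic disc) and uniform background molecules.
#' Imaging model: each molecule is labelled with probability
#' `labelling_efficiency`, its fluorophore sits an isotropic Gaussian
#' (`label_displacement_sigma_nm` per axis) away from the epitope, emits
#' `1 + Geometric` blinks with mean `blinks_per_fluorophore`, and each blink
#' is localised with anisotropic Gaussian noise (`sigma_xy_nm` per lateral
#' axis, `sigma_z_nm` axial) plus the channel's constant chromatic offset.
#' Spurious localisations are added uniformly at
#' `false_loc_density_per_um3_per_channel`.
#'
#' @export
setClass("SimulationConfig", representation(
  seed = "numeric",
  field_size_nm = "numeric",
  n_synapses = "numeric",
  synapse_separation_nm = "numeric",
  min_synapse_spacing_nm = "numeric",
  disc_radius_nm = "numeric",
  disc_thickness_sigma_nm = "numeric",
  molecules_per_disc = "numeric",
  glt1_inner_nm = "numeric",
  glt1_outer_nm = "numeric",
  glt1_molecules_per_synapse = "numeric",
  glt1_post_shift_nm = "numeric",
  glt1_background_density_per_um3 = "numeric",
  label_displacement_sigma_nm = "numeric",
  labelling_efficiency = "numeric",
  blinks_per_fluorophore = "numeric",
  sigma_xy_nm = "numeric",
  sigma_z_nm = "numeric",
  chromatic_offset_nm = "matrix",
  false_loc_density_per_um3_per_channel = "numeric",
  n_frames = "numeric",
  photons_mean = "numeric",
  bg_photons = "numeric",
  pixel_size_nm = "numeric",
  fov_px = "numeric",
  psf_w0_nm = "numeric",
  psf_zr_nm = "numeric",
  biplane_offset_nm = "numeric",
  channels = "ChannelSet"))

setValidity("SimulationConfig", function(object) {
  lens <- c(object@field_size_nm, object@synapse_separation_nm,
            object@disc_radius_nm, object@disc_thickness_sigma_nm,
            object@glt1_inner_nm, object@glt1_outer_nm,
            object@sigma_xy_nm, object@sigma_z_nm)
  if (any(lens <= 0)) return("all lengths must be positive")
  if (length(object@field_size_nm) != 3L) return("field_size_nm must be length 3")
  le <- object@labelling_efficiency
  if (le <= 0 || le > 1) return("labelling_efficiency must be in (0, 1]")
  if (object@blinks_per_fluorophore < 1) return("mean blink count must be >= 1")
  if (object@glt1_inner_nm >= object@glt1_outer_nm)
    return("glt1 shell inner radius must be < outer radius")
  ch <- object@channels@names
  if (!all(ch %in% rownames(object@chromatic_offset_nm)))
    return("chromatic_offset_nm must have a row per channel")
  TRUE
})

#' Ground-truth scene of a simulated tripartite-synapse field
#'
#' True molecule positions per channel plus per-synapse geometry (centre,
#' unit axis, pre- and post-disc centres). Molecule provenance (synapse id or
#' background) supports parameter-recovery tests.
#'
#' @slot molecules data.frame: `molecule_id, channel, x_nm, y_nm, z_nm,
#'   synapse_id` (NA = background), `component` ("disc", "shell",
#'   "background")
#' @slot synapses data.frame: `synapse_id, cx_nm, cy_nm, cz_nm, ax, ay, az,
#'   pre_x, pre_y, pre_z, post_x, post_y, post_z`
#' @slot config the generating [SimulationConfig-class]
#' @export
setClass("GroundTruthScene", representation(
  molecules = "data.frame", synapses = "data.frame",
  config = "SimulationConfig"))

#' Biplane frame stack
#'
#' Two co-registered photon-count pixel arrays (detection planes A and B),
#' indexed `[row (y), column (x), frame]`. For bead calibration stacks each
#' frame is one axial stage position, recorded in `z_planes_nm`.
#'
#' @export
setClass("FrameStack", representation(
  planeA = "array", planeB = "array",
  pixel_size_nm = "numeric", channel = "character",
  z_planes_nm = "numeric", meta = "list"))

setValidity("FrameStack", function(object) {
  if (!identical(dim(object@planeA), dim(object@planeB)))
    return("plane A and plane B must have identical dimensions")
  if (any(object@planeA < 0) || any(object@planeB < 0))
    return("pixel values must be non-negative")
  TRUE
})

#' Biplane PSF calibration
#'
#' Per-channel mapping from axial position to PSF widths in the two
#' detection planes, sampled on the bead-stack z grid. The log width ratio
#' is strictly monotone over `valid_range_nm`, which makes the
#' width-ratio-to-z inversion unique there.
#'
#' @export
setClass("PSFCalibration", representation(
  channel = "character", z_nm = "numeric",
  widthA_nm = "numeric", widthB_nm = "numeric",
  valid_range_nm = "numeric"))

setValidity("PSFCalibration", function(object) {
  if (any(object@widthA_nm <= 0) || any(object@widthB_nm <= 0))
    return("PSF widths must be positive")
  keep <- object@z_nm >= object@valid_range_nm[1] &
          object@z_nm <= object@valid_range_nm[2]
  lr <- log(object@widthA_nm[keep] / object@widthB_nm[keep])
  if (sum(keep) >= 2L && any(diff(lr) <= 0))
    return("log width ratio must be strictly monotone over the valid range")
  TRUE
})

#' Per-channel 3D affine channel-registration transform
#'
#' Maps a channel's coordinates onto the reference channel:
#' `x' = A x + t`.
#'
#' @export
setClass("ChannelTransform", representation(
  channel = "character", A = "matrix", t = "numeric",
  residual_nm = "numeric", n_beads = "numeric"))

setValidity("ChannelTransform", function(object) {
  if (!identical(dim(object@A), c(3L, 3L))) return("A must be 3x3")
  if (abs(det(object@A)) < 1e-12) return("linear part must be invertible")
  if (object@residual_nm < 0) return("residual must be >= 0")
  TRUE
})

#' A set of DBSCAN clusters with morphometry
#'
#' @slot summary data.frame: `cluster_id, channel, n_locs, cx_nm, cy_nm,
#'   cz_nm, hull_volume_nm3, density_per_um3` (density is NA when the hull is
#'   degenerate)
#' @slot members list of integer vectors: row indices (into the clustered
#'   table) of each cluster's member localisations
#' @slot hulls list of hull vertex coordinate matrices (nm)
#' @slot params list echoing `eps` and `min_pts`
#' @export
setClass("ClusterSet", representation(
  summary = "data.frame", members = "list", hulls = "list", params = "list"))

#' A set of distances of one kind with its histogram
#'
#' Kinds: `pre_post_nn` (per-localisation presynaptic-to-postsynaptic
#' nearest-neighbour distances), `glt1_to_center`, `glt1_to_pre`,
#' `glt1_to_post` (perisynaptic distances). Histogram bins are
#' `[k*bin, (k+1)*bin)`.
#'
#' @export
setClass("DistanceSet", representation(
  kind = "character", distances_nm = "numeric", synapse_id = "integer",
  bin_nm = "numeric", breaks = "numeric", counts = "integer"))

setValidity("DistanceSet", function(object) {
  if (length(object@distances_nm) != length(object@synapse_id))
    return("distances and synapse ids must align")
  if (sum(object@counts) != length(object@distances_nm))
    return("histogram counts must sum to n")
  TRUE
})
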