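#' Number of localisations in a table
#' @param x object
#' @return integer count
#' @export
setGeneric("nLocs", function(x) standardGeneric("nLocs"))

#' Channel labels of an object
#' @param x object
#' @return character vector
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Localisation records as a data.frame
#' @param x object
#' @return data.frame
#' @export
setGeneric("locData", function(x) standardGeneric("locData"))

#' Metadata list of an object
#' @param x object
#' @return named list
#' @export
setGeneric("locMeta", function(x) standardGeneric("locMeta"))

#' Coordinate matrix (nm)
#' @param x object
#' @return n x 3 numeric matrix of x/y/z in nm
#' @export
setGeneric("coordsNm", function(x) standardGeneric("coordsNm"))

#' @rdname nLocs
setMethod("nLocs", "LocalizationTable", function(x) nrow(x@data))

#' @rdname channels
setMethod("channels", "LocalizationTable", function(x) x@meta$channels)

#' @rdname channels
setMethod("channels", "ChannelSet", function(x) x@names)

#' @rdname channels
setMethod("channels", "SimulationConfig", function(x) x@channels@names)

#' @rdname locData
setMethod("locData", "LocalizationTable", function(x) x@data)

#' @rdname locMeta
setMethod("locMeta", "LocalizationTable", function(x) x@meta)

#' @rdname coordsNm
setMethod("coordsNm", "LocalizationTable", function(x)
  unname(as.matrix(x@data[, c("x_nm", "y_nm", "z_nm")])))

#' Channel of a single-channel object
#' @param x a FrameStack, PSFCalibration or ChannelTransform
#' @return channel label
#' @export
channelOf <- function(x) x@channel

setMethod("show", "LocalizationTable", function(object) {
  cat("LocalizationTable with", nrow(object@data), "localisations\n")
  tab <- table(object@data$channel)
  if (length(tab))
    cat("  channels:", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  cat("  pixel size:", object@meta$pixel_size_nm, "nm; axial range:",
      object@meta$axial_range_nm, "nm\n")
})

setMethod("show", "GroundTruthScene", function(object) {
  cat("GroundTruthScene:", nrow(object@synapses), "synapses,",
      nrow(object@molecules), "molecules\n")
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@planeA)
  cat(sprintf("FrameStack [%s]: %d x %d px, %d frame(s), %g nm/px\n",
              object@channel, d[1], d[2], d[3], object@pixel_size_nm))
})

setMethod("show", "PSFCalibration", function(object) {
  cat(sprintf("PSFCalibration [%s]: %d z samples, valid range [%g, %g] nm\n",
              object@channel, length(object@z_nm),
              object@valid_range_nm[1], object@valid_range_nm[2]))
})

setMethod("show", "ChannelTransform", function(object) {
  cat(sprintf("ChannelTransform [%s]: RMS residual %.3g nm (%d beads)\n",
              object@channel, object@residual_nm, object@n_beads))
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet with", nrow(object@summary), "cluster(s)",
      sprintf("(eps = %g nm, min_pts = %d)\n",
              object@params$eps, object@params$min_pts))
})

setMethod("show", "DistanceSet", function(object) {
  n <- length(object@distances_nm)
  cat(sprintf("DistanceSet [%s]: n = %d", object@kind, n))
  if (n > 0)
    cat(sprintf(", median = %.1f nm, modal bin centre = %.1f nm",
                stats::median(object@distances_nm), histogramMode(object)))
  cat("\n")
})

#' Cluster summary table of a ClusterSet
#' @param x a [ClusterSet-class]
#' @return data.frame of per-cluster statistics
#' @export
clusterSummary <- function(x) x@summary

#' Member row indices of each cluster
#' @param x a [ClusterSet-class]
#' @return list of integer vectors
#' @export
clusterMembers <- function(x) x@members

#' Distances held by a DistanceSet
#' @param x a [DistanceSet-class]
#' @return numeric vector of distances in nm
#' @export
distancesNm <- function(x) x@distances_nm
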