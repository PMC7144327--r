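#' Estimate a 3D affine channel-registration transform
#'
#' Least-squares affine `x' = A x + t` mapping `moving` bead positions onto
#' `ref`, with correspondence given by row index. Requires at least 4
#' non-coplanar pairs.
#'
#' @param ref n x 3 matrix of reference bead positions (nm)
#' @param moving n x 3 matrix of the same beads in the moving channel (nm)
#' @param channel label stored on the transform
#' @param tol relative rank tolerance
#' @return a [ChannelTransform-class]
#' @export
estimateTransform <- function(ref, moving, channel = "moving", tol = 1e-8) {
  ref <- as.matrix(ref); moving <- as.matrix(moving)
  if (nrow(ref) != nrow(moving)) stop("point sets must be matched by index")
  n <- nrow(ref)
  if (n < 4L) stop("rank error: need >= 4 matched bead pairs, got ", n)
  ctr <- sweep(moving, 2, colMeans(moving))
  sv <- svd(ctr)$d
  if (sv[3] < tol * max(sv[1], 1))
    stop("rank error: bead configuration is coplanar or degenerate")
  M <- cbind(moving, 1)
  B <- solve(crossprod(M), crossprod(M, ref))  # 4 x 3
  A <- t(B[1:3, , drop = FALSE])
  tvec <- as.numeric(B[4, ])
  pred <- moving %*% t(A) + matrix(tvec, n, 3, byrow = TRUE)
  rms <- sqrt(mean(rowSums((pred - ref)^2)))
  new("ChannelTransform", channel = channel, A = A, t = tvec,
      residual_nm = rms, n_beads = n)
}

#' Apply per-channel transforms to a localisation table
#'
#' Coordinates of every channel are mapped through its transform; all other
#' fields are untouched. Metadata is annotated with transform provenance.
#'
#' @param table a [LocalizationTable-class]
#' @param transforms named list of [ChannelTransform-class], one per channel
#' @param allow_identity if TRUE, channels without a transform are passed
#'   through unchanged; otherwise a missing transform is an error
#' @return the registered [LocalizationTable-class]
#' @export
applyTransform <- function(table, transforms, allow_identity = FALSE) {
  d <- table@data
  for (ch in unique(d$channel)) {
    tr <- transforms[[ch]]
    if (is.null(tr)) {
      if (allow_identity) next
      stop("no transform for channel '", ch,
           "' (use allow_identity = TRUE to pass it through)")
    }
    idx <- d$channel == ch
    P <- as.matrix(d[idx, c("x_nm", "y_nm", "z_nm")])
    P2 <- P %*% t(tr@A) + matrix(tr@t, sum(idx), 3, byrow = TRUE)
    d$x_nm[idx] <- P2[, 1]; d$y_nm[idx] <- P2[, 2]; d$z_nm[idx] <- P2[, 3]
  }
  meta <- table@meta
  meta$registered <- names(transforms)
  localizationTable(d, meta)
}

#' Invert a channel transform
#'
#' @param tr a [ChannelTransform-class]
#' @return the inverse [ChannelTransform-class]
#' @export
invertTransform <- function(tr) {
  Ai <- solve(tr@A)
  new("ChannelTransform", channel = tr@channel, A = Ai,
      t = as.numeric(-Ai %*% tr@t), residual_nm = tr@residual_nm,
      n_beads = tr@n_beads)
}

#' Match unordered bead sets by mutual nearest neighbours
#'
#' Two bead position sets are matched by mutual-nearest-neighbour pairing
#' within `max_dist_nm`; unmatched beads are dropped.
#'
#' @param ref,moving matrices of bead positions (nm)
#' @param max_dist_nm maximum pairing distance (default 500)
#' @return two-column integer matrix of matched (ref, moving) row indices
#' @export
matchBeads <- function(ref, moving, max_dist_nm = 500) {
  ref <- as.matrix(ref); moving <- as.matrix(moving)
  if (nrow(ref) == 0L || nrow(moving) == 0L)
    return(matrix(integer(0), 0, 2))
  d2 <- crossDist2(ref, moving)
  nn_rm <- apply(d2, 1, which.min)
  nn_mr <- apply(d2, 2, which.min)
  i <- which(nn_mr[nn_rm] == seq_len(nrow(ref)))
  keep <- d2[cbind(i, nn_rm[i])] <= max_dist_nm^2
  cbind(ref = i[keep], moving = nn_rm[i[keep]])
}

#' Estimate registration transforms from a multi-colour bead table
#'
#' Bead positions per channel are the centroids of each bead's
#' localisations (grouped by `bead_id` when present, otherwise by
#' mutual-nearest-neighbour matching of raw positions). Each non-reference
#' channel gets an affine transform onto the reference channel; the
#' reference channel gets the identity.
#'
#' @param bead_table a [LocalizationTable-class] of fiducial localisations
#' @param ref_channel reference channel label
#' @return named list of [ChannelTransform-class]
#' @export
registerChannels <- function(bead_table, ref_channel) {
  chs <- channels(bead_table)
  if (!ref_channel %in% chs)
    stop("reference channel '", ref_channel, "' not in table")
  centroids <- function(ch) {
    sub <- filterByChannel(bead_table, ch)@data
    if (!is.null(sub$bead_id)) {
      agg <- stats::aggregate(sub[, c("x_nm", "y_nm", "z_nm")],
                              by = list(bead_id = sub$bead_id), FUN = mean)
      agg <- agg[order(agg$bead_id), ]
      as.matrix(agg[, c("x_nm", "y_nm", "z_nm")])
    } else as.matrix(sub[, c("x_nm", "y_nm", "z_nm")])
  }
  refP <- centroids(ref_channel)
  out <- list()
  for (ch in chs) {
    if (ch == ref_channel) {
      out[[ch]] <- new("ChannelTransform", channel = ch, A = diag(3),
                       t = c(0, 0, 0), residual_nm = 0,
                       n_beads = nrow(refP))
    } else {
      movP <- centroids(ch)
      if (nrow(movP) == nrow(refP)) {
        pairs <- cbind(seq_len(nrow(refP)), seq_len(nrow(refP)))
      } else {
        pairs <- matchBeads(refP, movP)
      }
      out[[ch]] <- estimateTransform(refP[pairs[, 1], , drop = FALSE],
                                     movP[pairs[, 2], , drop = FALSE],
                                     channel = ch)
    }
  }
  out
}

#' Write channel transforms to JSON
#'
#' @param transforms named list of [ChannelTransform-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeTransforms <- function(transforms, path) {
  obj <- lapply(transforms, function(tr) list(
    channel = tr@channel, A = tr@A, t = tr@t,
    residual_nm = tr@residual_nm, n_beads = tr@n_beads))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
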