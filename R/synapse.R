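#' Pairing and distance parameters
#'
#' @param max_center_distance_nm maximum pre/post centroid distance for an
#'   opposed cluster pair to count as a synapse (default 500)
#' @param search_radius_nm perisynaptic search radius around the synapse
#'   centre (default 500)
#' @param nn_cutoff_nm nearest-neighbour distance cutoff (default 500)
#' @param histogram_bin_nm histogram bin width (default 10)
#' @return named list of parameters
#' @export
pairingParams <- function(max_center_distance_nm = 500,
                          search_radius_nm = 500,
                          nn_cutoff_nm = 500,
                          histogram_bin_nm = 10) {
  stopifnot(max_center_distance_nm > 0, search_radius_nm > 0,
            nn_cutoff_nm > 0, histogram_bin_nm > 0)
  list(max_center_distance_nm = max_center_distance_nm,
       search_radius_nm = search_radius_nm,
       nn_cutoff_nm = nn_cutoff_nm,
       histogram_bin_nm = histogram_bin_nm)
}

#' Identify synapses as opposed pre/postsynaptic cluster pairs
#'
#' Candidate pairs are all (pre, post) cluster pairs whose centroids lie
#' within `max_center_distance_nm`. Pairs are accepted greedily in
#' ascending centroid distance (ties broken by lower pre id, then lower
#' post id); each cluster is used at most once, so one presynaptic cluster
#' cannot spawn several synapses. The synapse centre is the midpoint of the
#' two centroids and the axis the unit vector from the presynaptic to the
#' postsynaptic centroid.
#'
#' @param pre_clusters,post_clusters [ClusterSet-class] objects for the
#'   presynaptic and postsynaptic channels
#' @param params see [pairingParams()]
#' @return data.frame with one row per synapse: `synapse_id, pre_cluster,
#'   post_cluster, cx_nm, cy_nm, cz_nm, ax, ay, az, center_distance_nm`
#' @export
pairSynapses <- function(pre_clusters, post_clusters,
                         params = pairingParams()) {
  empty <- data.frame(synapse_id = integer(0), pre_cluster = integer(0),
                      post_cluster = integer(0), cx_nm = numeric(0),
                      cy_nm = numeric(0), cz_nm = numeric(0),
                      ax = numeric(0), ay = numeric(0), az = numeric(0),
                      center_distance_nm = numeric(0))
  pre <- clusterSummary(pre_clusters)
  post <- clusterSummary(post_clusters)
  if (nrow(pre) == 0L || nrow(post) == 0L) return(empty)
  P <- as.matrix(pre[, c("cx_nm", "cy_nm", "cz_nm")])
  Q <- as.matrix(post[, c("cx_nm", "cy_nm", "cz_nm")])
  D <- sqrt(crossDist2(P, Q))
  cand <- which(D <= params$max_center_distance_nm, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  ord <- order(D[cand], pre$cluster_id[cand[, 1]],
               post$cluster_id[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  used_pre <- logical(nrow(pre)); used_post <- logical(nrow(post))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_pre[i] || used_post[j]) next
    used_pre[i] <- TRUE; used_post[j] <- TRUE
    ctr <- (P[i, ] + Q[j, ]) / 2
    ax <- Q[j, ] - P[i, ]
    nrm <- sqrt(sum(ax^2))
    ax <- if (nrm > 0) ax / nrm else c(NA_real_, NA_real_, NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      pre_cluster = pre$cluster_id[i], post_cluster = post$cluster_id[j],
      cx_nm = ctr[1], cy_nm = ctr[2], cz_nm = ctr[3],
      ax = ax[1], ay = ax[2], az = ax[3], center_distance_nm = D[i, j])
  }
  out <- do.call(rbind, rows)
  cbind(synapse_id = seq_len(nrow(out)) - 1L, out)
}

# Histogram over [k*bin, (k+1)*bin) bins covering all distances.
distanceSet <- function(kind, d, synapse_id = rep(NA_integer_, length(d)),
                        bin_nm = 10) {
  nb <- if (length(d)) floor(max(d) / bin_nm) + 1L else 1L
  breaks <- seq(0, nb * bin_nm, by = bin_nm)
  counts <- if (length(d))
    tabulate(findInterval(d, breaks, rightmost.closed = FALSE), nb)
  else integer(nb)
  new("DistanceSet", kind = kind, distances_nm = as.numeric(d),
      synapse_id = as.integer(synapse_id), bin_nm = bin_nm,
      breaks = breaks, counts = as.integer(counts))
}

#' Per-localisation nearest-neighbour distances between two channels
#'
#' For every source localisation, the 3D Euclidean distance to its nearest
#' target localisation; distances above `cutoff_nm` are discarded. The
#' result carries a histogram with `histogram_bin_nm`-wide bins.
#'
#' @param source,target [LocalizationTable-class] objects (e.g. the
#'   presynaptic and postsynaptic channel tables)
#' @param cutoff_nm distance cutoff (default 500, roughly half the spacing
#'   of neighbouring synapses)
#' @param bin_nm histogram bin width (default 10)
#' @param kind label stored on the [DistanceSet-class]
#' @return a [DistanceSet-class]
#' @export
nnDistances <- function(source, target, cutoff_nm = 500, bin_nm = 10,
                        kind = "pre_post_nn") {
  if (nLocs(source) == 0L || nLocs(target) == 0L)
    return(distanceSet(kind, numeric(0), integer(0), bin_nm))
  d <- nearestWithinCutoff(coordsNm(source), coordsNm(target), cutoff_nm)
  d <- d[!is.na(d)]
  distanceSet(kind, d, rep(NA_integer_, length(d)), bin_nm)
}

#' Perisynaptic GLT-1 distance statistics
#'
#' For each GLT-1 localisation and each identified synapse whose centre
#' lies within `search_radius_nm` of it, three distances are recorded:
#' to the synapse centre, to the nearest member localisation of the
#' synapse's presynaptic cluster, and to the nearest member of its
#' postsynaptic cluster. A localisation within range of k synapses
#' contributes k entries unless `nearest_synapse_only` is set.
#'
#' @param glt1 [LocalizationTable-class] of the perisynaptic channel
#' @param pairs synapse table from [pairSynapses()]
#' @param pre_channel,post_channel the labelled channel tables returned by
#'   [clusterChannel()] for the pre- and postsynaptic channels (lists with
#'   `table` and `clusters`)
#' @param params see [pairingParams()]
#' @param nearest_synapse_only if TRUE each localisation contributes only
#'   to its nearest in-range synapse
#' @param use_centroid if TRUE distances (b) and (c) are measured to the
#'   cluster centroid instead of the nearest member localisation
#' @return named list of three [DistanceSet-class] objects:
#'   `glt1_to_center`, `glt1_to_pre`, `glt1_to_post`
#' @export
perisynapticDistances <- function(glt1, pairs, pre_channel, post_channel,
                                  params = pairingParams(),
                                  nearest_synapse_only = FALSE,
                                  use_centroid = FALSE) {
  emptyRes <- function() list(
    glt1_to_center = distanceSet("glt1_to_center", numeric(0), integer(0),
                                 params$histogram_bin_nm),
    glt1_to_pre = distanceSet("glt1_to_pre", numeric(0), integer(0),
                              params$histogram_bin_nm),
    glt1_to_post = distanceSet("glt1_to_post", numeric(0), integer(0),
                               params$histogram_bin_nm))
  if (nLocs(glt1) == 0L || nrow(pairs) == 0L) return(emptyRes())
  G <- coordsNm(glt1)
  C <- as.matrix(pairs[, c("cx_nm", "cy_nm", "cz_nm")])
  D <- sqrt(crossDist2(G, C))
  inrange <- D <= params$search_radius_nm
  if (nearest_synapse_only) {
    nearest <- apply(D, 1, which.min)
    m <- matrix(FALSE, nrow(D), ncol(D))
    m[cbind(seq_len(nrow(D)), nearest)] <- TRUE
    inrange <- inrange & m
  }
  preX <- coordsNm(pre_channel$table)
  postX <- coordsNm(post_channel$table)
  preS <- clusterSummary(pre_channel$clusters)
  postS <- clusterSummary(post_channel$clusters)
  preM <- clusterMembers(pre_channel$clusters)
  postM <- clusterMembers(post_channel$clusters)
  dc <- list(); dp <- list(); dq <- list(); sid <- list()
  for (s in seq_len(nrow(pairs))) {
    gi <- which(inrange[, s])
    if (!length(gi)) next
    Gs <- G[gi, , drop = FALSE]
    nearestTo <- function(summ, memb, X, cluster_id) {
      k <- which(summ$cluster_id == cluster_id)
      if (use_centroid) {
        sqrt(rowSums(sweep(Gs, 2, as.numeric(
          summ[k, c("cx_nm", "cy_nm", "cz_nm")]))^2))
      } else {
        Pm <- X[memb[[k]], , drop = FALSE]
        sqrt(apply(crossDist2(Gs, Pm), 1, min))
      }
    }
    dc[[length(dc) + 1L]] <- D[gi, s]
    dp[[length(dp) + 1L]] <- nearestTo(preS, preM, preX,
                                       pairs$pre_cluster[s])
    dq[[length(dq) + 1L]] <- nearestTo(postS, postM, postX,
                                       pairs$post_cluster[s])
    sid[[length(sid) + 1L]] <- rep(pairs$synapse_id[s], length(gi))
  }
  sidv <- as.integer(unlist(sid))
  bin <- params$histogram_bin_nm
  list(glt1_to_center = distanceSet("glt1_to_center", unlist(dc), sidv, bin),
       glt1_to_pre = distanceSet("glt1_to_pre", unlist(dp), sidv, bin),
       glt1_to_post = distanceSet("glt1_to_post", unlist(dq), sidv, bin))
}

#' Modal bin centre of a distance histogram
#'
#' Centre of the most populated histogram bin; ties go to the lowest bin.
#'
#' @param ds a non-empty [DistanceSet-class]
#' @return bin centre in nm
#' @export
histogramMode <- function(ds) {
  if (!length(ds@distances_nm)) stop("empty distance set has no mode")
  k <- which.max(ds@counts)  # which.max takes the first (lowest) maximum
  (ds@breaks[k] + ds@breaks[k + 1L]) / 2
}
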