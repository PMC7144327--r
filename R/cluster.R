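#' DBSCAN clustering of a 3D point cloud
#'
#' Classic density-based clustering with deterministic semantics. A core
#' point has at least `min_pts` points (itself included) within Euclidean
#' distance `eps` (inclusive). Clusters are maximal density-connected sets;
#' seeds are taken in ascending point index, so a border point reachable
#' from several clusters is assigned to the cluster seeded earliest — the
#' first cluster that reaches it in scan order. Clusters whose final size
#' after border assignment is below `min_pts` are discarded to noise, making
#' "a minimum of `min_pts` localisations per cluster" literally true of
#' every reported cluster. Surviving labels are renumbered 0..k-1 by
#' ascending minimum member index; noise is `NOISE` (-1).
#'
#' Neighbourhoods are found with a uniform-grid index, so runtime is close
#' to linear for bounded-density point clouds.
#'
#' @param points n x 3 matrix of coordinates (nm)
#' @param eps neighbourhood radius in nm (default 100)
#' @param min_pts minimum neighbourhood size, self included (default 50)
#' @return integer vector of labels per point (0-based cluster ids, -1 for
#'   noise)
#' @export
dbscan <- function(points, eps = 100, min_pts = 50) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  stopifnot(eps > 0, min_pts >= 1, all(is.finite(points)))
  nb <- neighborLists(points, eps)
  core <- lengths(nb) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  queue <- integer(n + sum(lengths(nb)))
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (!core[i]) { labels[i] <- -1L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue[1L] <- i; head <- 1L; tail <- 1L
    while (head <= tail) {
      j <- queue[head]; head <- head + 1L
      if (core[j]) {
        for (k in nb[[j]]) {
          if (is.na(labels[k])) {
            labels[k] <- cl
            tail <- tail + 1L; queue[tail] <- k
          } else if (labels[k] == -1L) {
            labels[k] <- cl  # border point claimed by the first cluster
          }
        }
      }
    }
  }
  relabelClusters(labels, min_pts)
}

# Discard clusters smaller than min_pts and renumber the survivors
# 0..k-1 by ascending minimum member index; noise = -1.
relabelClusters <- function(labels, min_pts) {
  pos <- labels > 0L
  if (!any(pos)) return(rep(-1L, length(labels)))
  sizes <- table(labels[pos])
  keep <- as.integer(names(sizes)[sizes >= min_pts])
  labels[pos & !(labels %in% keep)] <- -1L
  pos <- labels > 0L
  if (!any(pos)) return(labels)
  firsts <- vapply(keep, function(cl) which(labels == cl)[1], integer(1))
  remap <- integer(max(keep))
  remap[keep[order(firsts)]] <- seq_along(keep) - 1L
  labels[pos] <- remap[labels[pos]]
  labels
}

#' Assign DBSCAN labels to a localisation table
#'
#' Convenience wrapper: clusters the table's coordinates and stores labels
#' in the `cluster_id` column.
#'
#' @param table a [LocalizationTable-class]
#' @param eps,min_pts see [dbscan()]
#' @return the table with a `cluster_id` column
#' @export
clusterLocalizations <- function(table, eps = 100, min_pts = 50) {
  d <- table@data
  d$cluster_id <- dbscan(coordsNm(table), eps, min_pts)
  localizationTable(d, table@meta)
}

#' Per-cluster morphometry
#'
#' For every cluster: localisation count, centroid (unweighted mean),
#' convex-hull volume in nm^3 (0 when fewer than 4 members or degenerate)
#' and density in localisations per um^3 (NA when the hull volume is 0).
#'
#' @param table a [LocalizationTable-class]
#' @param labels integer labels aligned with the table rows (defaults to the
#'   table's `cluster_id` column)
#' @param eps,min_pts clustering parameters echoed into the result
#' @return a [ClusterSet-class]
#' @export
summarizeClusters <- function(table, labels = NULL, eps = 100, min_pts = 50) {
  d <- table@data
  if (is.null(labels)) labels <- d$cluster_id
  if (is.null(labels)) stop("no labels given and no cluster_id column set")
  if (length(labels) != nrow(d)) stop("labels do not align with the table")
  X <- coordsNm(table)
  ids <- sort(unique(labels[labels >= 0L]))
  members <- lapply(ids, function(cl) which(labels == cl))
  hulls <- vector("list", length(ids))
  nc <- length(ids)
  s <- data.frame(cluster_id = as.integer(ids),
                  channel = vapply(members, function(m)
                    d$channel[m[1]], character(1)),
                  n_locs = lengths(members),
                  cx_nm = rep(NA_real_, nc), cy_nm = rep(NA_real_, nc),
                  cz_nm = rep(NA_real_, nc),
                  hull_volume_nm3 = rep(0, nc),
                  density_per_um3 = rep(NA_real_, nc))
  for (k in seq_along(ids)) {
    P <- X[members[[k]], , drop = FALSE]
    s[k, c("cx_nm", "cy_nm", "cz_nm")] <- colMeans(P)
    h <- convexHull3d(P)
    s$hull_volume_nm3[k] <- h$volume
    hulls[[k]] <- P[h$vertices, , drop = FALSE]
    if (h$volume > 0)
      s$density_per_um3[k] <- s$n_locs[k] / (h$volume / 1e9)
  }
  new("ClusterSet", summary = s, members = members, hulls = hulls,
      params = list(eps = eps, min_pts = as.integer(min_pts)))
}

#' Cluster one channel of a localisation table
#'
#' Filters the table to `channel`, runs [dbscan()] and summarises the
#' clusters.
#'
#' @param table a [LocalizationTable-class]
#' @param channel channel label
#' @param eps,min_pts see [dbscan()]
#' @return list with `table` (the filtered, labelled channel table) and
#'   `clusters` (a [ClusterSet-class])
#' @export
clusterChannel <- function(table, channel, eps = 100, min_pts = 50) {
  sub <- filterByChannel(table, channel)
  sub <- clusterLocalizations(sub, eps, min_pts)
  list(table = sub,
       clusters = summarizeClusters(sub, eps = eps, min_pts = min_pts))
}
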