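# Independent oracles and shared fixtures, implemented without reusing the
# package's internal search structures.

# O(n^2) DBSCAN with the documented semantics: neighbourhood includes the
# point itself, seeds scanned in ascending index, border points claimed by
# the first cluster that reaches them, clusters smaller than min_pts
# discarded, labels renumbered 0..k-1 by ascending minimum member index.
bruteDbscan <- function(X, eps, min_pts) {
  n <- nrow(X)
  if (n == 0L) return(integer(0))
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (!core[i]) { labels[i] <- -1L; next }
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        if (!core[j]) next
        for (k in nb[[j]]) {
          if (is.na(labels[k])) {
            labels[k] <- cl
            nxt <- c(nxt, k)
          } else if (labels[k] == -1L) labels[k] <- cl
        }
      }
      frontier <- nxt
    }
  }
  for (c0 in seq_len(cl))
    if (sum(labels == c0) < min_pts) labels[labels == c0] <- -1L
  remaining <- sort(unique(labels[labels > 0L]))
  firsts <- vapply(remaining, function(c0) which(labels == c0)[1], integer(1))
  out <- rep(-1L, n)
  for (r in seq_along(remaining))
    out[labels == remaining[order(firsts)][r]] <- r - 1L
  out
}

# O(n^2) nearest-neighbour distances with cutoff.
bruteNN <- function(S, Tg, cutoff) {
  d <- apply(S, 1, function(p)
    sqrt(min(colSums((t(Tg) - p)^2))))
  d[d <= cutoff]
}

# Facet-free point-in-hull test: Frank-Wolfe iterations on the projection
# problem, classifying a point as outside only when a separating-hyperplane
# certificate is found (all of X strictly on the far side of the current
# gradient direction). Points inside conv(X) can never be certified.
fwInHull <- function(X, P, iters = 150) {
  M <- nrow(P)
  scale <- max(apply(X, 2, function(v) diff(range(v))))
  x <- matrix(X[1, ], M, 3, byrow = TRUE)
  outside <- logical(M)
  for (it in seq_len(iters)) {
    G <- x - P
    D <- G %*% t(X)                      # <g_m, X_i>
    jmin <- max.col(-D, ties.method = "first")
    supp <- D[cbind(seq_len(M), jmin)]   # min_i <g, X_i>
    gp <- rowSums(G * P)                 # <g, p>
    gn <- sqrt(rowSums(G^2))
    outside <- outside | (supp - gp > 1e-9 * scale * pmax(gn, 1e-300))
    S <- X[jmin, , drop = FALSE]
    dxs <- x - S
    denom <- rowSums(dxs^2)
    gam <- ifelse(denom > 0, pmin(pmax(rowSums(G * dxs) / denom, 0), 1), 0)
    x <- x - gam * dxs
  }
  !outside
}

# Monte-Carlo rejection estimate of the convex-hull volume of X.
mcHullVolumeFW <- function(X, n_samples = 20000, seed = 1) {
  set.seed(seed)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  P <- cbind(stats::runif(n_samples, lo[1], hi[1]),
             stats::runif(n_samples, lo[2], hi[2]),
             stats::runif(n_samples, lo[3], hi[3]))
  mean(fwInHull(X, P)) * prod(hi - lo)
}

# Exhaustive greedy one-to-one matching oracle for synapse pairing.
bruteGreedyPairs <- function(P, Q, max_dist) {
  cand <- expand.grid(i = seq_len(nrow(P)), j = seq_len(nrow(Q)))
  cand$d <- sqrt(rowSums((P[cand$i, , drop = FALSE] -
                            Q[cand$j, , drop = FALSE])^2))
  cand <- cand[cand$d <= max_dist, , drop = FALSE]
  cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
  usedP <- logical(nrow(P)); usedQ <- logical(nrow(Q))
  out <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (usedP[i] || usedQ[j]) next
    usedP[i] <- TRUE; usedQ[j] <- TRUE
    out <- rbind(out, c(i, j))
  }
  out
}

# A small localisation table fixture.
makeFixtureTable <- function(n = 5, channels = c("bassoon", "Homer1")) {
  set.seed(42)
  localizationTable(data.frame(
    channel = rep(channels, length.out = n),
    frame = seq_len(n) - 1L,
    x_nm = round(stats::runif(n, 0, 5000), 3),
    y_nm = round(stats::runif(n, 0, 5000), 3),
    z_nm = round(stats::runif(n, -800, 800), 3),
    photons = 1000, bg = 5, sigma_xy_nm = 10, sigma_z_nm = 25),
    list(pixel_size_nm = 100, axial_range_nm = 2000,
         channels = channels, source = "fixture"))
}

# Partition of labels as a canonical set-of-sets (for permutation tests).
partitionOf <- function(labels) {
  cls <- sort(unique(labels[labels >= 0L]))
  sets <- lapply(cls, function(c0) sort(which(labels == c0)))
  sets[order(vapply(sets, `[`, integer(1), 1L))]
}

# DistanceSet straight from a numeric vector (internal constructor).
distancesToSet <- function(d, bin = 10) {
  TriSynapse:::distanceSet("pre_post_nn", d, rep(NA_integer_, length(d)), bin)
}

# Channel-result fixture: one tight 6-point cluster per centroid row, with
# zero-sum offsets so the cluster centroid equals the requested point.
clusterChannelFixture <- function(P, channel = "bassoon") {
  P <- matrix(P, ncol = 3)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  pts <- do.call(rbind, lapply(seq_len(nrow(P)), function(i)
    sweep(offs, 2, P[i, ], "+")))
  tb <- localizationTable(data.frame(
    channel = channel, frame = 0L, x_nm = pts[, 1], y_nm = pts[, 2],
    z_nm = pts[, 3], photons = 1000, bg = 5, sigma_xy_nm = 10,
    sigma_z_nm = 25), list(channels = channel))
  labels <- rep(seq_len(nrow(P)) - 1L, each = 6L)
  list(table = tb, clusters = summarizeClusters(tb, labels, min_pts = 6))
}
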