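#' 3D convex hull of a point cloud
#'
#' Incremental (beneath-beyond) convex hull. Returns the hull facets with
#' outward unit normals and the enclosed volume (divergence theorem over
#' the facet fan around an interior point). Degenerate inputs (< 4 points,
#' or all points collinear/coplanar within tolerance) yield zero volume and
#' no facets.
#'
#' @param X n x 3 numeric matrix of coordinates (nm)
#' @param tol relative degeneracy tolerance
#' @return list with `volume` (nm^3), `faces` (k x 3 vertex indices into
#'   `X`), `normals` (k x 3 outward unit normals), `offsets` (k, facet plane
#'   offsets so a point p is inside iff `normals %*% p <= offsets`),
#'   `vertices` (indices of hull vertices), `degenerate` flag
#' @examples
#' tet <- rbind(c(0, 0, 0), c(300, 0, 0), c(0, 300, 0), c(0, 0, 300))
#' convexHull3d(tet)$volume  # 300^3 / 6 = 4.5e6
#' @export
convexHull3d <- function(X, tol = 1e-9) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  degen <- list(volume = 0, faces = matrix(integer(0), 0, 3),
                normals = matrix(numeric(0), 0, 3), offsets = numeric(0),
                vertices = integer(0), degenerate = TRUE)
  if (n < 4L) return(degen)
  scale <- max(apply(X, 2, function(v) diff(range(v))))
  if (scale == 0) return(degen)
  eps <- tol * scale
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  # initial non-degenerate tetrahedron
  i1 <- which.min(X[, 1])
  d1 <- rowSums(sweep(X, 2, X[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) < eps) return(degen)
  u <- (X[i2, ] - X[i1, ]) / sqrt(d1[i2])
  W <- sweep(X, 2, X[i1, ])
  proj <- as.numeric(W %*% u)
  perp2 <- pmax(rowSums(W^2) - proj^2, 0)
  i3 <- which.max(perp2)
  if (sqrt(perp2[i3]) < eps) return(degen)
  nrm0 <- cross3(X[i2, ] - X[i1, ], X[i3, ] - X[i1, ])
  nrm0 <- nrm0 / sqrt(sum(nrm0^2))
  d4 <- abs(as.numeric(W %*% nrm0))
  i4 <- which.max(d4)
  if (d4[i4] < eps) return(degen)
  verts <- c(i1, i2, i3, i4)
  c0 <- colMeans(X[verts, ])
  mkface <- function(a, b, c) {
    nr <- cross3(X[b, ] - X[a, ], X[c, ] - X[a, ])
    nr <- nr / sqrt(sum(nr^2))
    if (sum(nr * (c0 - X[a, ])) > 0) nr <- -nr  # outward
    list(v = c(a, b, c), n = nr, o = sum(nr * X[a, ]))
  }
  faces <- list(mkface(i1, i2, i3), mkface(i1, i2, i4),
                mkface(i1, i3, i4), mkface(i2, i3, i4))
  rest <- setdiff(seq_len(n), verts)
  for (p in rest) {
    Np <- vapply(faces, function(f) sum(f$n * X[p, ]) - f$o, numeric(1))
    vis <- Np > eps
    if (!any(vis)) next
    vis_faces <- faces[vis]
    faces <- faces[!vis]
    edges <- do.call(rbind, lapply(vis_faces, function(f)
      rbind(sort(f$v[c(1, 2)]), sort(f$v[c(2, 3)]), sort(f$v[c(1, 3)]))))
    ek <- paste(edges[, 1], edges[, 2])
    horizon <- edges[ek %in% names(which(table(ek) == 1L)), , drop = FALSE]
    for (e in seq_len(nrow(horizon)))
      faces[[length(faces) + 1L]] <- mkface(horizon[e, 1], horizon[e, 2], p)
  }
  F <- t(vapply(faces, `[[`, numeric(3), "v"))
  N <- t(vapply(faces, `[[`, numeric(3), "n"))
  O <- vapply(faces, `[[`, numeric(1), "o")
  # fan volume around the interior point
  vol <- 0
  for (f in faces) {
    A <- X[f$v[1], ] - c0; B <- X[f$v[2], ] - c0; C <- X[f$v[3], ] - c0
    vol <- vol + abs(A[1] * (B[2] * C[3] - B[3] * C[2]) -
                     A[2] * (B[1] * C[3] - B[3] * C[1]) +
                     A[3] * (B[1] * C[2] - B[2] * C[1])) / 6
  }
  list(volume = as.numeric(unname(vol)), faces = matrix(as.integer(F), ncol = 3),
       normals = N, offsets = O,
       vertices = sort(unique(as.integer(F))), degenerate = FALSE)
}

#' Convex-hull volume of a point cloud
#'
#' @inheritParams convexHull3d
#' @return volume in nm^3 (0 for degenerate clouds)
#' @export
convexHullVolume <- function(X, tol = 1e-9) convexHull3d(X, tol)$volume

#' Test points for hull membership
#'
#' @param hull result of [convexHull3d()]
#' @param P m x 3 matrix of query points
#' @param eps slack on the facet planes (nm)
#' @return logical vector, TRUE where the point is inside (or on) the hull
#' @export
inHull <- function(hull, P, eps = 1e-9) {
  if (hull$degenerate) return(rep(FALSE, nrow(P)))
  S <- P %*% t(hull$normals)
  colSums(t(S) <= hull$offsets + eps) == nrow(hull$normals)
}
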