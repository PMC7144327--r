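# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Derive a stream seed from a base seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 99991 * stream) %% 2147483629)
}

# Squared Euclidean cross-distances between row sets A (n x 3) and B (m x 3).
crossDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Fixed-radius neighbour lists via uniform-grid bucketing.
# Returns, for every row of X, the indices of all points (self included)
# within Euclidean distance <= r.
neighborLists <- function(X, r) {
  n <- nrow(X)
  if (n == 0L) return(list())
  X <- as.matrix(X)
  g <- floor(sweep(X, 2, apply(X, 2, min)) / r)
  dims <- apply(g, 2, max) + 1
  key <- g[, 1] + dims[1] * (g[, 2] + dims[2] * g[, 3])
  cells <- split(seq_len(n), key)
  ckey <- as.numeric(names(cells))
  # integer cell coordinates recovered from the first member of each cell
  first <- vapply(cells, `[`, integer(1), 1L)
  ci <- g[first, , drop = FALSE]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  r2 <- r * r
  out <- vector("list", n)
  for (ic in seq_along(cells)) {
    nb_keys <- (ci[ic, 1] + off[, 1]) +
      dims[1] * ((ci[ic, 2] + off[, 2]) + dims[2] * (ci[ic, 3] + off[, 3]))
    valid <- ci[ic, 1] + off[, 1] >= 0 & ci[ic, 1] + off[, 1] < dims[1] &
             ci[ic, 2] + off[, 2] >= 0 & ci[ic, 2] + off[, 2] < dims[2] &
             ci[ic, 3] + off[, 3] >= 0 & ci[ic, 3] + off[, 3] < dims[3]
    hit <- match(nb_keys[valid], ckey)
    cand <- sort(unlist(cells[hit[!is.na(hit)]], use.names = FALSE))
    mem <- cells[[ic]]
    d2 <- crossDist2(X[mem, , drop = FALSE], X[cand, , drop = FALSE])
    for (k in seq_along(mem))
      out[[mem[k]]] <- cand[d2[k, ] <= r2]
  }
  out
}

# For each row of S, distance to the nearest row of Tg, provided it is
# <= cutoff; NA otherwise. Grid-accelerated, exact within the cutoff.
nearestWithinCutoff <- function(S, Tg, cutoff) {
  nS <- nrow(S)
  if (nS == 0L) return(numeric(0))
  res <- rep(NA_real_, nS)
  if (nrow(Tg) == 0L) return(res)
  lo <- pmin(apply(S, 2, min), apply(Tg, 2, min))
  gS <- floor(sweep(S, 2, lo) / cutoff)
  gT <- floor(sweep(Tg, 2, lo) / cutoff)
  dims <- pmax(apply(gS, 2, max), apply(gT, 2, max)) + 1
  keyf <- function(g) g[, 1] + dims[1] * (g[, 2] + dims[2] * g[, 3])
  tcells <- split(seq_len(nrow(Tg)), keyf(gT))
  tckey <- as.numeric(names(tcells))
  scells <- split(seq_len(nS), keyf(gS))
  first <- vapply(scells, `[`, integer(1), 1L)
  ci <- gS[first, , drop = FALSE]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  c2 <- cutoff * cutoff
  for (ic in seq_along(scells)) {
    cc <- sweep(off, 2, as.numeric(ci[ic, ]), "+")
    valid <- cc[, 1] >= 0 & cc[, 1] < dims[1] & cc[, 2] >= 0 &
             cc[, 2] < dims[2] & cc[, 3] >= 0 & cc[, 3] < dims[3]
    hit <- match(cc[valid, 1] + dims[1] * (cc[valid, 2] + dims[2] * cc[valid, 3]),
                 tckey)
    cand <- unlist(tcells[hit[!is.na(hit)]], use.names = FALSE)
    if (!length(cand)) next
    mem <- scells[[ic]]
    d2 <- crossDist2(S[mem, , drop = FALSE], Tg[cand, , drop = FALSE])
    dmin <- apply(d2, 1, min)
    ok <- dmin <= c2
    res[mem[ok]] <- sqrt(dmin[ok])
  }
  res
}

# Polynomial rolling hash of a character string, 8 hex digits
# (config provenance in output files).
contentHash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Canonical number formatting for the CSV dialect (6 dp, "." separator).
fmt6 <- function(x) sprintf("%.6f", x)

# Orthonormal basis perpendicular to a unit vector.
perpBasis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  rbind(e1, e2)
}
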