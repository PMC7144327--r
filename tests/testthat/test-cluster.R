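randomInstance <- function(seed, n_max = 300) {
  set.seed(seed)
  n_cl <- sample(1:4, 1)
  pts <- list()
  for (k in seq_len(n_cl)) {
    m <- sample(20:80, 1)
    ctr <- runif(3, 0, 3000)
    pts[[k]] <- sweep(matrix(rnorm(3 * m, 0, runif(1, 20, 60)), m, 3),
                      2, ctr, "+")
  }
  noise <- matrix(runif(3 * sample(10:60, 1), 0, 3000), ncol = 3)
  X <- rbind(do.call(rbind, pts), noise)
  X[sample(nrow(X)), , drop = FALSE][seq_len(min(n_max, nrow(X))), ,
                                     drop = FALSE]
}

test_that("a dense ball plus isolated points clusters as one cluster", {
  set.seed(1)
  ball <- matrix(rnorm(180, 0, 25), 60, 3)
  ball <- ball[sqrt(rowSums(ball^2)) <= 50, , drop = FALSE]
  while (nrow(ball) < 60) {
    p <- rnorm(3, 0, 25)
    if (sqrt(sum(p^2)) <= 50) ball <- rbind(ball, p)
  }
  iso <- cbind(runif(10, 2000, 8000), runif(10, 2000, 8000),
               runif(10, 2000, 8000))
  iso <- iso[1:10, ]
  X <- rbind(ball[1:60, ], iso)
  lab <- dbscan(X, eps = 100, min_pts = 50)
  expect_equal(sum(lab == 0L), 60L)
  expect_equal(sum(lab == -1L), 10L)
  expect_identical(lab, bruteDbscan(X, 100, 50))
})

test_that("empty input yields an empty labelling", {
  expect_equal(dbscan(matrix(numeric(0), 0, 3)), integer(0))
})

test_that("min_pts is a sharp threshold on mutually-close points", {
  set.seed(2)
  mk <- function(n) matrix(runif(3 * n, 0, 40), n, 3)  # all within eps
  X49 <- mk(49)
  expect_true(all(dbscan(X49, 100, 50) == -1L))
  expect_identical(dbscan(X49, 100, 50), bruteDbscan(X49, 100, 50))
  X50 <- mk(50)
  expect_true(all(dbscan(X50, 100, 50) == 0L))
  expect_identical(dbscan(X50, 100, 50), bruteDbscan(X50, 100, 50))
})

test_that("grid DBSCAN equals the brute-force oracle on random instances", {
  for (seed in 1:25) {
    X <- randomInstance(seed)
    eps <- sample(c(60, 80, 100), 1)
    mp <- sample(c(5, 10, 20), 1)
    expect_identical(dbscan(X, eps, mp), bruteDbscan(X, eps, mp),
                     info = paste("seed", seed))
  }
})

test_that("every reported cluster has at least min_pts members", {
  for (seed in 26:35) {
    X <- randomInstance(seed)
    lab <- dbscan(X, 80, 15)
    if (any(lab >= 0))
      expect_true(all(table(lab[lab >= 0]) >= 15))
  }
})

test_that("permuting the input permutes labels but not the partition", {
  X <- randomInstance(40)
  lab <- dbscan(X, 80, 10)
  set.seed(40)
  perm <- sample(nrow(X))
  labp <- dbscan(X[perm, , drop = FALSE], 80, 10)
  # map permuted labels back to original indexing
  back <- integer(nrow(X)); back[perm] <- seq_len(nrow(X))
  p1 <- partitionOf(lab)
  p2 <- lapply(partitionOf(labp), function(s) sort(perm[s]))
  p2 <- p2[order(vapply(p2, `[`, integer(1), 1L))]
  expect_equal(p1, p2)
  expect_equal(sort(which(lab == -1L)), sort(perm[which(labp == -1L)]))
})

test_that("cluster morphometry reports counts, centroids, hulls, densities", {
  tet <- rbind(c(0, 0, 0), c(300, 0, 0), c(0, 300, 0), c(0, 0, 300))
  d <- data.frame(channel = "bassoon", frame = 0L,
                  x_nm = tet[, 1], y_nm = tet[, 2], z_nm = tet[, 3],
                  photons = 1000, bg = 5, sigma_xy_nm = 10, sigma_z_nm = 25)
  tb <- localizationTable(d, list(channels = "bassoon"))
  cs <- summarizeClusters(tb, labels = rep(0L, 4), min_pts = 4)
  s <- clusterSummary(cs)
  expect_equal(s$n_locs, 4L)
  expect_equal(s$hull_volume_nm3, 300^3 / 6)
  expect_equal(unlist(s[, c("cx_nm", "cy_nm", "cz_nm")]),
               c(cx_nm = 75, cy_nm = 75, cz_nm = 75))
  expect_equal(s$density_per_um3, 4 / (4.5e6 / 1e9))
})

test_that("a coplanar cluster has zero hull volume and undefined density", {
  set.seed(3)
  d <- data.frame(channel = "bassoon", frame = 0L,
                  x_nm = runif(20, 0, 100), y_nm = runif(20, 0, 100),
                  z_nm = 50, photons = 1000, bg = 5, sigma_xy_nm = 10,
                  sigma_z_nm = 25)
  tb <- localizationTable(d, list(channels = "bassoon"))
  s <- clusterSummary(summarizeClusters(tb, labels = rep(0L, 20)))
  expect_equal(s$hull_volume_nm3, 0)
  expect_true(is.na(s$density_per_um3))
})
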