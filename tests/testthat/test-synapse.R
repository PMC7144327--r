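clusterSetFromCentroids <- function(P, channel = "bassoon") {
  s <- data.frame(cluster_id = seq_len(nrow(P)) - 1L, channel = channel,
                  n_locs = 50L, cx_nm = P[, 1], cy_nm = P[, 2],
                  cz_nm = P[, 3], hull_volume_nm3 = 1e6,
                  density_per_um3 = 50)
  new("ClusterSet", summary = s,
      members = lapply(seq_len(nrow(P)), function(i) i),
      hulls = vector("list", nrow(P)),
      params = list(eps = 100, min_pts = 50L))
}

test_that("one opposed pair is paired with midpoint centre and axis", {
  pre <- clusterSetFromCentroids(rbind(c(0, 0, 0)))
  post <- clusterSetFromCentroids(rbind(c(400, 0, 0)), "Homer1")
  p <- pairSynapses(pre, post)
  expect_equal(nrow(p), 1L)
  expect_equal(unlist(p[, c("cx_nm", "cy_nm", "cz_nm")]),
               c(cx_nm = 200, cy_nm = 0, cz_nm = 0))
  expect_equal(unlist(p[, c("ax", "ay", "az")]),
               c(ax = 1, ay = 0, az = 0))
  expect_equal(p$center_distance_nm, 400)
})

test_that("clusters farther than the cutoff are not paired", {
  pre <- clusterSetFromCentroids(rbind(c(0, 0, 0)))
  post <- clusterSetFromCentroids(rbind(c(600, 0, 0)), "Homer1")
  expect_equal(nrow(pairSynapses(pre, post)), 0L)
})

test_that("greedy matching is one-to-one, nearest first", {
  pre <- clusterSetFromCentroids(rbind(c(0, 0, 0)))
  post <- clusterSetFromCentroids(rbind(c(300, 0, 0), c(350, 0, 0)),
                                  "Homer1")
  p <- pairSynapses(pre, post)
  expect_equal(nrow(p), 1L)
  expect_equal(p$post_cluster, 0L)
  expect_equal(p$center_distance_nm, 300)
})

test_that("greedy matching equals the exhaustive greedy oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    nP <- sample(2:10, 1); nQ <- sample(2:10, 1)
    P <- matrix(runif(3 * nP, 0, 2000), nP, 3)
    Q <- matrix(runif(3 * nQ, 0, 2000), nQ, 3)
    p <- pairSynapses(clusterSetFromCentroids(P),
                      clusterSetFromCentroids(Q, "Homer1"))
    oracle <- bruteGreedyPairs(P, Q, 500)
    if (is.null(oracle)) {
      expect_equal(nrow(p), 0L)
    } else {
      expect_equal(nrow(p), nrow(oracle))
      expect_equal(p$pre_cluster + 1L, oracle[, 1])
      expect_equal(p$post_cluster + 1L, oracle[, 2])
      expect_true(!anyDuplicated(p$pre_cluster) &&
                  !anyDuplicated(p$post_cluster))
    }
  }
})

locTable <- function(P, channel = "bassoon") {
  localizationTable(data.frame(
    channel = channel, frame = 0L, x_nm = P[, 1], y_nm = P[, 2],
    z_nm = P[, 3], photons = 1000, bg = 5, sigma_xy_nm = 10,
    sigma_z_nm = 25), list(channels = channel))
}

test_that("a single trans-synaptic pair yields its geometric distance", {
  ds <- nnDistances(locTable(rbind(c(0, 0, 0))),
                    locTable(rbind(c(120, 0, 0)), "Homer1"))
  expect_equal(distancesNm(ds), 120)
  expect_equal(histogramMode(ds), 125)  # bin [120, 130)
})

test_that("targets beyond the cutoff are discarded", {
  ds <- nnDistances(locTable(rbind(c(0, 0, 0))),
                    locTable(rbind(c(501, 0, 0)), "Homer1"))
  expect_equal(length(distancesNm(ds)), 0L)
  ds2 <- nnDistances(locTable(rbind(c(0, 0, 0))),
                     locTable(rbind(c(500, 0, 0)), "Homer1"))
  expect_equal(distancesNm(ds2), 500)
})

test_that("grid NN distances equal the brute-force oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    S <- matrix(runif(900, 0, 3000), 300, 3)
    Tg <- matrix(runif(900, 0, 3000), 300, 3)
    ds <- nnDistances(locTable(S), locTable(Tg, "Homer1"))
    expect_equal(sort(distancesNm(ds)), sort(bruteNN(S, Tg, 500)),
                 tolerance = 1e-12)
  }
})

test_that("histogram mode picks the most populated bin, ties lowest", {
  ds <- distancesToSet(c(119, 121, 121, 400))
  expect_equal(histogramMode(ds), 125)
  expect_equal(histogramMode(distancesToSet(7)), 5)
  # tie between [0,10) and [10,20) resolves to the lower bin
  expect_equal(histogramMode(distancesToSet(c(5, 15))), 5)
  expect_error(histogramMode(distancesToSet(numeric(0))), "empty")
})

test_that("perisynaptic distances respect the search radius", {
  pre <- clusterChannelFixture(c(0, 0, 0))
  post <- clusterChannelFixture(c(120, 0, 0), "Homer1")
  pairs <- pairSynapses(pre$clusters, post$clusters)
  centre <- unlist(pairs[1, c("cx_nm", "cy_nm", "cz_nm")])
  glt <- locTable(rbind(centre, centre + c(600, 0, 0)), "GLT1")
  peri <- perisynapticDistances(glt, pairs, pre, post)
  expect_equal(length(distancesNm(peri$glt1_to_center)), 1L)
  expect_equal(distancesNm(peri$glt1_to_center), 0)
  expect_true(all(distancesNm(peri$glt1_to_center) <= 500))
})

test_that("a localisation in range of several synapses contributes to each", {
  pre <- clusterChannelFixture(rbind(c(-300, 0, 0), c(300, 0, 0)))
  post <- clusterChannelFixture(rbind(c(-300, 120, 0), c(300, 120, 0)),
                                "Homer1")
  pairs <- pairSynapses(pre$clusters, post$clusters)
  expect_equal(nrow(pairs), 2L)
  glt <- locTable(rbind(c(0, 60, 0)), "GLT1")
  peri <- perisynapticDistances(glt, pairs, pre, post)
  expect_equal(length(distancesNm(peri$glt1_to_center)), 2L)
  peri1 <- perisynapticDistances(glt, pairs, pre, post,
                                 nearest_synapse_only = TRUE)
  expect_equal(length(distancesNm(peri1$glt1_to_center)), 1L)
})
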