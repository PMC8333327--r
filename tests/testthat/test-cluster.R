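blob_distance <- function(n1 = 4, n2 = 4, sep = 10, seed = 1) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(n1 * 2, 0, 0.5), ncol = 2),
               matrix(rnorm(n2 * 2, sep, 0.5), ncol = 2))
  as.matrix(dist(pts))
}

test_that("PAM reaches the exhaustive optimum on two planted blobs", {
  D <- blob_distance()
  pam <- pam_cluster(D, 2, seed = 1)
  expect_equal(pam$cost, pam_oracle(D, 2), tolerance = 1e-12)
  expect_equal(unname(pam$assignment), rep(1:2, each = 4))
})

test_that("accepted swaps never increase the cost", {
  set.seed(4)
  pts <- matrix(rnorm(24), ncol = 2)
  D <- as.matrix(dist(pts))
  pam <- pam_cluster(D, 3, seed = 2)
  expect_true(all(diff(pam$cost_trace) <= 1e-12))
  expect_equal(pam$cost,
               sum(apply(D[, pam$medoids, drop = FALSE], 1, min)),
               tolerance = 1e-12)
  # medoids belong to their own clusters
  expect_equal(unname(pam$assignment[pam$medoids]),
               seq_along(pam$medoids))
})

test_that("PAM input contracts and k = n-1 structure", {
  D <- blob_distance(3, 3)
  expect_error(pam_cluster(D, 6), class = "zoopcurves_input_error")
  expect_error(pam_cluster(D, 1), class = "zoopcurves_input_error")
  pam <- pam_cluster(D, 5, seed = 3)
  sizes <- table(pam$assignment)
  expect_equal(sort(as.integer(sizes)), c(1L, 1L, 1L, 1L, 2L))
  # determinism under seed
  expect_identical(pam_cluster(D, 2, seed = 7)$medoids,
                   pam_cluster(D, 2, seed = 7)$medoids)
})

test_that("silhouette agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  D <- blob_distance(5, 4, sep = 4, seed = 2)
  pam <- pam_cluster(D, 2, seed = 1)
  vi <- validity_indices(D, pam$assignment)
  ref <- cluster::silhouette(unname(pam$assignment), dmatrix = D)
  expect_equal(vi$mean_silhouette, mean(ref[, "sil_width"]),
               tolerance = 1e-10)
})

test_that("validity indices hit their degenerate closed forms", {
  # two internally identical, mutually distinct clusters
  pts <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  D <- as.matrix(dist(pts))
  cl <- rep(1:2, each = 3)
  vi <- validity_indices(D, cl, coords = pts)
  expect_equal(vi$mean_silhouette, 1)
  expect_equal(vi$davies_bouldin, 0)
  expect_equal(vi$davies_bouldin_modified, 0)
  expect_true(is.infinite(vi$dunn))

  # tight distant clusters dominate a random split of one cluster
  D2 <- blob_distance(6, 6, sep = 20, seed = 3)
  good <- rep(1:2, each = 6)
  bad <- c(rep(1, 3), rep(2, 3), rep(2, 6))  # splits blob 1 randomly
  dunn_good <- validity_indices(D2, good)$dunn
  dunn_bad <- validity_indices(D2[1:6, 1:6], c(1, 1, 1, 2, 2, 2))$dunn
  expect_gte(dunn_good, 10 * dunn_bad)
  expect_error(validity_indices(D2, rep(1, 12)),
               class = "zoopcurves_input_error")
})

test_that("the index vote picks the planted k and obeys the tie rule", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(10, 0, 0.3), ncol = 2),
               matrix(rnorm(10, 8, 0.3), ncol = 2),
               matrix(c(rnorm(5, 0, 0.3), rnorm(5, 8, 0.3)), ncol = 2))
  D <- as.matrix(dist(pts))
  ck <- choose_k(D, k_range = 2:6, seed = 11)
  expect_equal(ck$k, 3)
  expect_gte(sum(ck$votes == 3), 3)  # clear majority for the planted k
  # unanimity trivially implies the common k
  expect_equal(zoopcurves:::vote_plurality(rep(4L, 5)), 4)
  # stated plurality tie rule
  expect_equal(zoopcurves:::vote_plurality(c(3, 3, 4, 4, 5)), 3)
  expect_equal(zoopcurves:::vote_plurality(c(4, 4, 4, 2, 2)), 4)
  expect_equal(zoopcurves:::vote_plurality(c(2, 3, 4, 5, 6)), 2)
})

test_that("classical MDS reproduces collinear geometry exactly", {
  x <- c(0, 1, 3)
  D <- as.matrix(dist(x))
  mds <- classical_mds(D, dim = 2)
  rec <- as.matrix(dist(mds$points))
  expect_equal(rec, D, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mds$n_clipped, 0)
})

test_that("Euclidean configurations embed with vanishing stress", {
  set.seed(6)
  pts <- matrix(rnorm(20), ncol = 2)
  D <- as.matrix(dist(pts))
  mds <- classical_mds(D, dim = 2)
  expect_lt(max(abs(as.matrix(dist(mds$points)) - D)), 1e-8)
  # against the reference implementation (up to reflection/rotation)
  ref <- stats::cmdscale(D, k = 2)
  expect_equal(as.matrix(dist(mds$points)), as.matrix(dist(ref)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("non-Euclidean distances get their negative eigenvalues clipped", {
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 2  # star geometry: not embeddable exactly
  mds <- classical_mds(D, dim = 2)
  expect_gte(mds$n_clipped, 1)
  # all-zero distances give a degenerate embedding at the origin
  mds0 <- classical_mds(matrix(0, 3, 3), dim = 2)
  expect_true(all(abs(mds0$points) < 1e-10))
})
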