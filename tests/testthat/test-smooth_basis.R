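test_that("knot grids are equally spaced with the documented extension", {
  kv <- build_knots(c(0, 1), n_segments = 4L, degree = 0L)
  expect_equal(kv$knots, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(kv$d, 4L)

  kv <- build_knots(runif(50), n_segments = 20L, degree = 3L)
  expect_equal(kv$d, 23L)
  expect_equal(length(kv$knots), 20 + 1 + 2 * 3)
  expect_equal(diff(kv$knots), rep(kv$spacing, length(kv$knots) - 1),
               tolerance = 1e-12)

  kv <- build_knots(c(6, 59), n_segments = 10L, degree = 3L)
  expect_equal(kv$spacing, 5.3)

  expect_error(build_knots(rep(2, 5), 4, 3, name = "child_age"), "child_age")
  expect_error(build_knots(c(0, 1), n_segments = 0L), "n_segments")
})

test_that("B-spline design matches an independent Cox-de Boor recursion", {
  set.seed(11)
  for (degree in 0:3) {
    x <- runif(250, 2, 7)
    x <- c(2, x, 7)  # include both boundaries
    kv <- build_knots(x, n_segments = 7L, degree = degree)
    B <- bspline_design(x, kv)
    expect_equal(dim(B), c(length(x), kv$d))
    O <- deboor_design(x, kv$knots, degree)
    expect_lt(max(abs(B - O)), 1e-12)
  }
})

test_that("basis rows are a partition of unity across the knot range", {
  set.seed(12)
  kv <- build_knots(c(-1, 3), n_segments = 20L, degree = 3L)
  x <- c(-1, 3, runif(10000, -1, 3))
  B <- bspline_design(x, kv)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  expect_true(all(B >= 0 & B <= 1))
})

test_that("degree-0 basis is the right-closed indicator basis", {
  kv <- build_knots(c(0, 2), n_segments = 2L, degree = 0L)
  B <- bspline_design(c(0.5, 1, 2), kv)
  expect_equal(B[1, ], c(1, 0))  # x in [0,1)
  expect_equal(B[2, ], c(0, 1))  # right-continuous at interior knot
  expect_equal(B[3, ], c(0, 1))  # maximum representable
})

test_that("evaluation outside the knot range is an error", {
  kv <- build_knots(c(0, 1), n_segments = 4L, degree = 3L)
  expect_error(bspline_design(c(0.5, 1.2), kv), "outside")
  expect_error(bspline_design(-0.1, kv), "outside")
})

test_that("difference penalties are D'D with the right rank and null space", {
  K1 <- difference_penalty(3, 1)
  expect_equal(K1$matrix,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, byrow = TRUE))
  expect_equal(K1$rank, 2L)

  for (d in c(5, 9, 23)) {
    K <- difference_penalty(d, 1)
    expect_lt(max(abs(K$matrix %*% rep(1, d))), 1e-12)
  }

  K2 <- difference_penalty(5, 2)
  ev <- eigen(K2$matrix, symmetric = TRUE)$values
  expect_equal(sum(ev > 1e-10), 3L)  # rank d - order
  expect_equal(K2$rank, 3L)
  expect_lt(max(abs(K2$matrix %*% rep(1, 5))), 1e-12)
  expect_lt(max(abs(K2$matrix %*% seq_len(5))), 1e-12)

  expect_error(difference_penalty(5, 3), "order")
  expect_error(difference_penalty(5, 0), "order")
})

test_that("tensor design is the row-wise Kronecker product", {
  B1 <- matrix(c(1, 0), 1)
  B2 <- matrix(c(0, 1), 1)
  expect_equal(as.numeric(tensor_design(B1, B2)), c(0, 1, 0, 0))

  set.seed(13)
  n <- 5
  x1 <- runif(n); x2 <- runif(n)
  kv <- build_knots(c(0, 1), n_segments = 3L, degree = 3L)  # d = 6
  M1 <- bspline_design(x1, kv)
  M2 <- bspline_design(x2, kv)
  TD <- tensor_design(M1, M2)
  expect_equal(dim(TD), c(5L, 36L))
  expect_lt(max(abs(rowSums(TD) - 1)), 1e-10)
  # brute-force double loop oracle
  O <- matrix(0, n, 36)
  for (r in seq_len(n)) {
    for (i in 1:6) for (j in 1:6) O[r, (i - 1) * 6 + j] <- M1[r, i] * M2[r, j]
  }
  expect_equal(TD, O, ignore_attr = TRUE)

  expect_error(tensor_design(M1, M2[1:3, ]), "mismatch")
})

test_that("the Kronecker-sum penalty annihilates exactly the tensor null space", {
  K1 <- difference_penalty(4, 1)
  K2 <- difference_penalty(5, 1)
  KT <- tensor_penalty(K1, K2)
  expect_equal(KT$rank, 4 * 5 - 1)
  ev <- eigen(KT$matrix, symmetric = TRUE)$values
  expect_equal(sum(ev < 1e-10), 1L)          # only the constant surface
  expect_lt(max(abs(KT$matrix %*% rep(1, 20))), 1e-12)

  # RW2 x RW2: null space = (const+linear) x (const+linear), dim 4
  KT2 <- tensor_penalty(difference_penalty(4, 2), difference_penalty(5, 2))
  ev2 <- eigen(KT2$matrix, symmetric = TRUE)$values
  expect_equal(sum(ev2 < 1e-10), 4L)
  expect_equal(KT2$rank, 16L)
})

test_that("k-nearest-neighbour graphs match geometry and a brute-force oracle", {
  # three collinear equidistant points, k = 1
  cents <- data.frame(region_id = c("a", "b", "c"),
                      lon = c(0, 1, 2), lat = c(10, 10, 10))
  A <- knn_adjacency(cents, k = 1)
  expect_equal(sum(A), 4)  # edges (a,b) and (b,c), symmetric
  expect_equal(A["a", "b"], 1L)
  expect_equal(A["b", "c"], 1L)
  expect_equal(A["a", "c"], 0L)

  # 6x6 lattice, k = 4: deep-interior nodes have exactly the rook neighbours
  geo <- make_geography(6L)
  A <- knn_adjacency(geo$centroids, k = 4)
  ids <- matrix(geo$centroids$region_id, 6, 6, byrow = TRUE)  # row-major
  for (r in 3:4) for (cc in 3:4) {
    nb <- names(which(A[ids[r, cc], ] == 1))
    expect_setequal(nb, c(ids[r - 1, cc], ids[r + 1, cc],
                          ids[r, cc - 1], ids[r, cc + 1]))
  }

  # random centroids vs exhaustive pairwise-sort oracle
  set.seed(14)
  cents <- data.frame(region_id = sprintf("r%02d", 1:36),
                      lon = runif(36, 70, 90), lat = runif(36, 10, 30))
  A <- knn_adjacency(cents, k = 4)
  D <- geosphere::distm(as.matrix(cents[, c("lon", "lat")]))
  O <- matrix(0L, 36, 36)
  for (i in 1:36) {
    nn <- setdiff(order(D[i, ]), i)[1:4]
    O[i, nn] <- 1L
  }
  O <- pmax(O, t(O))
  expect_equal(unname(A), O)

  cents$lon[2] <- cents$lon[1]; cents$lat[2] <- cents$lat[1]
  expect_error(knn_adjacency(cents, k = 4), "r01.*r02|duplicate")
})

test_that("MRF precision is the graph Laplacian with component-deficient rank", {
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  L <- mrf_precision(path3)
  expect_equal(L$matrix,
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, byrow = TRUE))
  expect_equal(L$rank, 2L)

  set.seed(15)
  cents <- data.frame(region_id = sprintf("r%02d", 1:20),
                      lon = runif(20, 70, 90), lat = runif(20, 10, 30))
  A <- knn_adjacency(cents, k = 3)
  L <- mrf_precision(A)
  expect_lt(max(abs(L$matrix %*% rep(1, 20))), 1e-12)

  # two disconnected dyads: rank 4 - 2 components = 2
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1
  L <- mrf_precision(dyads)
  expect_equal(L$rank, 2L)
  ev <- eigen(L$matrix, symmetric = TRUE)$values
  expect_equal(sum(ev > 1e-10), 2L)

  expect_error(mrf_precision(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("spatial basis modes expose the documented shapes", {
  geo <- make_geography(6L)
  sb <- spatial_basis(geo$centroids, mode = "tensor", k_segments = 8L)
  expect_equal(dim(sb$design), c(36L, 121L))  # (8+3)^2 coefficients
  expect_lt(max(abs(rowSums(sb$design) - 1)), 1e-10)
  expect_equal(sb$penalty$rank, 120L)

  sb <- spatial_basis(geo$centroids, mode = "mrf")
  expect_equal(dim(sb$design), c(36L, 36L))
  expect_equal(sb$penalty$rank, 35L)
})
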