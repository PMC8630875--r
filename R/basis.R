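#' Equally spaced knot vector for a P-spline basis
#'
#' Places `n_segments + 1` equally spaced knots spanning the observed range of
#' a covariate and extends the grid by `degree` further knots at the same
#' spacing on each side. The extension (rather than clamped boundary knots)
#' keeps the penalized coefficients exchangeable under a random-walk prior.
#' The implied basis dimension is `d = n_segments + degree`.
#'
#' @param values numeric covariate values; the knot span is `[min, max]`.
#' @param n_segments number of interior segments (>= 1).
#' @param degree polynomial degree of the B-spline basis (>= 0; cubic default).
#' @param name covariate label used in error messages.
#' @return an object of class `knot_vector` with fields `lower`, `upper`,
#'   `n_segments`, `degree`, `spacing`, `knots` and `d`.
#' @export
build_knots <- function(values, n_segments = 20L, degree = 3L,
                        name = deparse(substitute(values))) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values for covariate '", name, "'")
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) {
    stop("covariate '", name, "' is degenerate: min equals max (", lo, ")")
  }
  n_segments <- as.integer(n_segments)
  degree <- as.integer(degree)
  if (n_segments < 1L) stop("n_segments must be >= 1")
  if (degree < 0L) stop("degree must be >= 0")
  h <- (hi - lo) / n_segments
  knots <- lo + h * seq.int(-degree, n_segments + degree)
  structure(
    list(lower = lo, upper = hi, n_segments = n_segments, degree = degree,
         spacing = h, knots = knots, d = n_segments + degree),
    class = "knot_vector"
  )
}

#' @export
print.knot_vector <- function(x, ...) {
  cat(sprintf(
    "knot_vector: degree %d, %d segments on [%g, %g] (spacing %g, d = %d)\n",
    x$degree, x$n_segments, x$lower, x$upper, x$spacing, x$d))
  invisible(x)
}

#' B-spline design matrix
#'
#' Evaluates the `d = n_segments + degree` B-spline basis functions of a
#' [build_knots()] grid at the supplied points. Rows form a partition of unity
#' on `[lower, upper]`; the final knot is right-closed so the covariate
#' maximum is representable. Points outside the range are an error (no silent
#' extrapolation).
#'
#' @param x numeric evaluation points inside the knot range.
#' @param kv a `knot_vector`.
#' @return numeric matrix, `length(x)` by `kv$d`.
#' @export
bspline_design <- function(x, kv) {
  stopifnot(inherits(kv, "knot_vector"))
  if (anyNA(x)) stop("NA values in spline evaluation points")
  if (any(x < kv$lower | x > kv$upper)) {
    bad <- range(x[x < kv$lower | x > kv$upper])
    stop(sprintf(
      "evaluation points outside knot range [%g, %g] (offending range %g..%g)",
      kv$lower, kv$upper, bad[1], bad[2]))
  }
  splines::splineDesign(knots = kv$knots, x = x, ord = kv$degree + 1L,
                        outer.ok = FALSE)
}

#' Random-walk difference penalty
#'
#' Builds the penalty matrix `K = t(D) %*% D` where `D` is the order-th
#' forward-difference operator on `d` coefficients. `K` is the prior precision
#' (up to a smoothing variance) of a first- or second-order random walk; its
#' null space holds polynomials of degree below `order`, so `rank = d - order`.
#'
#' @param d number of basis coefficients (`d > order`).
#' @param order random-walk order, 1 or 2.
#' @return object of class `penalty_matrix` with fields `order`, `matrix`,
#'   `rank`.
#' @export
difference_penalty <- function(d, order = 2L) {
  d <- as.integer(d)
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) {
    stop("random-walk order must be 1 or 2, got ", order)
  }
  if (d <= order) stop("need d > order, got d = ", d, ", order = ", order)
  D <- diff(diag(d), differences = order)
  structure(
    list(order = order, matrix = crossprod(D), rank = d - order),
    class = "penalty_matrix"
  )
}

#' Row-wise tensor product of two marginal design matrices
#'
#' For each row `r`, returns `B1[r, ] %x% B2[r, ]` — the design of a
#' two-dimensional tensor-product spline evaluated at the paired coordinates
#' in row `r`. Column `(i - 1) * ncol(B2) + j` multiplies marginal basis `i`
#' of `B1` with basis `j` of `B2`. When both marginals are partitions of
#' unity, so is every tensor row.
#'
#' @param B1,B2 design matrices with equal row counts.
#' @return matrix with `nrow(B1)` rows and `ncol(B1) * ncol(B2)` columns.
#' @export
tensor_design <- function(B1, B2) {
  if (nrow(B1) != nrow(B2)) {
    stop("row-count mismatch: ", nrow(B1), " vs ", nrow(B2))
  }
  d1 <- ncol(B1)
  d2 <- ncol(B2)
  B1[, rep(seq_len(d1), each = d2), drop = FALSE] *
    B2[, rep(seq_len(d2), times = d1), drop = FALSE]
}

#' Kronecker-sum penalty for a tensor-product smooth
#'
#' `K1 %x% I + I %x% K2`, matching the column ordering of [tensor_design()].
#' Its null space is the tensor product of the marginal null spaces, so with
#' first-order random-walk marginals only the constant surface is unpenalized.
#'
#' @param K1,K2 marginal `penalty_matrix` objects (or plain matrices).
#' @return object of class `penalty_matrix` (order `NA`), rank
#'   `d1 * d2 - null1 * null2`.
#' @export
tensor_penalty <- function(K1, K2) {
  m1 <- if (inherits(K1, "penalty_matrix")) K1$matrix else K1
  m2 <- if (inherits(K2, "penalty_matrix")) K2$matrix else K2
  d1 <- ncol(m1)
  d2 <- ncol(m2)
  null1 <- if (inherits(K1, "penalty_matrix")) d1 - K1$rank else d1 - qr(m1)$rank
  null2 <- if (inherits(K2, "penalty_matrix")) d2 - K2$rank else d2 - qr(m2)$rank
  structure(
    list(order = NA_integer_,
         matrix = kronecker(m1, diag(d2)) + kronecker(diag(d1), m2),
         rank = d1 * d2 - null1 * null2),
    class = "penalty_matrix"
  )
}

#' k-nearest-neighbour adjacency between region centroids
#'
#' Connects each region to its `k` nearest neighbours by great-circle
#' (haversine) distance on longitude/latitude, then symmetrises by union.
#' Ties in distance are broken by region order, deterministically.
#'
#' @param centroids data frame with columns `region_id`, `lon`, `lat`
#'   (decimal degrees, WGS84 assumed).
#' @param k number of nearest neighbours (default 4).
#' @return symmetric 0/1 adjacency matrix with region ids as dimnames.
#' @export
knn_adjacency <- function(centroids, k = 4L) {
  stopifnot(all(c("region_id", "lon", "lat") %in% names(centroids)))
  n <- nrow(centroids)
  if (n < k + 1L) stop("need at least k + 1 = ", k + 1L, " regions, got ", n)
  dup <- duplicated(centroids[, c("lon", "lat")]) |
    duplicated(centroids[, c("lon", "lat")], fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate centroids for regions: ",
         paste(centroids$region_id[dup], collapse = ", "))
  }
  D <- geosphere::distm(as.matrix(centroids[, c("lon", "lat")]),
                        fun = geosphere::distHaversine)
  diag(D) <- Inf
  A <- matrix(0L, n, n, dimnames = list(centroids$region_id,
                                        centroids$region_id))
  for (i in seq_len(n)) {
    nn <- order(D[i, ], seq_len(n))[seq_len(k)]  # tie-break by region order
    A[i, nn] <- 1L
  }
  A <- pmax(A, t(A))  # union symmetrisation
  diag(A) <- 0L
  A
}

#' Markov random field precision (graph Laplacian)
#'
#' The intrinsic Gaussian MRF prior on region effects has precision equal to
#' the Laplacian of the neighbourhood graph: diagonal = neighbour counts,
#' off-diagonal = -1 for neighbours. Row sums are zero and the rank is
#' `n - (number of connected components)`.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @return object of class `penalty_matrix` (order 1 by convention).
#' @export
mrf_precision <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal")
  L <- diag(rowSums(adjacency)) - adjacency
  dimnames(L) <- dimnames(adjacency)
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  ncomp <- igraph::components(g)$no
  structure(
    list(order = 1L, matrix = L, rank = nrow(L) - ncomp),
    class = "penalty_matrix"
  )
}

#' Spatial smooth basis over region centroids
#'
#' Builds either a two-dimensional tensor-product P-spline over region
#' centroid coordinates (`mode = "tensor"`, the default) or an intrinsic MRF
#' term on the neighbourhood graph (`mode = "mrf"`; the adjacency defaults to
#' the 4-nearest-neighbour graph of the centroids).
#'
#' @param centroids data frame with `region_id`, `lon`, `lat`.
#' @param mode `"tensor"` or `"mrf"`.
#' @param k_segments marginal segments for the tensor spline (default 8).
#' @param degree marginal spline degree for the tensor spline.
#' @param order marginal random-walk order for the tensor penalty (default 1).
#' @param adjacency optional symmetric adjacency for `mode = "mrf"`.
#' @param knn_k neighbours used when the adjacency is built internally.
#' @return list of class `spatial_basis`: `design` (regions x coefficients),
#'   `penalty` (`penalty_matrix`), `mode`, `region_id`, plus the marginal
#'   knot vectors in tensor mode.
#' @export
spatial_basis <- function(centroids, mode = c("tensor", "mrf"),
                          k_segments = 8L, degree = 3L, order = 1L,
                          adjacency = NULL, knn_k = 4L) {
  mode <- match.arg(mode)
  stopifnot(all(c("region_id", "lon", "lat") %in% names(centroids)))
  if (mode == "tensor") {
    kv1 <- build_knots(centroids$lon, k_segments, degree, name = "lon")
    kv2 <- build_knots(centroids$lat, k_segments, degree, name = "lat")
    B1 <- bspline_design(centroids$lon, kv1)
    B2 <- bspline_design(centroids$lat, kv2)
    out <- list(design = tensor_design(B1, B2),
                penalty = tensor_penalty(difference_penalty(kv1$d, order),
                                         difference_penalty(kv2$d, order)),
                mode = mode, region_id = centroids$region_id,
                kv1 = kv1, kv2 = kv2)
  } else {
    if (is.null(adjacency)) adjacency <- knn_adjacency(centroids, k = knn_k)
    out <- list(design = diag(nrow(centroids)),
                penalty = mrf_precision(adjacency),
                mode = mode, region_id = centroids$region_id,
                adjacency = adjacency)
  }
  class(out) <- "spatial_basis"
  out
}
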