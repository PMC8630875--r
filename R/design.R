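#' Effect (deviation) coding of a categorical value
#'
#' Codes a categorical level against the grand mean: non-reference level `j`
#' maps to an indicator row with 1 in its own position, the reference level
#' maps to -1 in every position. Columns are ordered by the non-reference
#' levels of `levels`.
#'
#' @param levels ordered level labels.
#' @param reference the reference level (a member of `levels`).
#' @param value the observed level (scalar or vector).
#' @param name covariate label for error messages.
#' @return numeric matrix with `length(value)` rows and
#'   `length(levels) - 1` columns (a plain vector for scalar input).
#' @export
effect_code <- function(levels, reference, value, name = "covariate") {
  if (!reference %in% levels) {
    stop("reference level '", reference, "' not among levels of ", name)
  }
  bad <- setdiff(unique(value), levels)
  if (length(bad) > 0L) {
    stop("unknown level(s) for ", name, ": ", paste(bad, collapse = ", "))
  }
  nonref <- setdiff(levels, reference)
  M <- matrix(0, length(value), length(nonref),
              dimnames = list(NULL, nonref))
  for (j in seq_along(nonref)) M[, j] <- as.numeric(value == nonref[j])
  M[value == reference, ] <- -1
  if (length(value) == 1L) drop(M) else M
}

#' Geo-additive model specification
#'
#' Describes one of the nested model forms: `M0` fixed effects only, `M1`
#' adds nonlinear smooths of the continuous covariates, `M2` adds the spatial
#' term only, `M3` has both.
#'
#' @param form one of `"M0"`, `"M1"`, `"M2"`, `"M3"`.
#' @param fixed named list: for each categorical covariate, `list(levels=,
#'   ref=)`. Defaults to the synthetic covariate dictionary.
#' @param smooth named list: for each continuous covariate, `list(n_segments=,
#'   degree=, order=)`. Defaults: 20 segments, cubic, second-order random
#'   walk, for child age / mother age / breastfeeding duration.
#' @param spatial list with `mode` (`"tensor"` or `"mrf"`), `k_segments`,
#'   `order`, `knn_k`.
#' @param hyper inverse-gamma hyperparameters `a`, `b` on every smoothing
#'   variance.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(form = c("M3", "M0", "M1", "M2"),
                       fixed = NULL, smooth = NULL,
                       spatial = list(mode = "tensor", k_segments = 8L,
                                      order = 1L, knn_k = 4L),
                       hyper = list(a = 0.001, b = 0.001)) {
  form <- match.arg(form)
  if (is.null(fixed)) {
    fixed <- lapply(covariate_dictionary(), function(cv) {
      list(levels = cv$levels, ref = cv$ref)
    })
  }
  if (is.null(smooth)) {
    smooth <- list(
      child_age = list(n_segments = 20L, degree = 3L, order = 2L),
      mother_age = list(n_segments = 20L, degree = 3L, order = 2L),
      breastfeed = list(n_segments = 20L, degree = 3L, order = 2L)
    )
  }
  spatial <- utils::modifyList(
    list(mode = "tensor", k_segments = 8L, order = 1L, knn_k = 4L), spatial)
  structure(
    list(form = form, fixed = fixed, smooth = smooth, spatial = spatial,
         hyper = hyper,
         has_smooth = form %in% c("M1", "M3"),
         has_spatial = form %in% c("M2", "M3")),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec %s: %d fixed covariates%s%s\n", x$form,
              length(x$fixed),
              if (x$has_smooth)
                paste0(", smooths: ", paste(names(x$smooth), collapse = ", "))
              else "",
              if (x$has_spatial) paste0(", spatial (", x$spatial$mode, ")")
              else ""))
  invisible(x)
}

#' MCMC configuration
#'
#' @param n_iter total iterations (the motivating analysis used 40000).
#' @param n_burnin burn-in iterations (< `n_iter`; 10000 in the motivating
#'   analysis).
#' @param thin thinning interval (>= 1).
#' @param seed integer seed.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 40000L, n_burnin = 10000L, thin = 1L,
                        seed = 1L) {
  n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin)
  thin <- as.integer(thin)
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = n_iter, n_burnin = n_burnin, thin = thin,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Assemble design blocks for a geo-additive model
#'
#' Builds the blocks the sampler consumes: a fixed block (leading intercept
#' column plus effect-coded categorical columns, flat prior), one centred
#' P-spline block per smooth covariate, and a centred spatial block
#' (tensor-product over centroids, or MRF region indicators) when the model
#' form includes it. Column-centring makes every penalized block orthogonal
#' to the intercept; the spatial block is centred with observed region
#' frequencies as weights and kept in a memory-efficient region-level
#' representation (`group` index per row).
#'
#' Rows with missing values in any used column are dropped (complete-case)
#' with a message recording the count.
#'
#' @param data data frame of child records (`anaemic` outcome column plus
#'   covariates named in `spec`).
#' @param spec a `model_spec`.
#' @param centroids data frame `region_id`, `lon`, `lat`; required for
#'   M2/M3.
#' @param adjacency optional adjacency matrix for `spatial mode = "mrf"`.
#' @param outcome name of the binary outcome column.
#' @return object of class `geoadd_design`: `y`, `blocks`, `n`,
#'   `n_dropped`, term metadata for prediction.
#' @export
assemble_design <- function(data, spec, centroids = NULL, adjacency = NULL,
                            outcome = "anaemic") {
  stopifnot(inherits(spec, "model_spec"))
  used <- c(outcome, names(spec$fixed))
  if (spec$has_smooth) used <- c(used, names(spec$smooth))
  if (spec$has_spatial) used <- c(used, "region_id")
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L) {
    stop("columns missing from data: ", paste(missing_cols, collapse = ", "))
  }
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped > 0L) {
    message("assemble_design: dropped ", n_dropped,
            " rows with missing values (complete-case)")
  }
  data <- data[cc, , drop = FALSE]
  n <- nrow(data)
  if (n == 0L) stop("no complete rows left")
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")

  blocks <- list()

  # fixed block: intercept + effect-coded categorical columns, flat prior
  cols <- list(`(Intercept)` = rep(1, n))
  for (nm in names(spec$fixed)) {
    cv <- spec$fixed[[nm]]
    M <- effect_code(cv$levels, cv$ref, data[[nm]], name = nm)
    colnames(M) <- paste0(nm, ":", colnames(M))
    cols[[nm]] <- M
  }
  U <- do.call(cbind, c(list(`(Intercept)` = rep(1, n)),
                        cols[names(spec$fixed)]))
  colnames(U)[1] <- "(Intercept)"
  blocks$fixed <- list(
    name = "fixed", type = "fixed", X = U, group = NULL,
    K = diag(1e-8, ncol(U)), penalized = FALSE, center = FALSE,
    rank = 0L, a = 0, b = 0, labels = colnames(U)
  )

  if (spec$has_smooth) {
    for (nm in names(spec$smooth)) {
      st <- spec$smooth[[nm]]
      x <- data[[nm]]
      kv <- build_knots(x, st$n_segments, st$degree, name = nm)
      B <- bspline_design(x, kv)
      cm <- colMeans(B)
      Bc <- sweep(B, 2L, cm)
      pen <- difference_penalty(kv$d, st$order)
      blocks[[paste0("sm_", nm)]] <- list(
        name = paste0("sm_", nm), type = "smooth", term = nm,
        X = Bc, group = NULL, K = pen$matrix, penalized = TRUE,
        center = TRUE, rank = pen$rank, a = spec$hyper$a, b = spec$hyper$b,
        kv = kv, colmeans = cm
      )
    }
  }

  if (spec$has_spatial) {
    if (is.null(centroids)) stop("centroids required for form ", spec$form)
    present <- unique(as.character(data$region_id))
    unknown <- setdiff(present, centroids$region_id)
    if (length(unknown) > 0L) {
      stop("regions in data without centroids: ",
           paste(unknown, collapse = ", "))
    }
    sb <- spatial_basis(centroids, mode = spec$spatial$mode,
                        k_segments = spec$spatial$k_segments,
                        order = spec$spatial$order,
                        adjacency = adjacency, knn_k = spec$spatial$knn_k)
    group <- match(as.character(data$region_id), centroids$region_id)
    ng <- tabulate(group, nbins = nrow(centroids))
    cm <- colSums(sb$design * ng) / n   # frequency-weighted column means
    Rc <- sweep(sb$design, 2L, cm)
    blocks$spatial <- list(
      name = "spatial", type = "spatial", X = Rc, group = group,
      K = sb$penalty$matrix, penalized = TRUE, center = TRUE,
      rank = sb$penalty$rank, a = spec$hyper$a, b = spec$hyper$b,
      basis = sb, colmeans = cm, region_id = centroids$region_id,
      region_counts = ng
    )
  }

  structure(
    list(y = as.numeric(y), blocks = blocks, n = n, n_dropped = n_dropped,
         spec = spec),
    class = "geoadd_design"
  )
}

#' @export
print.geoadd_design <- function(x, ...) {
  p_pen <- sum(vapply(x$blocks, function(b) {
    if (b$penalized) ncol(b$X) else 0L
  }, 0L))
  cat(sprintf(
    "geoadd_design (%s): n = %d, %d blocks, %d fixed columns, %d penalized coefficients\n",
    x$spec$form, x$n, length(x$blocks), ncol(x$blocks$fixed$X), p_pen))
  invisible(x)
}
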