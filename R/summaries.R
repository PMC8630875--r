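#' Deviance information criterion
#'
#' `DIC = dbar + pd` with `dbar` the posterior mean deviance and
#' `pd = dbar - D(posterior-mean parameters)` the effective number of
#' parameters. A negative `pd` is reported with a warning, never silently
#' clipped.
#'
#' @param x a `geoadd_fit`, or a numeric vector of per-iteration deviance
#'   draws.
#' @param deviance_at_mean deviance at the posterior-mean parameters
#'   (required when `x` is a vector).
#' @return object of class `dic_result` with fields `dbar`, `pd`, `dic`.
#' @export
dic <- function(x, deviance_at_mean = NULL) {
  if (inherits(x, "geoadd_fit")) {
    draws <- x$deviance
    deviance_at_mean <- x$deviance_at_mean
  } else {
    draws <- as.numeric(x)
    if (is.null(deviance_at_mean)) stop("deviance_at_mean required")
  }
  if (length(draws) < 2L) stop("need at least 2 deviance draws")
  dbar <- mean(draws)
  pd <- dbar - deviance_at_mean
  if (pd < 0) {
    warning(sprintf("negative effective parameter count pd = %.3f", pd))
  }
  structure(list(dbar = dbar, pd = pd, dic = dbar + pd),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.2f (mean deviance %.2f, pd %.2f)\n",
              x$dic, x$dbar, x$pd))
  invisible(x)
}

#' Compare fitted models by DIC
#'
#' Ranks fits ascending by DIC; the smallest-DIC model is flagged preferred.
#' All fits must be on identical data (checked by row count).
#'
#' @param fits named list of `geoadd_fit` objects.
#' @return data frame with columns `model`, `dbar`, `pd`, `dic`,
#'   `preferred`, sorted ascending by `dic`.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  ns <- vapply(fits, function(f) f$n, 0L)
  if (length(unique(ns)) != 1L) {
    stop("fits are on differing datasets (row counts: ",
         paste(ns, collapse = ", "), ")")
  }
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$spec$form, "")
  }
  rows <- lapply(names(fits), function(nm) {
    d <- dic(fits[[nm]])
    data.frame(model = nm, dbar = d$dbar, pd = d$pd, dic = d$dic,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dic), , drop = FALSE]
  tab$preferred <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}

# quantile convention used throughout: linear interpolation of order
# statistics (R type 7), so the sort-based oracle in the tests matches
post_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

#' Posterior summary table for the fixed effects
#'
#' Per coefficient: posterior mean, SD, 10% quantile, median, 90% quantile,
#' and a significance flag (the 95% equal-tailed credible interval excludes
#' zero).
#'
#' @param fit a `geoadd_fit` (or a draws matrix with named columns).
#' @return data frame, one row per fixed-effect coefficient.
#' @export
fixed_effect_table <- function(fit) {
  draws <- if (inherits(fit, "geoadd_fit")) fit$draws$fixed else as.matrix(fit)
  if (is.null(draws)) stop("fit has no fixed-effect draws")
  out <- data.frame(
    coefficient = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    q10 = apply(draws, 2L, post_quantile, probs = 0.10),
    median = apply(draws, 2L, post_quantile, probs = 0.50),
    q90 = apply(draws, 2L, post_quantile, probs = 0.90),
    stringsAsFactors = FALSE
  )
  lo <- apply(draws, 2L, post_quantile, probs = 0.025)
  hi <- apply(draws, 2L, post_quantile, probs = 0.975)
  out$significant <- lo > 0 | hi < 0
  rownames(out) <- NULL
  out
}

#' Posterior nonlinear-effect curve with credible bands
#'
#' Evaluates the centred P-spline smooth of one continuous covariate on a
#' grid: posterior mean and pointwise 2.5%/97.5% equal-tailed quantiles. The
#' curve inherits the model's centring constraint (the basis columns were
#' centred at the observed covariate values).
#'
#' @param fit a `geoadd_fit` from a model with smooths (M1/M3).
#' @param term smooth covariate name (e.g. `"breastfeed"`).
#' @param grid evaluation points inside the knot range; defaults to 200
#'   equally spaced points.
#' @return data frame `x`, `mean`, `lower`, `upper`.
#' @export
smooth_curve <- function(fit, term, grid = NULL) {
  bname <- paste0("sm_", term)
  b <- fit$design$blocks[[bname]]
  if (is.null(b)) stop("fit has no smooth term '", term, "'")
  kv <- b$kv
  if (is.null(grid)) grid <- seq(kv$lower, kv$upper, length.out = 200L)
  if (any(grid < kv$lower | grid > kv$upper)) {
    stop("grid outside knot range [", kv$lower, ", ", kv$upper, "]")
  }
  B <- sweep(bspline_design(grid, kv), 2L, b$colmeans)
  curves <- B %*% t(fit$draws[[bname]])   # grid x draws
  data.frame(
    x = grid,
    mean = rowMeans(curves),
    lower = apply(curves, 1L, post_quantile, probs = 0.025),
    upper = apply(curves, 1L, post_quantile, probs = 0.975)
  )
}

#' Credible-interval classification of spatial effects
#'
#' Evaluates the spatial effect of every region at its centroid across the
#' retained draws and classifies each region by the equal-tailed credible
#' interval at `level`: `positive` if the lower quantile exceeds zero,
#' `negative` if the upper quantile is below zero, else `insignificant`.
#' Intervals are nested, so any region significant at 95% is also
#' significant at 80%.
#'
#' @param fit a `geoadd_fit` from a model with a spatial term (M2/M3).
#' @param level credible level, 0.80 or 0.95.
#' @return object of class `spatial_classification`: data frame
#'   `region_id`, `mean`, `lower`, `upper`, `category`, with the level as an
#'   attribute.
#' @export
classify_spatial <- function(fit, level = 0.95) {
  b <- fit$design$blocks$spatial
  if (is.null(b)) {
    stop("fit ", fit$spec$form, " has no spatial term (need M2 or M3)")
  }
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  eff <- b$X %*% t(fit$draws$spatial)   # regions x draws
  alpha <- (1 - level) / 2
  lo <- apply(eff, 1L, post_quantile, probs = alpha)
  hi <- apply(eff, 1L, post_quantile, probs = 1 - alpha)
  cat3 <- ifelse(lo > 0, "positive", ifelse(hi < 0, "negative",
                                            "insignificant"))
  out <- data.frame(region_id = b$region_id, mean = rowMeans(eff),
                    lower = lo, upper = hi, category = cat3,
                    stringsAsFactors = FALSE)
  attr(out, "level") <- level
  class(out) <- c("spatial_classification", class(out))
  out
}

#' @export
print.spatial_classification <- function(x, ...) {
  lv <- attr(x, "level")
  cat(sprintf(
    "spatial_classification at %.0f%%: %d positive, %d negative, %d insignificant of %d regions\n",
    100 * lv, sum(x$category == "positive"), sum(x$category == "negative"),
    sum(x$category == "insignificant"), nrow(x)))
  invisible(NextMethod())
}
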