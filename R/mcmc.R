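#' Fit a geo-additive logistic model by Polya-Gamma Gibbs sampling
#'
#' Runs the blockwise Gibbs sampler with Polya-Gamma augmentation: latent
#' `omega_i ~ PG(1, eta_i)` linearise the Bernoulli-logit likelihood, so each
#' coefficient block has a Gaussian full conditional with precision
#' `X' Omega X + K / tau^2`, and each smoothing variance an inverse-gamma
#' full conditional `IG(a + rank(K)/2, b + beta' K beta / 2)`. Fixed effects
#' carry an improper flat prior (1e-8 ridge for numerical stability); the
#' constant direction of each penalized block is removed by centring plus a
#' post-draw projection. Fixed effects are initialised at the IRLS solution
#' of the fixed-only logistic fit, smooth coefficients at 0, variances at
#' 0.1. The per-iteration deviance `-2 log L` is recorded for every retained
#' draw. Fully deterministic given `cfg$seed`.
#'
#' @param design a `geoadd_design` from [assemble_design()].
#' @param y binary outcomes; defaults to the outcomes stored in the design.
#' @param cfg an `mcmc_config`.
#' @param lik_weight likelihood weight in `[0, 1]`; 0 samples from the prior
#'   only (validation hook).
#' @return object of class `geoadd_fit`.
#' @export
fit_mcmc <- function(design, y = design$y, cfg = mcmc_config(),
                     lik_weight = 1) {
  stopifnot(inherits(design, "geoadd_design"), inherits(cfg, "mcmc_config"))
  y <- as.numeric(y)
  if (length(y) != design$n) stop("length(y) != design n")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")

  # initialise fixed effects at the fixed-only IRLS solution
  blocks <- design$blocks
  U <- blocks$fixed$X
  init_fix <- tryCatch(
    suppressWarnings(stats::glm.fit(U, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, ncol(U)))
  init_fix[!is.finite(init_fix)] <- 0

  cpp_blocks <- lapply(blocks, function(b) {
    d <- ncol(b$X)
    init <- if (b$type == "fixed" && lik_weight > 0) init_fix else rep(0, d)
    list(X = b$X, group = b$group, K = b$K, penalized = b$penalized,
         center = b$center, rank = as.integer(b$rank), a = b$a, b = b$b,
         init = init, tau2_init = if (b$penalized) 0.1 else 1)
  })

  set.seed(cfg$seed)
  res <- .gibbs_pg(y, unname(cpp_blocks), cfg$n_iter, cfg$n_burnin,
                   cfg$thin, lik_weight, 1e-8)

  draws <- res$beta
  names(draws) <- names(blocks)
  colnames(draws$fixed) <- blocks$fixed$labels
  pen_names <- names(blocks)[vapply(blocks, `[[`, TRUE, "penalized")]
  tau2 <- res$tau2
  colnames(tau2) <- pen_names

  # posterior-mean linear predictor and its deviance (for DIC's p_D)
  post_mean <- lapply(draws, colMeans)
  eta_hat <- numeric(design$n)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    f <- as.numeric(b$X %*% post_mean[[nm]])
    eta_hat <- eta_hat + if (is.null(b$group)) f else f[b$group]
  }
  # stable log(1+exp(x)): x + log1p(exp(-x)) for large x
  l1pe <- ifelse(eta_hat > 30, eta_hat + log1p(exp(-eta_hat)),
                 log1p(exp(eta_hat)))
  dev_at_mean <- -2 * sum(y * eta_hat - l1pe)

  mean_abs_eta <- mean(abs(eta_hat))
  if (lik_weight > 0 && mean_abs_eta > 15) {
    warning("possible perfect separation: posterior-mean |eta| is very large")
  }

  structure(
    list(draws = draws, tau2 = tau2, deviance = as.numeric(res$deviance),
         deviance_at_mean = dev_at_mean, eta_hat = eta_hat,
         design = design, spec = design$spec, mcmc = cfg,
         n = design$n, n_keep = res$n_keep, lik_weight = lik_weight),
    class = "geoadd_fit"
  )
}

#' Fit a geo-additive model from data
#'
#' Convenience wrapper: assembles the design with [assemble_design()] and
#' samples with [fit_mcmc()].
#'
#' @inheritParams assemble_design
#' @param mcmc an `mcmc_config`.
#' @param ... passed to [fit_mcmc()].
#' @return a `geoadd_fit`.
#' @export
fit_geoadd <- function(data, spec, centroids = NULL, adjacency = NULL,
                       mcmc = mcmc_config(), outcome = "anaemic", ...) {
  design <- assemble_design(data, spec, centroids = centroids,
                            adjacency = adjacency, outcome = outcome)
  fit_mcmc(design, cfg = mcmc, ...)
}

#' @export
print.geoadd_fit <- function(x, ...) {
  cat(sprintf(
    "geoadd_fit (%s): n = %d, %d retained draws (of %d, burn-in %d, thin %d)\n",
    x$spec$form, x$n, x$n_keep, x$mcmc$n_iter, x$mcmc$n_burnin, x$mcmc$thin))
  cat(sprintf("  posterior mean deviance: %.2f\n", mean(x$deviance)))
  invisible(x)
}

#' Convergence diagnostics for posterior draws
#'
#' Per-parameter lag autocorrelations (up to `max_lag`) and effective sample
#' sizes. ESS uses the initial-positive-sequence truncation
#' `n / (1 + 2 sum(rho_k))`, stopping at the first non-positive
#' autocorrelation. Chains with zero variance are flagged degenerate and get
#' `NA` ESS.
#'
#' @param x a `geoadd_fit` or a numeric matrix of draws (iterations in rows).
#' @param max_lag largest autocorrelation lag reported (default 50).
#' @return object of class `mcmc_diagnostics`: `acf` (lag x parameter
#'   matrix), `ess`, `degenerate` (logical), `n_draws`.
#' @export
diagnostics <- function(x, max_lag = 50L) {
  draws <- if (inherits(x, "geoadd_fit")) {
    do.call(cbind, unname(x$draws))
  } else {
    as.matrix(x)
  }
  if (is.null(colnames(draws))) {
    colnames(draws) <- paste0("par", seq_len(ncol(draws)))
  }
  n <- nrow(draws)
  if (n < 100L) stop("need at least 100 retained draws for diagnostics")
  max_lag <- min(max_lag, n - 1L)
  p <- ncol(draws)
  acfs <- matrix(NA_real_, max_lag, p,
                 dimnames = list(paste0("lag", seq_len(max_lag)),
                                 colnames(draws)))
  ess <- numeric(p)
  degen <- logical(p)
  for (j in seq_len(p)) {
    v <- draws[, j]
    if (stats::sd(v) == 0) {
      degen[j] <- TRUE
      ess[j] <- NA_real_
      next
    }
    a <- stats::acf(v, lag.max = max_lag, plot = FALSE)$acf[-1]
    acfs[, j] <- a
    pos <- which(a <= 0)
    K <- if (length(pos) > 0L) pos[1] - 1L else max_lag
    ess[j] <- n / (1 + 2 * sum(a[seq_len(K)]))
  }
  names(ess) <- colnames(draws)
  structure(list(acf = acfs, ess = ess, degenerate = degen, n_draws = n),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat(sprintf("mcmc_diagnostics: %d draws, %d parameters\n",
              x$n_draws, length(x$ess)))
  if (any(x$degenerate)) {
    cat("  DEGENERATE (zero-variance) chains: ",
        paste(names(x$ess)[x$degenerate], collapse = ", "), "\n")
  }
  cat(sprintf("  ESS range: %.0f .. %.0f\n",
              min(x$ess, na.rm = TRUE), max(x$ess, na.rm = TRUE)))
  invisible(x)
}
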