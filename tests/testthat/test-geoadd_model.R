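test_that("effect coding contrasts against the grand mean", {
  lv <- c("Poor", "Middle", "Rich", "Richest", "Poorest")
  expect_equal(effect_code(lv, "Poorest", "Poor"), c(Poor = 1, Middle = 0,
                                                     Rich = 0, Richest = 0))
  expect_equal(unname(effect_code(lv, "Poorest", "Poorest")), rep(-1, 4))
  expect_error(effect_code(lv, "Poorest", "Pauper", name = "wealth"),
               "wealth.*Pauper")

  # balanced two-level sample: coded column sums to zero
  x <- rep(c("Yes", "No"), each = 30)
  M <- effect_code(c("Yes", "No"), "No", x)
  expect_equal(sum(M), 0)
})

test_that("assembled designs have the documented shapes and centring", {
  sim <- tiny_sim()
  dat <- sim$data

  fx <- list(fever = list(levels = c("Yes", "No"), ref = "No"),
             stunted = list(levels = c("Yes", "No"), ref = "No"),
             mother_anaemic = list(levels = c("Yes", "No"), ref = "No"))
  d0 <- assemble_design(dat, model_spec("M0", fixed = fx))
  expect_equal(ncol(d0$blocks$fixed$X), 1L + 3L)
  expect_equal(length(d0$blocks), 1L)

  d3 <- assemble_design(dat, model_spec("M3"),
                        centroids = sim$geography$centroids)
  p_pen <- sum(vapply(d3$blocks, function(b) {
    if (b$penalized) ncol(b$X) else 0L
  }, 0L))
  expect_equal(p_pen, 3L * 23L + 121L)

  # centred blocks: smooth columns mean 0; spatial weighted-mean 0
  expect_lt(max(abs(colMeans(d3$blocks$sm_child_age$X))), 1e-10)
  sp <- d3$blocks$spatial
  expect_lt(max(abs(colSums(sp$X * sp$region_counts) / d3$n)), 1e-10)

  # missing covariates: complete-case with a message
  dat2 <- dat
  dat2$fever[1:5] <- NA
  expect_message(d <- assemble_design(dat2, model_spec("M0", fixed = fx)),
                 "dropped 5")
  expect_equal(d$n, nrow(dat) - 5L)

  expect_error(assemble_design(dat, model_spec("M3")), "centroids")
  expect_error(assemble_design(dat[, -1], model_spec("M3"),
                               centroids = sim$geography$centroids),
               "child_age")
})

test_that("retained draw count follows (n_iter - n_burnin) / thin", {
  expect_equal((40000 - 10000) / 1, 30000)  # the production configuration
  y <- rbinom(200, 1, 0.5)
  des <- assemble_design(data.frame(anaemic = y),
                         model_spec("M0", fixed = list()))
  fit <- fit_mcmc(des, cfg = mcmc_config(400, 100, 3, seed = 1))
  expect_equal(fit$n_keep, 100L)
  expect_equal(nrow(fit$draws$fixed), 100L)
  expect_error(mcmc_config(100, 100), "n_burnin")
  expect_error(mcmc_config(100, 10, 0), "thin")
})

test_that("sampler recovers an intercept-only Bernoulli model", {
  set.seed(31)
  y <- rbinom(5000, 1, 0.3)
  des <- assemble_design(data.frame(anaemic = y),
                         model_spec("M0", fixed = list()))
  fit <- fit_mcmc(des, cfg = mcmc_config(5000, 1000, 1, seed = 32))
  m <- mean(fit$draws$fixed[, 1])
  s <- sd(fit$draws$fixed[, 1])
  expect_lt(abs(m - qlogis(0.3)), 3 * s + 3 * sqrt(1 / (5000 * 0.21)))
})

test_that("sampler agrees with a Newton-Raphson maximum-likelihood oracle", {
  set.seed(33)
  n <- 5000
  x <- rbinom(n, 1, 0.45)
  eta <- -0.4 + 0.7 * (2 * x - 1)
  y <- rbinom(n, 1, plogis(eta))
  dat <- data.frame(anaemic = y, expo = ifelse(x == 1, "Yes", "No"))
  des <- assemble_design(dat, model_spec(
    "M0", fixed = list(expo = list(levels = c("Yes", "No"), ref = "No"))))
  fit <- fit_mcmc(des, cfg = mcmc_config(4000, 1000, 1, seed = 34))
  tab <- fixed_effect_table(fit)
  bhat <- newton_logistic(des$blocks$fixed$X, y)
  expect_lt(abs(tab$mean[1] - bhat[1]), 3 * tab$sd[1])
  expect_lt(abs(tab$mean[2] - bhat[2]), 3 * tab$sd[2])
})

test_that("identical seeds give identical chains", {
  sim <- tiny_sim()
  spec <- model_spec("M1", smooth = list(
    child_age = list(n_segments = 6L, degree = 3L, order = 2L)))
  f1 <- fit_geoadd(sim$data, spec, mcmc = mcmc_config(300, 100, 1, seed = 5))
  f2 <- fit_geoadd(sim$data, spec, mcmc = mcmc_config(300, 100, 1, seed = 5))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("prior-only sampling respects the random-walk structure", {
  sim <- tiny_sim()
  spec <- model_spec("M1", smooth = list(
    breastfeed = list(n_segments = 8L, degree = 3L, order = 1L)))
  des <- assemble_design(sim$data, spec)
  fit <- fit_mcmc(des, cfg = mcmc_config(1200, 200, 1, seed = 6),
                  lik_weight = 0)
  sm <- fit$draws$sm_breastfeed
  # the constant (unpenalized) direction is excluded by the centring constraint
  expect_lt(max(abs(rowMeans(sm))), 1e-8)
  # penalized directions do vary under the prior
  expect_true(all(apply(sm, 2, sd) > 0))
  # RW1 prior: increments scale with tau; marginal spread grows along the walk
  expect_gt(sd(sm[, 8] - sm[, 1]), sd(sm[, 2] - sm[, 1]))
})

test_that("permuting the outcome removes all fixed effects", {
  sim <- memo("null_perm_sim",
              generate_dataset(default_truth(n_children = 2000L, seed = 40L)))
  covered <- integer(0)
  for (r in 1:20) {
    dat <- sim$data
    set.seed(700 + r)
    dat$anaemic <- sample(dat$anaemic)
    fit <- fit_geoadd(dat, model_spec("M0"),
                      mcmc = mcmc_config(800, 200, 1, seed = 800 + r))
    draws <- fit$draws$fixed[, -1, drop = FALSE]  # drop intercept
    lo <- apply(draws, 2, quantile, 0.025)
    hi <- apply(draws, 2, quantile, 0.975)
    covered <- c(covered, as.integer(lo <= 0 & hi >= 0))
  }
  # pooled across coefficients and replicates, ~95% nominal coverage of zero
  expect_gte(mean(covered), 0.90)
})

test_that("diagnostics report autocorrelation and effective sample size", {
  set.seed(35)
  white <- matrix(rnorm(10000), ncol = 1)
  d <- diagnostics(white)
  expect_lt(abs(d$acf[1, 1]), 0.05)
  expect_gt(d$ess[1], 8000)

  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 10000))
  d <- diagnostics(matrix(ar, ncol = 1))
  expect_lt(abs(d$acf[1, 1] - rho), 0.05)
  expect_lt(d$ess[1], 2000)

  const <- matrix(rep(1, 500), ncol = 1)
  d <- diagnostics(const)
  expect_true(d$degenerate[1])
  expect_true(is.na(d$ess[1]))

  expect_error(diagnostics(matrix(rnorm(50), ncol = 1)), "100")
})
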