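#' @name synthetic
#' @title Synthetic child-anaemia survey generator
#' @description
#' Generates child-level records with the statistical structure the
#' geo-additive model assumes: effect-coded categorical fixed effects,
#' centred nonlinear effects of child age, mother's age and breastfeeding
#' duration, a smooth spatial surface over region centroids, and a Bernoulli
#' outcome on the logit scale. Because the truth is known in closed form,
#' every downstream stage (design assembly, MCMC, DIC, curve and map
#' summaries) can be validated by parameter recovery.
NULL

#' Categorical covariate dictionary
#'
#' Levels, reference level, marginal frequencies resembling a large Indian
#' child-health survey, and true effect-coded coefficients for the
#' non-reference levels (the reference takes minus the sum through the
#' coding, not an own coefficient). These are the documented defaults of the
#' synthetic generator and of [model_spec()].
#'
#' @return named list, one entry per categorical covariate.
#' @export
covariate_dictionary <- function() {
  list(
    residence = list(levels = c("Urban", "Rural"), ref = "Rural",
                     probs = c(Urban = 0.228, Rural = 0.772),
                     beta = c(Urban = 0.0359)),
    sex = list(levels = c("Male", "Female"), ref = "Female",
               probs = c(Male = 0.520, Female = 0.480),
               beta = c(Male = 0.0074)),
    mother_edu = list(levels = c("Primary", "Secondary", "Higher", "None"),
                      ref = "None",
                      probs = c(Primary = 0.149, Secondary = 0.420,
                                Higher = 0.079, None = 0.352),
                      beta = c(Primary = 0.0563, Secondary = -0.0358,
                               Higher = -0.1843)),
    wealth = list(levels = c("Poor", "Middle", "Rich", "Richest", "Poorest"),
                  ref = "Poorest",
                  probs = c(Poor = 0.236, Middle = 0.195, Rich = 0.156,
                            Richest = 0.123, Poorest = 0.290),
                  beta = c(Poor = 0.0740, Middle = 0.0069, Rich = -0.0904,
                           Richest = -0.1332)),
    fever = list(levels = c("Yes", "No"), ref = "No",
                 probs = c(Yes = 0.139, No = 0.861), beta = c(Yes = 0.0326)),
    cough = list(levels = c("Yes", "No"), ref = "No",
                 probs = c(Yes = 0.116, No = 0.884), beta = c(Yes = -0.0594)),
    vitamin_a = list(levels = c("Yes", "No"), ref = "No",
                     probs = c(Yes = 0.326, No = 0.674),
                     beta = c(Yes = -0.0041)),
    stunted = list(levels = c("Yes", "No"), ref = "No",
                   probs = c(Yes = 0.441, No = 0.559), beta = c(Yes = 0.0999)),
    underweight = list(levels = c("Yes", "No"), ref = "No",
                       probs = c(Yes = 0.395, No = 0.605),
                       beta = c(Yes = 0.0797)),
    wasted = list(levels = c("Yes", "No"), ref = "No",
                  probs = c(Yes = 0.077, No = 0.923), beta = c(Yes = 0.0387)),
    mother_anaemic = list(levels = c("Yes", "No"), ref = "No",
                          probs = c(Yes = 0.409, No = 0.591),
                          beta = c(Yes = 0.2715))
  )
}

# ranges of the continuous covariates (months, years, months)
continuous_ranges <- function() {
  list(child_age = c(6, 59), mother_age = c(15, 49), breastfeed = c(0, 59))
}

#' Default generative truth
#'
#' The documented default truth used throughout the package's validation:
#' a decaying child-age effect (steepest over 6-15 months), a U-shaped
#' mother's-age effect with minimum at 31 years (declining over roughly
#' 25-37), a breastfeeding-duration effect with minimum at 29 months, a
#' smooth sinusoidal spatial surface over the map, fixed effects of the
#' magnitude seen in large national child-anaemia analyses (mother anaemic
#' +0.27 on the logit scale), and an intercept calibrated so the marginal
#' anaemia prevalence is about 57.6%.
#'
#' Each nonlinear truth is centred analytically under the uniform sampling
#' marginal of its covariate; the spatial surface is centred over the region
#' centroids at generation time.
#'
#' @param n_children number of children to generate (default 20000).
#' @param n_side lattice side for the synthetic geography (default 6, i.e. 36
#'   regions).
#' @param seed integer seed (mandatory for generation).
#' @param copula_rho Gaussian-copula correlation between mother's age and
#'   breastfeeding duration; 0 (independent) by default for testability.
#' @return object of class `truth_config`.
#' @export
default_truth <- function(n_children = 20000L, n_side = 6L, seed = 1L,
                          copula_rho = 0) {
  rng <- continuous_ranges()
  # analytic centring constants under uniform covariate marginals
  a0 <- rng$child_age[1]; a1 <- rng$child_age[2]
  c_age <- 0.8 * 10 / (a1 - a0) * (1 - exp(-(a1 - a0) / 10))
  m0 <- rng$mother_age[1]; m1 <- rng$mother_age[2]
  mmean <- (m0 + m1) / 2
  c_mage <- 0.0022 * ((m1 - m0)^2 / 12 + (mmean - 31)^2)
  b0 <- rng$breastfeed[1]; b1 <- rng$breastfeed[2]
  bmean <- (b0 + b1) / 2
  c_bf <- 0.0012 * ((b1 - b0)^2 / 12 + (bmean - 29)^2)
  structure(
    list(
      intercept = 0.3786,  # calibrated to marginal prevalence ~ 0.576
      fixed = covariate_dictionary(),
      ranges = rng,
      age = list(amp = 0.8, scale = 10, onset = 6, center = c_age),
      mage = list(coef = 0.0022, vertex = 31, center = c_mage),
      bf = list(coef = 0.0012, vertex = 29, center = c_bf),
      spatial = list(amp = 0.7),
      n_children = as.integer(n_children),
      n_side = as.integer(n_side),
      seed = as.integer(seed),
      copula_rho = copula_rho
    ),
    class = "truth_config"
  )
}

#' Zeroed truth (pure-noise variant)
#'
#' The default truth with all fixed, nonlinear and spatial effects set to
#' zero and the requested intercept: the null generative model used for
#' calibration checks (no spurious DIC gaps, screen rejection rates).
#'
#' @inheritParams default_truth
#' @param intercept logit-scale intercept (default 0).
#' @param keep_fixed keep the fixed-effect coefficients (only smooth and
#'   spatial truth zeroed)?
#' @return a `truth_config`.
#' @export
null_truth <- function(n_children = 10000L, n_side = 6L, seed = 1L,
                       intercept = 0, keep_fixed = FALSE) {
  tr <- default_truth(n_children = n_children, n_side = n_side, seed = seed)
  tr$intercept <- intercept
  tr$age$amp <- 0
  tr$age$center <- 0
  tr$mage$coef <- 0
  tr$mage$center <- 0
  tr$bf$coef <- 0
  tr$bf$center <- 0
  tr$spatial$amp <- 0
  if (!keep_fixed) {
    tr$fixed <- lapply(tr$fixed, function(cv) {
      cv$beta[] <- 0
      cv
    })
  }
  tr
}

#' Truth nonlinear effects, evaluated
#'
#' `truth_f_age`, `truth_f_mage` and `truth_f_bf` evaluate the centred true
#' nonlinear effects of a `truth_config`; `truth_spatial` evaluates the
#' (uncentred) spatial surface at longitude/latitude given the map bounding
#' box.
#'
#' @param truth a `truth_config`.
#' @param x evaluation points.
#' @return numeric vector of effect values (logit scale).
#' @export
truth_f_age <- function(truth, x) {
  truth$age$amp * exp(-(x - truth$age$onset) / truth$age$scale) -
    truth$age$center
}

#' @rdname truth_f_age
#' @export
truth_f_mage <- function(truth, x) {
  truth$mage$coef * (x - truth$mage$vertex)^2 - truth$mage$center
}

#' @rdname truth_f_age
#' @export
truth_f_bf <- function(truth, x) {
  truth$bf$coef * (x - truth$bf$vertex)^2 - truth$bf$center
}

#' @rdname truth_f_age
#' @param lon,lat coordinates.
#' @param bbox map bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @export
truth_spatial <- function(truth, lon, lat, bbox) {
  xt <- (lon - bbox[1]) / (bbox[2] - bbox[1])
  yt <- (lat - bbox[3]) / (bbox[4] - bbox[3])
  truth$spatial$amp * sin(pi * xt) * cos(pi * yt)
}

# effect-coded contribution of one categorical covariate column
fixed_contribution <- function(values, cv) {
  beta_full <- c(cv$beta, structure(-sum(cv$beta), names = cv$ref))
  unname(beta_full[values])
}

#' Generate a synthetic child-anaemia dataset
#'
#' Draws covariates from the documented marginals (uniform continuous ranges,
#' categorical frequencies from the covariate dictionary), allocates children
#' uniformly across the lattice regions, forms the logit-scale linear
#' predictor from the truth, and draws the Bernoulli outcome. Fully
#' reproducible from `truth$seed`.
#'
#' @param truth a `truth_config` from [default_truth()] or [null_truth()].
#' @return object of class `synthetic_dataset`: `data` (one row per child),
#'   `geography` (a `region_set`), `truth`, and `eta` (the true linear
#'   predictor, for oracle checks).
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "truth_config"))
  n <- truth$n_children
  if (n < 100L) {
    message("generate_dataset: n_children < 100; recovery tests unreliable")
  }
  set.seed(truth$seed)
  geo <- make_geography(truth$n_side, seed = truth$seed)
  G <- nrow(geo$centroids)

  region_idx <- sample.int(G, n, replace = TRUE)
  region_id <- geo$centroids$region_id[region_idx]

  rng <- truth$ranges
  child_age <- stats::runif(n, rng$child_age[1], rng$child_age[2])
  if (truth$copula_rho != 0) {
    z1 <- stats::rnorm(n)
    z2 <- truth$copula_rho * z1 +
      sqrt(1 - truth$copula_rho^2) * stats::rnorm(n)
    mother_age <- rng$mother_age[1] +
      stats::pnorm(z1) * diff(rng$mother_age)
    breastfeed <- rng$breastfeed[1] +
      stats::pnorm(z2) * diff(rng$breastfeed)
  } else {
    mother_age <- stats::runif(n, rng$mother_age[1], rng$mother_age[2])
    breastfeed <- stats::runif(n, rng$breastfeed[1], rng$breastfeed[2])
  }

  dat <- data.frame(child_age = child_age, mother_age = mother_age,
                    breastfeed = breastfeed, region_id = region_id,
                    stringsAsFactors = FALSE)
  for (nm in names(truth$fixed)) {
    cv <- truth$fixed[[nm]]
    dat[[nm]] <- sample(cv$levels, n, replace = TRUE, prob = cv$probs[cv$levels])
  }

  surf <- truth_spatial(truth, geo$centroids$lon, geo$centroids$lat, geo$bbox)
  surf <- surf - mean(surf)  # centred over region centroids

  eta <- truth$intercept +
    truth_f_age(truth, child_age) +
    truth_f_mage(truth, mother_age) +
    truth_f_bf(truth, breastfeed) +
    surf[region_idx]
  for (nm in names(truth$fixed)) {
    eta <- eta + fixed_contribution(dat[[nm]], truth$fixed[[nm]])
  }
  dat$anaemic <- stats::rbinom(n, 1L, stats::plogis(eta))

  structure(
    list(data = dat, geography = geo, truth = truth, eta = eta,
         spatial_truth = data.frame(region_id = geo$centroids$region_id,
                                    effect = surf, stringsAsFactors = FALSE)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d children, %d regions, prevalence %.1f%% (seed %d)\n",
    nrow(x$data), nrow(x$geography$centroids), 100 * mean(x$data$anaemic),
    x$truth$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `data.csv` (child records), `regions.geojson` (geometry) and
#' `truth.json` (the generative truth, for recovery tests) into `dir`.
#'
#' @param sim a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(dir, "data.csv")
  geo_path <- file.path(dir, "regions.geojson")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(sim$data, data_path, row.names = FALSE)
  write_geojson_regions(sim$geography, geo_path)
  truth <- sim$truth
  truth$fixed <- lapply(truth$fixed, function(cv) {
    cv$probs <- as.list(cv$probs)
    cv$beta <- as.list(cv$beta)
    cv
  })
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(data_path, geo_path, truth_path))
}
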