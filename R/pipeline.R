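#' Apply the study exclusion filters
#'
#' Mirrors the pre-analysis filters of the motivating survey study: rows in
#' excluded regions are removed, rows with missing haemoglobin are removed,
#' and — when a haemoglobin column is supplied — the binary anaemia outcome
#' is derived with the strict rule `Hb < cutoff` (11 g/dL by default; Hb
#' values are assumed altitude-adjusted upstream).
#'
#' @param data data frame with a `region_id` column and either the binary
#'   outcome or a haemoglobin column.
#' @param exclude_regions character vector of region ids to drop.
#' @param hb_column optional haemoglobin column name; when given, rows with
#'   `NA` haemoglobin are dropped and `outcome` is (re)derived.
#' @param hb_cutoff anaemia threshold in g/dL (strict less-than).
#' @param outcome binary outcome column name (created if `hb_column` given).
#' @return list: `data` (filtered) and `report` (counts removed per rule and
#'   the final analytic n).
#' @export
apply_filters <- function(data, exclude_regions = character(),
                          hb_column = NULL, hb_cutoff = 11,
                          outcome = "anaemic") {
  if (is.null(hb_column) && !outcome %in% names(data)) {
    stop("need either an outcome column '", outcome,
         "' or a haemoglobin column")
  }
  if (hb_cutoff <= 0) stop("hb_cutoff must be positive")
  n0 <- nrow(data)
  in_excl <- as.character(data$region_id) %in% exclude_regions
  n_region <- sum(in_excl)
  data <- data[!in_excl, , drop = FALSE]
  n_missing_hb <- 0L
  if (!is.null(hb_column)) {
    if (!hb_column %in% names(data)) {
      stop("haemoglobin column '", hb_column, "' not in data")
    }
    miss <- is.na(data[[hb_column]])
    n_missing_hb <- sum(miss)
    data <- data[!miss, , drop = FALSE]
    data[[outcome]] <- as.integer(data[[hb_column]] < hb_cutoff)
  }
  if (nrow(data) == 0L) stop("all rows removed by filters")
  list(data = data,
       report = list(n_input = n0, region = n_region,
                     missing_hb = n_missing_hb, n_final = nrow(data)))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (or accepts an equivalent list) describing a
#' full analysis run: input paths (or a `simulate` block), exclusion rules,
#' the model forms to fit, MCMC settings, and the screen alpha. A seed is
#' mandatory.
#'
#' @param config YAML file path or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config must contain a seed")
  cfg$seed <- as.integer(cfg$seed)
  defaults <- list(
    models = c("M0", "M1", "M2", "M3"),
    screen_alpha = 0.20,
    hb_cutoff = 11,
    exclude_regions = character(),
    mcmc = list(n_iter = 40000L, n_burnin = 10000L, thin = 1L),
    smooth = list(n_segments = 20L, degree = 3L, order = 2L),
    spatial = list(mode = "tensor", k_segments = 8L, order = 1L, knn_k = 4L)
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
    }
  }
  if (cfg$hb_cutoff <= 0) stop("hb_cutoff must be positive")
  if (!all(cfg$models %in% c("M0", "M1", "M2", "M3"))) {
    stop("models must be a subset of M0..M3")
  }
  for (p in c("data", "geometry", "adjacency")) {
    path <- cfg$paths[[p]]
    if (!is.null(path) && !file.exists(path)) {
      stop("configured ", p, " file does not exist: ", path)
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# per-run logger writing timestamped stage lines
pipeline_log <- function(log_path) {
  function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> filter -> describe -> fit the configured
#' model forms -> DIC comparison -> fixed-effect tables, nonlinear curves and
#' spatial credible-interval classification, writing every artifact into
#' `out_dir`. Each run writes a log with stage timings and row counts and a
#' manifest carrying the config echo, its MD5 hash and the seed, so every
#' artifact is re-derivable from config + seed alone. Any stage failure
#' aborts with the stage name and cause.
#'
#' @param config a `pipeline_config`, YAML path, or list.
#' @param out_dir output directory (defaults to `config$paths$out`).
#' @return (invisibly) list with the out directory, the comparison table and
#'   per-model DIC results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(out_dir)) out_dir <- cfg$paths$out
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- pipeline_log(file.path(out_dir, "run.log"))
  t_all <- Sys.time()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log(sprintf("stage %-10s done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # config echo + hash
  cfg_echo <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(unclass(cfg), cfg_echo)
  cfg_hash <- unname(tools::md5sum(cfg_echo))
  log("config hash ", cfg_hash, ", seed ", cfg$seed)

  # --- simulate or load -----------------------------------------------------
  loaded <- stage("input", {
    if (!is.null(cfg$simulate)) {
      truth <- default_truth(
        n_children = cfg$simulate$n_children %||% 20000L,
        n_side = cfg$simulate$n_side %||% 6L,
        seed = cfg$seed)
      sim <- generate_dataset(truth)
      list(data = sim$data, geography = sim$geography)
    } else {
      dat <- utils::read.csv(cfg$paths$data, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"))
      geo <- read_geojson_regions(cfg$paths$geometry)
      list(data = dat, geography = geo)
    }
  })
  dat <- loaded$data
  geo <- loaded$geography
  adjacency <- if (!is.null(cfg$paths$adjacency)) {
    read_adjacency(cfg$paths$adjacency, geo$centroids$region_id)
  } else NULL

  # --- filters --------------------------------------------------------------
  filt <- stage("filter", {
    apply_filters(dat, exclude_regions = cfg$exclude_regions,
                  hb_column = cfg$hb_column, hb_cutoff = cfg$hb_cutoff)
  })
  dat <- filt$data
  log("filter report: ", jsonlite::toJSON(filt$report, auto_unbox = TRUE))

  # --- descriptives ---------------------------------------------------------
  cat_covs <- names(covariate_dictionary())
  cat_covs <- intersect(cat_covs, names(dat))
  stage("describe", {
    utils::write.csv(prevalence_by(dat, "region_id"),
                     file.path(out_dir, "prevalence_by_region.csv"),
                     row.names = FALSE)
    prev_cov <- do.call(rbind, lapply(cat_covs, function(nm) {
      p <- prevalence_by(dat, nm)
      cbind(covariate = nm, p)
    }))
    utils::write.csv(prev_cov, file.path(out_dir, "prevalence_by_covariate.csv"),
                     row.names = FALSE)
    utils::write.csv(chi2_screen(dat, cat_covs, alpha = cfg$screen_alpha),
                     file.path(out_dir, "screen.csv"), row.names = FALSE)
  })

  # --- fits -----------------------------------------------------------------
  smooth_settings <- lapply(
    stats::setNames(nm = intersect(c("child_age", "mother_age", "breastfeed"),
                                   names(dat))),
    function(nm) cfg$smooth)
  fits <- list()
  for (form in cfg$models) {
    spec <- model_spec(form = form, smooth = smooth_settings,
                       spatial = cfg$spatial)
    fits[[form]] <- stage(paste0("fit_", form), {
      fit_geoadd(dat, spec, centroids = geo$centroids, adjacency = adjacency,
                 mcmc = mcmc_config(n_iter = cfg$mcmc$n_iter,
                                    n_burnin = cfg$mcmc$n_burnin,
                                    thin = cfg$mcmc$thin, seed = cfg$seed))
    })
    log(sprintf("fit %s: n = %d, %d retained draws", form,
                fits[[form]]$n, fits[[form]]$n_keep))
  }

  # --- comparison and summaries --------------------------------------------
  comparison <- NULL
  dics <- lapply(fits, dic)
  if (length(fits) >= 2L) {
    comparison <- stage("compare", compare_models(fits))
    utils::write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(lapply(dics, unclass),
                       file.path(out_dir, "dic.json"),
                       auto_unbox = TRUE, digits = NA)

  best <- if (!is.null(comparison)) comparison$model[1] else cfg$models[1]
  fit <- fits[[best]]
  stage("summarize", {
    for (form in names(fits)) {
      utils::write.csv(fixed_effect_table(fits[[form]]),
                       file.path(out_dir, paste0("fixed_effects_", form, ".csv")),
                       row.names = FALSE)
    }
    if (fit$spec$has_smooth) {
      for (nm in names(fit$spec$smooth)) {
        utils::write.csv(smooth_curve(fit, nm),
                         file.path(out_dir, paste0("curve_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
    saveRDS(fit$draws, file.path(out_dir, "draws.rds"))
    manifest <- list(
      config_hash = cfg_hash, seed = cfg$seed, best_model = best,
      blocks = lapply(fit$design$blocks, function(b) {
        list(name = b$name, type = b$type, d = ncol(b$X),
             penalized = b$penalized)
      }),
      n = fit$n, n_keep = fit$n_keep)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  if (fit$spec$has_spatial) {
    stage("map", {
      cls95 <- classify_spatial(fit, 0.95)
      cls80 <- classify_spatial(fit, 0.80)
      joined <- data.frame(region_id = cls95$region_id, mean = cls95$mean,
                           lower95 = cls95$lower, upper95 = cls95$upper,
                           category95 = cls95$category,
                           lower80 = cls80$lower, upper80 = cls80$upper,
                           category80 = cls80$category,
                           stringsAsFactors = FALSE)
      utils::write.csv(joined, file.path(out_dir, "spatial_classification.csv"),
                       row.names = FALSE)
      write_geojson_regions(geo, file.path(out_dir, "spatial_effects.geojson"),
                            properties = joined)
    })
  }

  log(sprintf("pipeline complete in %.1fs",
              as.numeric(difftime(Sys.time(), t_all, units = "secs"))))
  invisible(list(out_dir = out_dir, comparison = comparison, dic = dics,
                 fits = fits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
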