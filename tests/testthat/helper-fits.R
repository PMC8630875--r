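# Shared fitted models, memoized so expensive posterior runs are computed
# once per session and reused across test files.

.fit_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# the reference synthetic study: default truth at n = 20000
big_sim <- function() {
  memo("big_sim", generate_dataset(default_truth(n_children = 20000L,
                                                 seed = 101L)))
}

# full geo-additive fit (M3) on the reference study, production-length chain
big_fit_m3 <- function() {
  memo("big_fit_m3", {
    sim <- big_sim()
    fit_geoadd(sim$data, model_spec("M3"),
               centroids = sim$geography$centroids,
               mcmc = mcmc_config(8000, 2000, 1, seed = 202L))
  })
}

# the nested comparison fits on the same data (shorter chains: the DIC gaps
# between model forms are orders of magnitude larger than Monte-Carlo error)
big_fit <- function(form) {
  memo(paste0("big_fit_", form), {
    sim <- big_sim()
    fit_geoadd(sim$data, model_spec(form),
               centroids = sim$geography$centroids,
               mcmc = mcmc_config(3000, 1000, 1, seed = 202L))
  })
}

# medium fit for summary-level module tests: reduced bases, MRF spatial
med_fit <- function() {
  memo("med_fit", {
    sim <- med_sim()
    smooth <- list(
      child_age = list(n_segments = 10L, degree = 3L, order = 2L),
      mother_age = list(n_segments = 10L, degree = 3L, order = 2L),
      breastfeed = list(n_segments = 10L, degree = 3L, order = 2L)
    )
    fit_geoadd(sim$data, model_spec("M3", smooth = smooth,
                                    spatial = list(mode = "mrf")),
               centroids = sim$geography$centroids,
               mcmc = mcmc_config(2000, 500, 1, seed = 303L))
  })
}

med_sim <- function() {
  memo("med_sim", generate_dataset(default_truth(n_children = 6000L,
                                                 seed = 104L)))
}

# 20 small-replicate refits of a reduced model, for interval-coverage checks
coverage_replicates <- function() {
  memo("coverage_replicates", {
    smooth <- list(
      child_age = list(n_segments = 8L, degree = 3L, order = 2L),
      mother_age = list(n_segments = 8L, degree = 3L, order = 2L),
      breastfeed = list(n_segments = 8L, degree = 3L, order = 2L)
    )
    lapply(1:20, function(r) {
      sim <- generate_dataset(default_truth(n_children = 5000L,
                                            seed = 500L + r))
      fit_geoadd(sim$data, model_spec("M3", smooth = smooth,
                                      spatial = list(mode = "mrf")),
                 centroids = sim$geography$centroids,
                 mcmc = mcmc_config(1500, 500, 1, seed = 600L + r))
    })
  })
}

# a tiny complete dataset for plumbing tests
tiny_sim <- function() {
  memo("tiny_sim", generate_dataset(default_truth(n_children = 800L,
                                                  n_side = 3L, seed = 42L)))
}
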