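# Shared fixtures: built in code, cached per test run.

# Compact phantom geometry for fast unit tests.
small_params <- function(...) {
  base <- list(canvas = c(48L, 64L), arc_center = c(23, 32),
               arc_radii = c(12, 20),
               thickness_profile = c(4, 2.6, 2.2, 2, 2.6, 4.4))
  do.call(phantom_params, utils::modifyList(base, list(...)))
}

# Cheap pipeline configuration for unit tests (not the study defaults).
small_config <- function(...) {
  bibs_config(utils::modifyList(
    list(prior = list(n_select = 5L, patch = 5L),
         lesre = list(n_select = 8L, search = 3L, patch = 5L, sparsity = 3L),
         bayes = list(min_calib_samples = 20L)),
    list(...)))
}

cached <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, envir = env)) assign(key, force(expr), envir = env)
    get(key, envir = env)
  }
})

small_cohort <- function(n = 8L, seed = 101L) {
  cached(sprintf("cohort_%d_%d", n, seed),
         generate_cohort(n, small_params(), seed = seed))
}

# A cohort whose members are exact copies of one atlas (consensus limit).
copies_cohort <- function(n = 5L) {
  a <- generate_phantom(small_params(seed = 5L))
  lapply(seq_len(n), function(i)
    atlas(sprintf("copy_%03d", i - 1L), a$image, a$mask))
}

# Random unit-norm dictionary for solver tests.
random_dictionary <- function(n_rows, n_cols, seed) {
  set.seed(seed)
  D <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  sweep(D, 2, sqrt(colSums(D^2)), "/")
}
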