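# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Uniform single-tissue maps on a small grid.
flat_maps <- function(t1 = 1000, t2 = 100, pd = 1, dims = c(4, 4, 2)) {
  relaxometry_maps(array(t1, dims), array(t2, dims), array(pd, dims))
}

# Small noiseless cohort used by several synthesis tests.
small_noiseless_cohort <- function() {
  fixture("small_noiseless", function() {
    generate_cohort(cohort_spec(n_subjects = 6, grid_shape = c(32, 32, 8),
                                seed = 11, noise_sigma = 0, cyst_max = 0))
  })
}

# Small noisy cohort with the planted survival signal.
small_noisy_cohort <- function() {
  fixture("small_noisy", function() {
    generate_cohort(cohort_spec(n_subjects = 14, grid_shape = c(32, 32, 10),
                                seed = 21))
  })
}

# Synthetic feature table: n rows, p noise features, optionally a planted
# feature that separates the classes perfectly.
toy_feature_table <- function(n = 120, p = 30, planted = TRUE, seed = 1) {
  set.seed(seed)
  label <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("T1w.WT.firstorder.f%02d", seq_len(p))))
  tbl <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                    label = label, X, check.names = FALSE)
  if (planted)
    tbl[["FLAIR.ED.glcm.planted"]] <- label + rnorm(n, 0, 0.01)
  tbl
}
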