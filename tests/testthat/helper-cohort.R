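# Shared fixtures, built once per test run. The default cohort uses the
# package's default group profiles (21/24/25 subjects) under a fixed seed;
# the small cohort keeps the same profiles at 6 subjects per group for
# cheaper tests.

.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(cohort_spec(), seed = 42L)
  }
  .fixtures$cohort
}

default_fm <- function() {
  if (is.null(.fixtures$fm)) {
    .fixtures$fm <- run_extract(default_cohort(), seed = 42L)
  }
  .fixtures$fm
}

small_cohort_spec <- function(n = 6L) {
  cohort_spec(profiles = list(group_profile("Healthy", n_subjects = n),
                              group_profile("KOA", n_subjects = n),
                              group_profile("TKA", n_subjects = n)))
}

# feature matrix with group separation of `delta` pooled SDs on every
# informative column, for separability / permutation-null checks
separable_matrix <- function(n_per_group = c(21L, 24L, 25L), p_inform = 5L,
                             p_noise = 8L, delta = 5, seed = 1L) {
  set.seed(seed)
  g <- factor(rep(c("Healthy", "KOA", "TKA"), n_per_group))
  n <- length(g)
  shift <- (as.integer(g) - 1) * delta
  X <- cbind(
    matrix(stats::rnorm(n * p_inform) + shift, n, p_inform),
    matrix(stats::rnorm(n * p_noise), n, p_noise)
  )
  X <- as.data.frame(X)
  names(X) <- paste0("f", seq_len(ncol(X)))
  list(x = X, y = g)
}
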