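# shared fixtures built in code

toy_kinetic <- function() {
  clonal_kinetic("toy", times = c(0, 2, 4, 6, 8), total = c(0, 10, 20, 10, 0))
}

# a small clean batch with lineages for pipeline tests
small_batch <- function(n = 6, seed = 42) {
  spec <- cohort_spec(n_clones = n, lifespan_range = c(36, 58), seed = seed)
  gen_cohort(spec)
}

# random reliability series decreasing from 1 to 0 on a common grid
random_reliability <- function(n, seed) {
  set.seed(seed)
  w <- stats::rexp(n - 1)
  c(1, 1 - cumsum(w) / sum(w))
}
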