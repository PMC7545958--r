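# shared fixtures: all built in code at test time

# small 6-item, 3-attribute Q-matrix for fast fits
tiny_qmatrix <- function() {
  validate_qmatrix(rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)))
}

tiny_design <- function(model = "DINA", pi_j = 1, I = 200L) {
  sim_design(tiny_qmatrix(), n_persons = I, model = model, pi_j = pi_j)
}

quick_chain <- function(...) {
  chain_config(n_chains = 1L, n_iter = 400L, n_burnin = 200L,
               store_deviance = FALSE, ...)
}

# chain settings used for the full-scale recovery conditions
desk_chain <- function(store_deviance = FALSE) {
  chain_config(n_chains = 2L, n_iter = 1500L, n_burnin = 500L,
               store_deviance = store_deviance)
}

# brute-force G-DINA evaluation: enumerate subsets of required
# attributes explicitly and sum the delta terms of mastered subsets
brute_gdina <- function(alpha_reduced, delta) {
  ks <- length(alpha_reduced)
  total <- 0
  for (code in 0:(2^ks - 1)) {
    members <- which(bitwAnd(code %/% 2^(seq_len(ks) - 1), 1) == 1)
    if (all(alpha_reduced[members] == 1)) total <- total + delta[code + 1]
  }
  total
}

# cache for the expensive acceptance-condition runs (shared across
# test_that blocks within one test run)
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_run <- function(key, fun) {
  if (!exists(key, envir = .acceptance_cache)) {
    assign(key, fun(), envir = .acceptance_cache)
  }
  get(key, envir = .acceptance_cache)
}
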