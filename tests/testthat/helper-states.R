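# shared fixtures built in code; cached per test run

two_wall_state <- function(q = 2, phi = c(1, 2), labels = c(1L, 0L),
                           R0 = 100 / (2 * pi), geometry = "linear") {
  frontier_state(phi, labels, q = q, R0 = R0, geometry = geometry)
}

# deterministic-bias params: strain i always beats j when force[i+1, j+1] = 1
forced_bias <- function(q, winner, loser) {
  b <- matrix(0, q, q)
  b[winner + 1, loser + 1] <- 1
  b[loser + 1, winner + 1] <- -1
  b
}

.helper_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.helper_cache[[key]])) .helper_cache[[key]] <- force(expr)
  .helper_cache[[key]]
}

# a small neutral q = 3 ensemble reused across observable tests
small_neutral3 <- function() cached("neutral3", {
  p <- sim_params(n0 = 600, q = 3, geometry = "radial",
                  snapshot_lengths = c(20, 60))
  run_ensemble(p, 60, 101, n_bins = 200)
})
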