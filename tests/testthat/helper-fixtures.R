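# Small fixtures for unit tests. The acceptance tests use the full
# study-scale network (N_E = 1000); unit tests use a reduced net that
# preserves the structure (fixed in-degrees, g = 6, Poisson drive).

tiny_spec <- function(J = 0.85, g = 6)
  network_spec(N_E = 200, N_I = 50, epsilon = 0.1, g = g, J = J)

tiny_drive <- function(nu_X = 5.42)
  external_drive(p = 250, nu_X = nu_X, K_X_out = 100, J_X = 0.85)

tiny_net <- function(seed = 1, J = 0.85, g = 6)
  build_network(tiny_spec(J, g), neuron_params(), tiny_drive(), seed = seed)

# Independent stationary Poisson spike set (control for CV/FF tests).
poisson_spikes <- function(n = 50, rate = 10, T = 20000, seed = 1) {
  withr::with_seed(seed, {
    times <- ids <- c()
    for (i in seq_len(n)) {
      k <- rpois(1, rate * T / 1000)
      times <- c(times, sort(runif(k, 0, T)))
      ids <- c(ids, rep(i, k))
    }
    spike_data(times, ids, n, T)
  })
}

# Cache for expensive shared computations within one test run.
.lifnet_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .lifnet_cache))
    assign(key, expr, envir = .lifnet_cache)
  get(key, envir = .lifnet_cache)
}
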