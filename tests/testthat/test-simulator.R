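# A two-neuron probe: one synapse from neuron 1 to neuron 2, driven by a
# single hand-written external spike onto neuron 1 (or directly onto 2).
probe_net <- function(J = 0.85, J_X = 25) {
  spec <- network_spec(N_E = 4, N_I = 1, epsilon = 0.01, J = J, g = 6)
  dr <- external_drive(p = 1, nu_X = 0, K_X_out = 1, J_X = J_X)
  net <- build_network(spec, neuron_params(), dr, seed = 1)
  net$synapses <- data.frame(source = 1L, target = 2L, weight = J)
  net$external_map <- list(1L)
  net
}

test_that("PSC amplitude reproduces the PSP peak in simulation", {
  nrn <- neuron_params()
  # closed form: zero weight -> zero current; linearity
  expect_equal(psc_amplitude_from_psp(0, nrn), 0)
  expect_equal(psc_amplitude_from_psp(2 * 0.85, nrn),
               2 * psc_amplitude_from_psp(0.85, nrn))
  expect_error(psc_amplitude_from_psp(1, neuron_params(tau_s = 19.99, tau_m = 20)),
               NA)
  # simulated PSP of a sub-threshold synapse peaks at J
  net <- probe_net(J = 0.85, J_X = 5)
  ext <- list(50)  # one external spike onto neuron 1 (5 mV, stays silent)
  cfg <- sim_config(duration = 300, seed = 1, dt = 0.01)
  res <- simulate_network(net, cfg, ext_input = ext, v_init = 0,
                          record_v = 1:2, return_state = TRUE)
  expect_length(res$spikes$times, 0)
  expect_equal(max(res$v_trace[, 1]), 5, tolerance = 1e-4)
  # drive neuron 1 over threshold; neuron 2 sees a PSP peaking at J
  net2 <- probe_net(J = 0.85, J_X = 25)
  res2 <- simulate_network(net2, cfg, ext_input = ext, v_init = 0,
                           record_v = 1:2, return_state = TRUE)
  expect_length(res2$spikes$times, 1)
  expect_equal(res2$spikes$ids, 1L)
  expect_equal(max(res2$v_trace[, 2]), 0.85, tolerance = 1e-3)
})

test_that("rescaled weight equals tau_s * I_hat / C_m", {
  nrn <- neuron_params()
  expect_equal(rescaled_weight(0.85, nrn),
               nrn$tau_s * psc_amplitude_from_psp(0.85, nrn) / nrn$C_m)
})

test_that("subthreshold responses superpose linearly", {
  net <- probe_net(J_X = 3)
  cfg <- sim_config(duration = 400, seed = 1)
  va <- simulate_network(net, cfg, ext_input = list(50), v_init = 0,
                         record_v = 1, return_state = TRUE)$v_trace
  vb <- simulate_network(net, cfg, ext_input = list(150), v_init = 0,
                         record_v = 1, return_state = TRUE)$v_trace
  vab <- simulate_network(net, cfg, ext_input = list(c(50, 150)), v_init = 0,
                          record_v = 1, return_state = TRUE)$v_trace
  expect_equal(vab, va + vb, tolerance = 1e-12)
})

test_that("zero drive and zero initial potentials give no spikes", {
  net <- tiny_net(seed = 1)
  net$drive$nu_X <- 0
  sp <- simulate_network(net, sim_config(duration = 500, seed = 2), v_init = 0)
  expect_length(sp$times, 0)
})

test_that("twin runs are bit-identical and refractoriness is enforced", {
  net <- tiny_net(seed = 4)
  cfg <- sim_config(duration = 2000, seed = 6)
  a <- simulate_network(net, cfg)
  b <- simulate_network(net, cfg)
  expect_identical(a, b)
  expect_gt(length(a$times), 0)
  isi <- unlist(lapply(spike_trains(a), diff))
  if (length(isi)) expect_true(all(isi >= net$neuron$tau_ref))
  expect_true(all(a$times > 0 & a$times <= a$T))
})

test_that("chunked simulation with carried state matches a single run", {
  net <- tiny_net(seed = 4)
  full_cfg <- sim_config(duration = 1000, seed = 6)
  ext <- generate_external_input(net$drive, 1000, seed = full_cfg$seed)
  full <- simulate_network(net, full_cfg, ext_input = ext)
  # same external spikes split into two 500 ms chunks
  chunk_cfg <- sim_config(duration = 500, seed = full_cfg$seed)
  ext1 <- lapply(ext, function(t) t[t <= 500])
  ext2 <- lapply(ext, function(t) t[t > 500] - 500)
  r1 <- simulate_network(net, chunk_cfg, ext_input = ext1,
                         v_init = withr::with_seed(
                           lifnet:::derive_seed(full_cfg$seed, "vinit"),
                           runif(net$spec$N, 0, 20)),
                         return_state = TRUE)
  r2 <- simulate_network(net, chunk_cfg, ext_input = ext2,
                         state = r1$state, t0 = 500, return_state = TRUE)
  times <- c(r1$spikes$times, r2$spikes$times)
  ids <- c(r1$spikes$ids, r2$spikes$ids)
  expect_equal(times, full$times, tolerance = 1e-9)
  expect_identical(ids, full$ids)
})

test_that("halving dt changes the population rate only slightly", {
  net <- tiny_net(seed = 9)
  ext <- generate_external_input(net$drive, 5000, seed = 31)
  r1 <- population_rate(simulate_network(
    net, sim_config(duration = 5000, seed = 31, dt = 0.1),
    ext_input = ext, v_init = 10), window = c(100, 5000))
  r2 <- population_rate(simulate_network(
    net, sim_config(duration = 5000, seed = 31, dt = 0.05),
    ext_input = ext, v_init = 10), window = c(100, 5000))
  expect_gt(r1, 0)
  expect_lt(abs(r2 - r1) / r1, 0.1)
})

test_that("spike files round-trip exactly", {
  net <- tiny_net(seed = 4)
  sp <- simulate_network(net, sim_config(duration = 1000, seed = 6))
  path <- withr::local_tempfile(fileext = ".dat")
  write_spikes(sp, path)
  back <- read_spikes(path)
  expect_identical(back$times, sp$times)
  expect_identical(back$ids, sp$ids)
  expect_identical(back$N, sp$N)
  # empty spike data round-trips too
  write_spikes(spike_data(numeric(0), integer(0), 5, 100), path)
  expect_length(read_spikes(path)$times, 0)
})

test_that("a diverging membrane potential is reported, not silently kept", {
  net <- probe_net(J_X = 25)
  # an absurdly strong inhibitory synapse drives the target towards -Inf
  net$synapses <- data.frame(source = 5L, target = 2L, weight = -1e307)
  net$external_map <- list(5L)
  expect_error(
    simulate_network(net, sim_config(duration = 500, seed = 1),
                     ext_input = list(seq(10, 490, 5)), v_init = 0),
    "diverged")
})
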