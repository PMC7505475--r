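#' Simulation configuration
#'
#' @param duration observation time (ms); the simulation runs on
#'   `[0, duration]`
#' @param dt integration step (ms); must divide the synaptic delay
#' @param t_transient warm-up interval (ms) that measurement protocols
#'   discard before computing statistics
#' @param seed integer seed governing initial membrane potentials and the
#'   external input realization
#' @return an object of class `sim_config`
#' @export
sim_config <- function(duration, dt = 0.1, t_transient = 100, seed = 1) {
  stopifnot(duration > 0, dt > 0, t_transient >= 0)
  structure(list(duration = duration, dt = dt, t_transient = t_transient,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Single-spike perturbation
#'
#' Describes the twin-simulation perturbation: the spike of external source
#' `source_id` closest to `t_star` is delayed by `delta_t`; all other
#' external spikes are identical between the two runs.
#'
#' @param source_id index of the perturbed external source
#' @param t_star nominal time of the perturbed spike (ms)
#' @param delta_t delay applied to it (ms), `> 0`
#' @return an object of class `perturbation`
#' @export
perturbation <- function(source_id = 1, t_star = 400, delta_t = 0.5) {
  stopifnot(delta_t >= 0, t_star >= 0, source_id >= 1)
  structure(list(source_id = as.integer(source_id), t_star = t_star,
                 delta_t = delta_t),
            class = "perturbation")
}

#' PSC amplitude from PSP peak
#'
#' Synaptic weights are parameterized by the peak amplitude `J` (mV) of the
#' postsynaptic potential. For exponential postsynaptic currents the PSP is
#' a double exponential peaking at
#' `t_max = tau_m tau_s / (tau_m - tau_s) * log(tau_m / tau_s)`; this
#' returns the current amplitude `I_hat` (pA) whose PSP peaks exactly at
#' `J`.
#'
#' @param J PSP peak amplitude(s) (mV); may be a vector
#' @param neuron a [neuron_params()]
#' @return PSC amplitude(s) in pA
#' @seealso [rescaled_weight()] for the mean-field weight
#'   `J_hat = tau_s * I_hat / C_m`
#' @export
psc_amplitude_from_psp <- function(J, neuron = neuron_params()) {
  tm <- neuron$tau_m; ts <- neuron$tau_s
  if (ts >= tm) stop("degenerate PSC kernel: tau_s must be < tau_m")
  tmax <- tm * ts / (tm - ts) * log(tm / ts)
  peak_per_pA <- tm * ts / ((tm - ts) * neuron$C_m) *
    (exp(-tmax / tm) - exp(-tmax / ts))
  J / peak_per_pA
}

#' Rescaled synaptic weight for the mean-field theory
#'
#' `J_hat = tau_s * I_hat / C_m` (mV), the weight entering the
#' diffusion-approximation input moments.
#'
#' @inheritParams psc_amplitude_from_psp
#' @return rescaled weight(s) in mV
#' @export
rescaled_weight <- function(J, neuron = neuron_params()) {
  neuron$tau_s * psc_amplitude_from_psp(J, neuron) / neuron$C_m
}

#' Spike data container
#'
#' @param times spike times (ms), sorted ascending
#' @param ids neuron ids (1-based), parallel to `times`
#' @param N number of neurons
#' @param T observation window length (ms)
#' @return an object of class `spike_data`
#' @export
spike_data <- function(times, ids, N, T) {
  o <- order(times, ids)
  structure(list(times = times[o], ids = as.integer(ids[o]),
                 N = as.integer(N), T = T),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d spikes, N=%d, T=%g ms (%.3g spikes/s)\n",
              length(x$times), x$N, x$T,
              1000 * length(x$times) / (x$N * x$T)))
  invisible(x)
}

#' Per-neuron spike-time lists
#'
#' @param spikes a [spike_data()]
#' @return a list of `N` numeric vectors of spike times
#' @export
spike_trains <- function(spikes) {
  out <- rep(list(numeric(0)), spikes$N)
  if (length(spikes$times)) {
    sp <- split(spikes$times, spikes$ids)
    out[as.integer(names(sp))] <- sp
  }
  out
}

apply_perturbation <- function(trains, pert) {
  tr <- trains[[pert$source_id]]
  if (length(tr) == 0)
    stop("perturbed source emits no spikes; cannot apply perturbation")
  k <- which.min(abs(tr - pert$t_star))
  tr[k] <- tr[k] + pert$delta_t
  trains[[pert$source_id]] <- sort(tr)
  trains
}

csr_from_synapses <- function(net) {
  syn <- net$synapses
  o <- order(syn$source, syn$target)
  src <- syn$source[o]
  ptr <- c(0L, cumsum(tabulate(src, nbins = net$spec$N)))
  list(ptr = as.integer(ptr), tgt = as.integer(syn$target[o] - 1L),
       amp = psc_amplitude_from_psp(syn$weight[o], net$neuron))
}

# external spikes are delivered at the grid step containing the spike time
# (the synaptic delay applies to recurrent spikes; for stationary Poisson
# sources a delay is an irrelevant shift of the time origin)
ext_events <- function(trains, dt, nsteps) {
  n_per <- lengths(trains)
  tms <- unlist(trains, use.names = FALSE)
  src <- rep.int(seq_along(trains), n_per)
  astep <- as.integer(floor(tms / dt))
  keep <- astep < nsteps
  o <- order(astep[keep])
  list(astep = astep[keep][o], src = as.integer(src[keep][o] - 1L))
}

#' Simulate a network realization
#'
#' Clock-driven integration of the LIF network with exponential
#' postsynaptic currents (exact subthreshold propagator per step, spikes
#' and current jumps constrained to the grid). Initial membrane potentials
#' are drawn uniformly between reset and threshold from the configuration
#' seed, so twin runs with identical seeds have identical initial
#' conditions and external inputs; with a [perturbation()], the external
#' input differs only in the one delayed spike.
#'
#' @param net a [build_network()] realization
#' @param config a [sim_config()]
#' @param perturb optional [perturbation()]
#' @param ext_input optional pre-generated external input (list of spike
#'   trains per source, as from [generate_external_input()]); defaults to
#'   trains generated from the configuration seed
#' @param state optional continuation state from a previous call (see
#'   `return_state`)
#' @param record_v optional vector of neuron ids whose membrane potential
#'   trace is recorded
#' @param v_init optional vector of initial membrane potentials (mV);
#'   default drawn uniformly between reset and threshold from the seed
#' @param t0 time offset (ms) added to returned spike times
#' @param return_state if `TRUE`, also return the final integrator state
#'   for exact continuation
#' @return a [spike_data()] object; with `return_state = TRUE` a list
#'   `(spikes, state, v_trace)`
#' @export
simulate_network <- function(net, config, perturb = NULL, ext_input = NULL,
                             state = NULL, record_v = NULL, v_init = NULL,
                             t0 = 0, return_state = FALSE) {
  spec <- net$spec; nrn <- net$neuron
  dt <- config$dt
  delay_steps <- as.integer(round(spec$delay / dt))
  if (abs(delay_steps * dt - spec$delay) > 1e-9)
    stop("dt must divide the synaptic delay")
  nsteps <- as.integer(round(config$duration / dt))
  if (is.null(ext_input))
    ext_input <- generate_external_input(net$drive, config$duration,
                                         seed = config$seed)
  if (!is.null(perturb))
    ext_input <- apply_perturbation(ext_input, perturb)
  ev <- ext_events(ext_input, dt, nsteps)
  ext_ptr <- c(0L, cumsum(lengths(net$external_map)))
  ext_tgt <- as.integer(unlist(net$external_map, use.names = FALSE) - 1L)
  csr <- csr_from_synapses(net)
  v0 <- if (!is.null(v_init)) {
    rep_len(v_init, spec$N)
  } else if (is.null(state)) {
    withr::with_seed(derive_seed(config$seed, "vinit"),
                     runif(spec$N, nrn$V_r, nrn$theta))
  } else numeric(spec$N)  # overwritten by state inside the C++ core
  res <- simulate_lif_cpp(
    n = spec$N, v0 = v0,
    syn_ptr = csr$ptr, syn_tgt = csr$tgt, syn_amp = csr$amp,
    ext_astep = ev$astep, ext_src = ev$src,
    ext_ptr = as.integer(ext_ptr), ext_tgt = ext_tgt,
    ext_amp = psc_amplitude_from_psp(net$drive$J_X, nrn),
    steps = nsteps, dt = dt, tau_m = nrn$tau_m, tau_s = nrn$tau_s,
    c_m = nrn$C_m, v_r = nrn$V_r, theta = nrn$theta,
    ref_steps = as.integer(round(nrn$tau_ref / dt)),
    delay_steps = delay_steps, t0 = t0, step0 = round(t0 / dt),
    state = state,
    record_v = as.integer((record_v %||% integer(0)) - 1L))
  spikes <- spike_data(res$times, res$ids, spec$N, config$duration)
  if (return_state)
    list(spikes = spikes, state = res$state, v_trace = res$v_trace)
  else spikes
}

#' Write spikes as a two-column text table
#'
#' gdf-style format: one line per spike, `time_ms neuron_id`, sorted by
#' time. Round-trips exactly.
#'
#' @param spikes a [spike_data()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_spikes <- function(spikes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lifnet spikes N %d T %.17g", spikes$N, spikes$T),
             con)
  writeLines(sprintf("%.17g %d", spikes$times, spikes$ids), con)
  invisible(path)
}

#' Read spikes written by [write_spikes()]
#'
#' @param path file path
#' @return a [spike_data()]
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(lines[1], " ")[[1]]
  N <- as.integer(hd[5]); T <- as.numeric(hd[7])
  body <- lines[-1]
  if (length(body) == 0) return(spike_data(numeric(0), integer(0), N, T))
  parts <- strsplit(body, " ", fixed = TRUE)
  spike_data(as.numeric(vapply(parts, `[`, "", 1)),
             as.integer(vapply(parts, `[`, "", 2)), N, T)
}
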