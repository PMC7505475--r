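#' Low-pass filter configuration
#'
#' Filtered signals are `x_i(t) = sum_k exp(-(t - t_ik)/tau_f)` for spikes
#' `t_ik <= t`, sampled every `delta_t_f`. The sampling resolution of 1 ms
#' is the resolution at which perturbed and unperturbed spike patterns are
#' compared; the filter time constant defaults to a membrane-scale 20 ms.
#'
#' @param tau_f exponential kernel time constant (ms)
#' @param delta_t_f sampling resolution (ms)
#' @return an object of class `filter_config`
#' @export
filter_config <- function(tau_f = 20, delta_t_f = 1) {
  stopifnot(tau_f > 0, delta_t_f > 0)
  structure(list(tau_f = tau_f, delta_t_f = delta_t_f),
            class = "filter_config")
}

clip_window <- function(spikes, window) {
  if (is.null(window)) return(spikes)
  keep <- spikes$times > window[1] & spikes$times <= window[2]
  spike_data(spikes$times[keep] - window[1], spikes$ids[keep], spikes$N,
             diff(window))
}

#' Time- and population-averaged firing rate
#'
#' Total spike count in the window, normalized by network size and window
#' length: `nu = (N T)^-1 sum_i n_i`.
#'
#' @param spikes a [spike_data()]
#' @param window optional `c(from, to)` (ms); default the full `[0, T]`
#' @param ids optional subset of neuron ids over which to average (e.g. the
#'   excitatory population)
#' @return rate in spikes/s
#' @export
population_rate <- function(spikes, window = NULL, ids = NULL) {
  Tw <- if (is.null(window)) spikes$T else diff(window)
  n <- if (is.null(ids)) spikes$N else length(ids)
  tms <- spikes$times
  keep <- rep(TRUE, length(tms))
  if (!is.null(window)) keep <- tms > window[1] & tms <= window[2]
  if (!is.null(ids)) keep <- keep & spikes$ids %in% ids
  1000 * sum(keep) / (n * Tw)
}

#' Population-averaged coefficient of variation of inter-spike intervals
#'
#' `CV_i = SD(tau_ik) / mean(tau_ik)` per neuron, averaged over all neurons
#' with at least two spikes in the window. The SD uses the population
#' (1/n) variance convention. If no neuron is eligible the result is
#' undefined and an error of class `lifnet_undefined` is signalled.
#'
#' @inheritParams population_rate
#' @return dimensionless population-average CV
#' @export
isi_cv <- function(spikes, window = NULL) {
  sp <- clip_window(spikes, window)
  cvs <- vapply(spike_trains(sp), function(tr) {
    if (length(tr) < 2) return(NA_real_)
    isi <- diff(tr)
    m <- mean(isi)
    s <- sqrt(mean((isi - m)^2))
    s / m
  }, numeric(1))
  if (all(is.na(cvs)))
    stop_undefined("CV undefined: no neuron emitted two or more spikes")
  mean(cvs, na.rm = TRUE)
}

#' Fano factor of the population spike count
#'
#' `FF(b) = Var_t(n(t;b)) / mean_t(n(t;b))` for the population spike count
#' in disjoint bins of width `b` (population-variance convention). FF = 1
#' for independent stationary Poisson trains; larger values indicate
#' synchrony on the time scale `b`.
#'
#' @inheritParams population_rate
#' @param b bin width (ms)
#' @return dimensionless Fano factor
#' @export
population_fano <- function(spikes, b = 10, window = NULL) {
  sp <- clip_window(spikes, window)
  nb <- floor(sp$T / b)
  if (nb < 2)
    stop("observation window must cover at least 2 bins")
  if (nb < 10)
    warning("fewer than 10 bins; the Fano factor estimate is crude")
  idx <- floor(sp$times / b) + 1
  counts <- tabulate(idx[idx <= nb], nbins = nb)
  m <- mean(counts)
  if (m == 0)
    stop_undefined("Fano factor undefined: zero mean population count")
  mean((counts - m)^2) / m
}

#' Low-pass filtered spike signals
#'
#' Convolves every spike train with the exponential kernel
#' `h(t) = exp(-t/tau_f)` for `t >= 0` and samples the result every
#' `delta_t_f`.
#'
#' @param spikes a [spike_data()]
#' @param cfg a [filter_config()]
#' @return a matrix with one row per sample time (`delta_t_f, 2 delta_t_f,
#'   ...`) and one column per neuron; sample times in `rownames`
#' @export
low_pass_filter <- function(spikes, cfg = filter_config()) {
  m <- lowpass_filter_cpp(spikes$times, spikes$ids, spikes$N, spikes$T,
                          cfg$tau_f, cfg$delta_t_f)
  rownames(m) <- sprintf("%g", seq_len(nrow(m)) * cfg$delta_t_f)
  m
}

#' E/I balance of synaptic input currents
#'
#' Per target population, the magnitude ratio of summed excitatory to
#' summed inhibitory recurrent input currents,
#' `B_E = |J_EE K_EE nu_E| / |J_EI K_EI nu_I|` (and analogously `B_I`);
#' the network balance is the population-size-weighted average
#' `B = (N_E B_E + N_I B_I) / N`. Magnitudes are used so that `B > 0`.
#'
#' @param net a `network_realization`
#' @param nu_E excitatory population rate (spikes/s)
#' @param nu_I inhibitory population rate (spikes/s)
#' @return a list with `B`, `B_E`, `B_I`
#' @export
ei_balance <- function(net, nu_E, nu_I) {
  s <- net$spec
  if (nu_I <= 0 || s$Jw["E", "I"] == 0)
    stop_undefined("E/I balance undefined: zero inhibitory drive")
  B_E <- abs(s$Jw["E", "E"] * s$K["E", "E"] * nu_E) /
    abs(s$Jw["E", "I"] * s$K["E", "I"] * nu_I)
  B_I <- abs(s$Jw["I", "E"] * s$K["I", "E"] * nu_E) /
    abs(s$Jw["I", "I"] * s$K["I", "I"] * nu_I)
  list(B = (s$N_E * B_E + s$N_I * B_I) / s$N, B_E = B_E, B_I = B_I)
}

#' Relative total synaptic contact area (rTSCA)
#'
#' The total synaptic contact area of the EE synapses is modeled as the
#' product `K_EE * J_EE` of in-degree and weight; the relative TSCA is its
#' ratio between a (degenerated, possibly homeostatically rescaled)
#' network and the intact reference.
#'
#' @param net a `network_realization`
#' @param reference the intact reference `network_realization`
#' @return dimensionless ratio
#' @export
relative_tsca <- function(net, reference) {
  ref <- reference$spec$K["E", "E"] * reference$spec$Jw["E", "E"]
  if (ref == 0)
    stop("reference network has zero EE contact area")
  net$spec$K["E", "E"] * net$spec$Jw["E", "E"] / ref
}

#' Summary of network activity
#'
#' Convenience wrapper computing the scalar statistics of one simulation:
#' rate, CV, Fano factor, E/I balance and rTSCA.
#'
#' @param net a `network_realization`
#' @param spikes a [spike_data()] from simulating `net`
#' @param reference intact reference network for the rTSCA (default `net`)
#' @param b Fano-factor bin width (ms)
#' @param window optional measurement window (ms)
#' @return a one-row `data.frame` with columns `nu`, `nu_E`, `nu_I`, `CV`,
#'   `FF`, `B`, `rTSCA`
#' @export
activity_summary <- function(net, spikes, reference = net, b = 10,
                             window = NULL) {
  s <- net$spec
  nu_E <- population_rate(spikes, window, ids = seq_len(s$N_E))
  nu_I <- population_rate(spikes, window, ids = s$N_E + seq_len(s$N_I))
  safe <- function(expr) tryCatch(expr, lifnet_undefined = function(e) NA_real_)
  data.frame(nu = population_rate(spikes, window), nu_E = nu_E, nu_I = nu_I,
             CV = safe(isi_cv(spikes, window)),
             FF = safe(population_fano(spikes, b, window)),
             B = safe(ei_balance(net, nu_E, nu_I)$B),
             rTSCA = relative_tsca(net, reference))
}
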