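#' Neuron parameters
#'
#' Membrane and synapse parameters of the leaky integrate-and-fire (LIF)
#' neuron with exponential postsynaptic currents. All neurons in a network
#' are identical. The defaults are standard for this model class:
#' a 20 ms membrane, a 2 ms synaptic current (fast compared to the
#' membrane, as the mean-field theory assumes, yet slow enough that the
#' recurrent dynamics can become chaotic rather than pulse-coupled), a
#' 2 ms absolute refractory period and a 20 mV distance between reset and
#' threshold.
#'
#' @param tau_m membrane time constant (ms)
#' @param tau_s synaptic (PSC) time constant (ms)
#' @param tau_ref absolute refractory period (ms)
#' @param C_m membrane capacitance (pF)
#' @param V_r reset potential (mV)
#' @param theta firing threshold (mV)
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(tau_m = 20, tau_s = 2, tau_ref = 2,
                          C_m = 250, V_r = 0, theta = 20) {
  stopifnot(tau_m > 0, tau_s > 0, tau_ref >= 0, C_m > 0)
  if (tau_s >= tau_m)
    stop("tau_s must be smaller than tau_m")
  if (theta <= V_r)
    stop("threshold theta must exceed the reset potential V_r")
  structure(list(tau_m = tau_m, tau_s = tau_s, tau_ref = tau_ref,
                 C_m = C_m, V_r = V_r, theta = theta),
            class = "neuron_params")
}

#' Network specification
#'
#' Describes the intact two-population (excitatory/inhibitory) random
#' network: population sizes, fixed in-degrees derived from the connection
#' probability `epsilon`, and the reference synaptic weight `J` (EPSP peak
#' amplitude in mV). Inhibitory weights are `-g * J`; `g = 6` makes the
#' network inhibition-dominated so that it can fire asynchronously and
#' irregularly at low rates.
#'
#' The in-degrees are `K_EE = K_IE = epsilon * N_E` and
#' `K_EI = K_II = epsilon * N_I` for every neuron. Current (possibly
#' protocol-modified) values of the EE in-degree and of the four weights are
#' tracked in the fields `K` (2x2 matrix, rows = target population E/I,
#' columns = source population) and `Jw` (same layout, mV).
#'
#' @param N_E number of excitatory neurons
#' @param epsilon connection probability defining the in-degrees
#' @param g relative strength of inhibitory weights (dimensionless)
#' @param J reference synaptic weight (mV, PSP peak amplitude)
#' @param delay synaptic transmission delay (ms)
#' @param N_I number of inhibitory neurons (default `N_E / 4`)
#' @return an object of class `network_spec`
#' @export
network_spec <- function(N_E = 1000, epsilon = 0.1, g = 6, J = 0.85,
                         delay = 1, N_I = N_E / 4) {
  stopifnot(N_E >= 2, N_I >= 1, epsilon > 0, epsilon <= 1, g >= 0,
            J >= 0, delay > 0)
  N_I <- as.integer(round(N_I))
  N_E <- as.integer(N_E)
  K <- matrix(c(round(epsilon * N_E), round(epsilon * N_E),
                round(epsilon * N_I), round(epsilon * N_I)),
              2, 2, dimnames = list(target = c("E", "I"),
                                    source = c("E", "I")))
  Jw <- matrix(c(J, J, -g * J, -g * J), 2, 2,
               dimnames = dimnames(K))
  if (any(K[, "E"] > N_E - 1) || any(K[, "I"] > N_I))
    stop("in-degree exceeds available source-population size")
  structure(list(N_E = N_E, N_I = N_I, N = N_E + N_I, epsilon = epsilon,
                 g = g, J = J, delay = delay, K = K, Jw = Jw),
            class = "network_spec")
}

#' External Poisson drive
#'
#' The network is driven by an ensemble of `p` independent Poissonian spike
#' trains of rate `nu_X`; each train projects with weight `J_X` onto
#' `K_X_out` randomly selected neurons (excitatory and inhibitory alike), so
#' the average external in-degree is `K_X = p * K_X_out / N`.
#'
#' The default source rate is the package's calibration for the default
#' network: it makes the intact reference network at `J = 0.85` mV fire at
#' the 1.2 spikes/s working point (see [calibrate_drive()] to recompute it
#' for modified parameters).
#'
#' @param p number of independent external Poisson sources
#' @param nu_X rate of each source (spikes/s)
#' @param K_X_out number of target neurons per source
#' @param J_X weight of external synapses (mV, PSP peak)
#' @return an object of class `external_drive`
#' @export
external_drive <- function(p = 1250, nu_X = 5.42, K_X_out = 100, J_X = 0.85) {
  stopifnot(p >= 1, nu_X >= 0, K_X_out >= 1, J_X >= 0)
  structure(list(p = as.integer(p), nu_X = nu_X,
                 K_X_out = as.integer(K_X_out), J_X = J_X),
            class = "external_drive")
}

#' Average external in-degree
#'
#' @param drive an [external_drive()]
#' @param N network size
#' @return `p * K_X_out / N`
#' @export
external_indegree <- function(drive, N) drive$p * drive$K_X_out / N

pop_of <- function(ids, spec) ifelse(ids <= spec$N_E, "E", "I")

sample_sources <- function(pool, k, exclude = NULL) {
  if (!is.null(exclude)) pool <- pool[pool != exclude]
  if (k > length(pool))
    stop("in-degree exceeds available source-population size minus one")
  if (k == 0L) integer(0) else pool[sample.int(length(pool), k)]
}

#' Build a network realization
#'
#' Draws a concrete random connectivity realization: every excitatory
#' (inhibitory) neuron receives exactly `K_EE` (`K_IE`) excitatory and
#' `K_EI` (`K_II`) inhibitory presynaptic partners, sampled uniformly
#' without replacement and excluding the neuron itself (no autapses, no
#' multapses in the initial wiring). Each external source is assigned
#' `K_X_out` distinct targets. Neurons `1..N_E` are excitatory,
#' `N_E+1..N` inhibitory.
#'
#' Identical seeds give bit-identical realizations.
#'
#' @param spec a [network_spec()]
#' @param neuron a [neuron_params()]
#' @param drive an [external_drive()]
#' @param seed integer RNG seed
#' @return an object of class `network_realization` with fields `spec`,
#'   `neuron`, `drive`, `synapses` (data frame `source`, `target`,
#'   `weight` in mV), `external_map` (list of target-id vectors per
#'   source) and `seed`
#' @export
build_network <- function(spec = network_spec(), neuron = neuron_params(),
                          drive = external_drive(), seed = 1) {
  exc <- seq_len(spec$N_E)
  inh <- spec$N_E + seq_len(spec$N_I)
  syn <- withr::with_seed(derive_seed(seed, "wiring"), {
    src <- vector("list", spec$N)
    for (i in seq_len(spec$N)) {
      tp <- if (i <= spec$N_E) "E" else "I"
      se <- sample_sources(exc, spec$K[tp, "E"], exclude = i)
      si <- sample_sources(inh, spec$K[tp, "I"], exclude = i)
      src[[i]] <- c(se, si)
    }
    nin <- lengths(src)
    data.frame(source = unlist(src),
               target = rep.int(seq_len(spec$N), nin))
  })
  tp <- pop_of(syn$target, spec)
  sp <- pop_of(syn$source, spec)
  syn$weight <- spec$Jw[cbind(tp, sp)]
  extmap_seed <- derive_seed(seed, "extmap")
  external_map <- withr::with_seed(extmap_seed, {
    lapply(seq_len(drive$p),
           function(s) sort(sample.int(spec$N, drive$K_X_out)))
  })
  structure(list(spec = spec, neuron = neuron, drive = drive,
                 synapses = syn, external_map = external_map,
                 seed = as.integer(seed), extmap_seed = extmap_seed),
            class = "network_realization")
}

#' @export
print.network_realization <- function(x, ...) {
  cat(sprintf(paste0("<network_realization> N_E=%d N_I=%d  K_EE=%d  ",
                     "J=%.4g mV  J_EE=%.4g mV  g=%g  seed=%d\n"),
              x$spec$N_E, x$spec$N_I, x$spec$K["E", "E"], x$spec$J,
              x$spec$Jw["E", "E"], x$spec$g, x$seed))
  cat(sprintf("  %d synapses, %d external sources (nu_X=%.4g spikes/s)\n",
              nrow(x$synapses), x$drive$p, x$drive$nu_X))
  invisible(x)
}

ee_rows <- function(net) {
  net$synapses$source <= net$spec$N_E & net$synapses$target <= net$spec$N_E
}

current_jee <- function(net) {
  w <- unique(net$synapses$weight[ee_rows(net)])
  if (length(w) > 1) return(NA_real_)
  if (length(w) == 0) return(net$spec$Jw["E", "E"])
  w
}

#' Remove EE synapses (synapse-loss protocol)
#'
#' Models neurodegeneration as a reduction of the in-degree of
#' excitatory-to-excitatory (EE) synapses: the EE wiring is redrawn from
#' scratch at the reduced in-degree `round(K_EE * (1 - loss_fraction))`
#' (round half to even). All EI, IE and II synapses as well as all synaptic
#' weights are untouched. A `"subset"` mode that deletes a random subset of
#' the existing EE synapses instead of redrawing is available for
#' robustness checks.
#'
#' @param net a [build_network()] realization
#' @param loss_fraction fraction of EE synapses to remove, in `[0, 1]`,
#'   relative to the current EE in-degree of `net`
#' @param seed integer seed for the redraw
#' @param mode `"redraw"` (default) or `"subset"`
#' @return the modified `network_realization`
#' @export
apply_ee_loss <- function(net, loss_fraction, seed = net$seed + 1,
                          mode = c("redraw", "subset")) {
  mode <- match.arg(mode)
  stopifnot(loss_fraction >= 0, loss_fraction <= 1)
  spec <- net$spec
  k_new <- as.integer(round(spec$K["E", "E"] * (1 - loss_fraction)))
  jee <- current_jee(net)
  if (is.na(jee))
    stop("EE weights are not uniform; redrawing EE wiring is ill-defined")
  keep <- !ee_rows(net)
  if (mode == "redraw") {
    exc <- seq_len(spec$N_E)
    new_syn <- withr::with_seed(derive_seed(seed, "ee-redraw"), {
      src <- lapply(seq_len(spec$N_E),
                    function(i) sample_sources(exc, k_new, exclude = i))
      srcv <- as.integer(unlist(src, use.names = FALSE))
      data.frame(source = srcv,
                 target = rep.int(seq_len(spec$N_E), lengths(src)),
                 weight = rep_len(jee, length(srcv)))
    })
  } else {
    old <- net$synapses[!keep, , drop = FALSE]
    new_syn <- withr::with_seed(derive_seed(seed, "ee-subset"), {
      kept <- unlist(lapply(split(seq_len(nrow(old)), old$target),
                            function(idx) idx[sample.int(length(idx),
                                                         min(k_new, length(idx)))]))
      old[sort(kept), , drop = FALSE]
    })
  }
  net$synapses <- rbind(net$synapses[keep, , drop = FALSE], new_syn)
  rownames(net$synapses) <- NULL
  net$spec$K["E", "E"] <- k_new
  net
}

#' Scale the weights of EE synapses
#'
#' Multiplies all excitatory-to-excitatory weights by `factor`, leaving
#' `J_IE`, `J_EI` and `J_II` unchanged. Used both by the firing-rate
#' homeostasis (upscaling of remaining EE synapses) and by the
#' hyperactivity protocol (`J_EE > J_IE`).
#'
#' @param net a `network_realization`
#' @param factor dimensionless scale factor, `>= 0`
#' @return the modified `network_realization`
#' @export
scale_ee_weights <- function(net, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0)
    stop("factor must be a single non-negative number")
  r <- ee_rows(net)
  net$synapses$weight[r] <- net$synapses$weight[r] * factor
  net$spec$Jw["E", "E"] <- net$spec$Jw["E", "E"] * factor
  net
}

#' Set the EE weight to an absolute value
#'
#' @param net a `network_realization`
#' @param J_EE new EE weight (mV)
#' @return the modified `network_realization`
#' @export
set_ee_weight <- function(net, J_EE) {
  stopifnot(J_EE >= 0)
  r <- ee_rows(net)
  net$synapses$weight[r] <- J_EE
  net$spec$Jw["E", "E"] <- J_EE
  net
}

#' Generate external Poisson input
#'
#' Draws, for each of the `p` external sources, an independent homogeneous
#' Poisson spike train of rate `nu_X` on `[0, duration]`. Identical seeds
#' give bit-identical trains.
#'
#' @param drive an [external_drive()]
#' @param duration length of the trains (ms)
#' @param seed integer RNG seed
#' @return a list of `p` numeric vectors of ascending spike times (ms)
#' @export
generate_external_input <- function(drive, duration, seed = 1) {
  stopifnot(duration > 0)
  withr::with_seed(derive_seed(seed, "extspk"), {
    counts <- rpois(drive$p, drive$nu_X * duration / 1000)
    lapply(counts, function(k) sort(runif(k, 0, duration)))
  })
}

#' Export a network realization as a delimited text table
#'
#' Writes the synapse list as `source,target,weight_mV` preceded by a
#' header block (lines starting with `#`) that records the spec, neuron,
#' drive parameters and seeds. [read_network()] restores a bit-identical
#' realization (weights are written with 17 significant digits; the
#' external map is regenerated from its stored seed).
#'
#' @param net a `network_realization`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  s <- net$spec
  hdr <- c(
    sprintf("# lifnet network realization"),
    sprintf("# N_E %d", s$N_E), sprintf("# N_I %d", s$N_I),
    sprintf("# epsilon %.17g", s$epsilon), sprintf("# g %.17g", s$g),
    sprintf("# J %.17g", s$J), sprintf("# delay %.17g", s$delay),
    sprintf("# K_EE %d", s$K["E", "E"]),
    sprintf("# Jw %s", paste(sprintf("%.17g", as.vector(s$Jw)),
                             collapse = " ")),
    sprintf("# neuron %s", paste(sprintf("%.17g", unlist(net$neuron)),
                                 collapse = " ")),
    sprintf("# drive %d %.17g %d %.17g", net$drive$p, net$drive$nu_X,
            net$drive$K_X_out, net$drive$J_X),
    sprintf("# seed %d", net$seed),
    sprintf("# extmap_seed %d", net$extmap_seed),
    "source,target,weight_mV")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%d,%d,%.17g", net$synapses$source,
                     net$synapses$target, net$synapses$weight), con)
  invisible(path)
}

#' Read a network realization written by [write_network()]
#'
#' @param path file path
#' @return a `network_realization`
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gethdr <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)[1]
    strsplit(sub(paste0("^# ", key, " "), "", ln), " ")[[1]]
  }
  N_E <- as.integer(gethdr("N_E")); N_I <- as.integer(gethdr("N_I"))
  spec <- network_spec(N_E = N_E, N_I = N_I,
                       epsilon = as.numeric(gethdr("epsilon")),
                       g = as.numeric(gethdr("g")),
                       J = as.numeric(gethdr("J")),
                       delay = as.numeric(gethdr("delay")))
  spec$K["E", "E"] <- as.integer(gethdr("K_EE"))
  spec$Jw[] <- as.numeric(gethdr("Jw"))
  np <- as.numeric(gethdr("neuron"))
  neuron <- neuron_params(tau_m = np[1], tau_s = np[2], tau_ref = np[3],
                          C_m = np[4], V_r = np[5], theta = np[6])
  dr <- as.numeric(gethdr("drive"))
  drive <- external_drive(p = dr[1], nu_X = dr[2], K_X_out = dr[3],
                          J_X = dr[4])
  seed <- as.integer(gethdr("seed"))
  extmap_seed <- as.integer(gethdr("extmap_seed"))
  body <- lines[!grepl("^#", lines)]
  body <- body[-1]  # column header
  parts <- strsplit(body, ",", fixed = TRUE)
  syn <- data.frame(source = as.integer(vapply(parts, `[`, "", 1)),
                    target = as.integer(vapply(parts, `[`, "", 2)),
                    weight = as.numeric(vapply(parts, `[`, "", 3)))
  external_map <- withr::with_seed(extmap_seed, {
    lapply(seq_len(drive$p),
           function(s) sort(sample.int(spec$N, drive$K_X_out)))
  })
  structure(list(spec = spec, neuron = neuron, drive = drive,
                 synapses = syn, external_map = external_map,
                 seed = seed, extmap_seed = extmap_seed),
            class = "network_realization")
}
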