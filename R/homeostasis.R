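#' Global homeostasis configuration
#'
#' Parameters of the global firing-rate homeostasis: the EE weight of the
#' degenerated network is adjusted by bisection until the simulated
#' population rate matches the reference rate within `precision` (relative,
#' default 0.5%). With `cap_factor` set, the returned weight never exceeds
#' `cap_factor * J` of the reference weight (limited homeostasis).
#'
#' @param nu_ref target population rate (spikes/s)
#' @param precision relative rate tolerance
#' @param cap_factor optional maximum `J_EE` as a multiple of the reference
#'   weight (e.g. 1.2), or `NULL` for unlimited homeostasis
#' @param T_measure rate-measurement window per evaluation (ms)
#' @param t_transient warm-up discarded before each rate measurement (ms)
#' @param hard_ceiling search ceiling as a multiple of the reference weight
#' @param max_evals maximum number of simulation evaluations
#' @param n_eval noise realizations averaged per rate evaluation. With the
#'   default single frozen realization the rate is a staircase in `J_EE`
#'   (one recruited synchronous event jumps the 1-s count), so the
#'   stopping precision may be unattainable; averaging over a few
#'   realizations smooths the staircase while keeping the search
#'   deterministic
#' @return an object of class `global_homeostasis_config`
#' @export
global_homeostasis_config <- function(nu_ref, precision = 0.005,
                                      cap_factor = NULL, T_measure = 1000,
                                      t_transient = 100,
                                      hard_ceiling = 10, max_evals = 60,
                                      n_eval = 1) {
  stopifnot(nu_ref > 0, precision > 0, n_eval >= 1,
            is.null(cap_factor) || cap_factor > 1)
  structure(list(nu_ref = nu_ref, precision = precision,
                 cap_factor = cap_factor, T_measure = T_measure,
                 t_transient = t_transient, hard_ceiling = hard_ceiling,
                 max_evals = max_evals, n_eval = as.integer(n_eval)),
            class = "global_homeostasis_config")
}

#' Measure the population rate of a network by simulation
#'
#' Simulates for `T_measure + t_transient` and returns the population rate
#' after the warm-up. With a fixed seed the measurement is deterministic,
#' which makes bisection searches over network parameters well posed.
#'
#' @param net a `network_realization`
#' @param seed evaluation seed
#' @param T_measure measurement window (ms)
#' @param t_transient discarded warm-up (ms)
#' @param ids optional neuron subset over which to average
#' @return rate in spikes/s
#' @export
measure_rate <- function(net, seed = 1, T_measure = 1000,
                         t_transient = 100, ids = NULL) {
  cfg <- sim_config(duration = T_measure + t_transient,
                    t_transient = t_transient, seed = seed)
  sp <- simulate_network(net, cfg)
  population_rate(sp, window = c(t_transient, cfg$duration), ids = ids)
}

#' Global firing-rate homeostasis (bisection on the EE weight)
#'
#' Upscales the EE weight of a degenerated network until the simulated
#' population rate regains the reference rate: starting from the current
#' `J_EE` the weight increment is doubled until the target is straddled,
#' then standard bisection runs until the rate matches `nu_ref` within
#' `precision`. Each evaluation is a fresh short simulation with a fixed
#' evaluation seed, so the search is deterministic. Only the EE weight is
#' changed.
#'
#' With `cap_factor` set, the result is `min(solution, cap_factor * J)` and
#' `capped` records whether the bound was binding.
#'
#' @param net a `network_realization` (typically after [apply_ee_loss()])
#' @param cfg a [global_homeostasis_config()]
#' @param seed evaluation seed
#' @return list with `J_EE` (mV), `capped`, `achieved_rate`, `converged`
#'   and the evaluation log `evals` (data frame `J_EE`, `rate`)
#' @export
calibrate_jee_global <- function(net, cfg, seed = 1) {
  if (net$spec$K["E", "E"] < 1)
    stop("network has no EE synapses; the EE weight has no effect")
  J_ref <- net$spec$J
  evals <- data.frame(J_EE = numeric(0), rate = numeric(0))
  eval_seeds <- if ((cfg$n_eval %||% 1L) > 1L) {
    vapply(seq_len(cfg$n_eval),
           function(k) derive_seed(seed, paste0("ev", k)), integer(1))
  } else seed
  rate_at <- function(jee) {
    n2 <- set_ee_weight(net, jee)
    r <- mean(vapply(eval_seeds, function(es)
      measure_rate(n2, seed = es, T_measure = cfg$T_measure,
                   t_transient = cfg$t_transient), numeric(1)))
    evals <<- rbind(evals, data.frame(J_EE = jee, rate = r))
    r
  }
  within_tol <- function(r) abs(r - cfg$nu_ref) <= cfg$precision * cfg$nu_ref
  finish <- function(jee, rate, converged) {
    capped <- FALSE
    if (!is.null(cfg$cap_factor) && jee > cfg$cap_factor * J_ref) {
      jee <- cfg$cap_factor * J_ref
      capped <- TRUE
      rate <- rate_at(jee)
    }
    list(J_EE = jee, capped = capped, achieved_rate = rate,
         converged = converged, evals = evals)
  }
  j0 <- net$spec$Jw["E", "E"]
  r0 <- rate_at(j0)
  if (within_tol(r0)) return(finish(j0, r0, TRUE))
  up <- r0 < cfg$nu_ref
  dj <- j0
  lo <- j0; hi <- j0
  repeat {
    if (nrow(evals) >= cfg$max_evals) break
    if (up) {
      cand <- min(hi + dj, cfg$hard_ceiling * J_ref)
      r <- rate_at(cand)
      if (within_tol(r)) return(finish(cand, r, TRUE))
      if (r >= cfg$nu_ref) { lo <- hi; hi <- cand; break }
      if (cand >= cfg$hard_ceiling * J_ref)
        return(finish(cand, r, FALSE))
      lo <- cand; hi <- cand
    } else {
      cand <- max(0, lo - dj)
      r <- rate_at(cand)
      if (within_tol(r)) return(finish(cand, r, TRUE))
      if (r <= cfg$nu_ref) { hi <- lo; lo <- cand; break }
      if (cand <= 0) return(finish(0, r, FALSE))
      hi <- cand; lo <- cand
    }
    dj <- 2 * dj
  }
  while (nrow(evals) < cfg$max_evals) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (within_tol(r)) return(finish(mid, r, TRUE))
    if (r < cfg$nu_ref) lo <- mid else hi <- mid
  }
  # in strongly fluctuating regimes the frozen-noise rate is effectively
  # discontinuous in J_EE; report the best evaluation inside the bracket
  best <- evals[which.min(abs(evals$rate - cfg$nu_ref)), ]
  finish(best$J_EE, best$rate, FALSE)
}

#' Calibrate the external drive to a reference working point
#'
#' Adjusts the source rate `nu_X` of the external drive by bisection until
#' the simulated population rate of `net` matches `nu_target` within
#' `precision`. This anchors the network's working point (by default the
#' intact reference network at `J = 0.85` mV firing at 1.2 spikes/s), from
#' which all loss/homeostasis protocols start.
#'
#' Because the rate is reported as a mean across random network
#' realizations throughout, the calibration averages each evaluation over
#' `n_realizations` independently wired networks.
#'
#' @param net a `network_realization`
#' @param nu_target target population rate (spikes/s)
#' @param seed evaluation seed
#' @param precision relative rate tolerance
#' @param bounds search interval for `nu_X` (spikes/s)
#' @param T_measure,t_transient rate-measurement window (ms)
#' @param n_realizations network realizations averaged per evaluation
#' @return list with the calibrated `drive`, `nu_X`, `achieved_rate` and
#'   the evaluation log
#' @export
calibrate_drive <- function(net, nu_target = 1.2, seed = 1,
                            precision = 0.005, bounds = c(0.5, 40),
                            T_measure = 10000, t_transient = 100,
                            n_realizations = 3) {
  evals <- data.frame(nu_X = numeric(0), rate = numeric(0))
  nets <- lapply(seq_len(n_realizations), function(k)
    build_network(net$spec, net$neuron, net$drive,
                  seed = derive_seed(seed, paste0("cal-net", k))))
  rate_at <- function(nux) {
    r <- mean(vapply(seq_along(nets), function(k) {
      nets[[k]]$drive$nu_X <- nux
      measure_rate(nets[[k]], seed = derive_seed(seed, paste0("cal-ev", k)),
                   T_measure = T_measure, t_transient = t_transient)
    }, numeric(1)))
    evals <<- rbind(evals, data.frame(nu_X = nux, rate = r))
    r
  }
  lo <- bounds[1]; hi <- bounds[2]
  rlo <- rate_at(lo); rhi <- rate_at(hi)
  if (rlo > nu_target || rhi < nu_target)
    stop(sprintf("target rate %.3g spikes/s not bracketed by nu_X in [%g, %g] (rates %.3g..%.3g)",
                 nu_target, lo, hi, rlo, rhi))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - nu_target) <= precision * nu_target) break
    if (r < nu_target) lo <- mid else hi <- mid
  }
  last <- evals[nrow(evals), ]
  net$drive$nu_X <- last$nu_X
  list(drive = net$drive, nu_X = last$nu_X, achieved_rate = last$rate,
       evals = evals)
}

#' Compensatory synapse loss restoring a reference rate
#'
#' For a hyperactive network (e.g. after EE weight upscaling), finds the EE
#' loss fraction whose redrawn-wiring realization fires at `nu_ref`:
#' monotone bisection over the loss fraction, each evaluation redrawing the
#' EE wiring at the reduced in-degree (fixed evaluation seed) and measuring
#' the rate over a short window. The search stops when the rate matches
#' within `precision` or when the bracket is finer than one in-degree step.
#'
#' @param net a `network_realization` whose current rate exceeds `nu_ref`
#' @param nu_ref target population rate (spikes/s)
#' @param seed evaluation seed
#' @param precision relative rate tolerance
#' @param T_measure,t_transient rate-measurement window (ms)
#' @param max_evals maximum number of simulation evaluations
#' @return list with `loss_fraction`, `achieved_rate`, `converged`, and
#'   the evaluation log `evals`
#' @export
find_compensatory_loss <- function(net, nu_ref, seed = 1,
                                   precision = 0.005, T_measure = 1000,
                                   t_transient = 100, max_evals = 60) {
  k0 <- net$spec$K["E", "E"]
  evals <- data.frame(loss = numeric(0), rate = numeric(0))
  rate_at <- function(loss) {
    # loss = 0 keeps the current wiring, so a network already at the target
    # reports zero additional loss instead of realization noise
    n2 <- if (loss == 0) net else
      apply_ee_loss(net, loss, seed = derive_seed(seed, "loss-eval"))
    r <- measure_rate(n2, seed = seed, T_measure = T_measure,
                      t_transient = t_transient)
    evals <<- rbind(evals, data.frame(loss = loss, rate = r))
    r
  }
  r0 <- rate_at(0)
  if (r0 < nu_ref - precision * nu_ref)
    stop("current rate is below the target; no compensatory loss exists")
  if (abs(r0 - nu_ref) <= precision * nu_ref)
    return(list(loss_fraction = 0, achieved_rate = r0, converged = TRUE,
                evals = evals))
  r1 <- rate_at(1)
  if (r1 > nu_ref + precision * nu_ref)
    return(list(loss_fraction = 1, achieved_rate = r1, converged = FALSE,
                evals = evals))
  lo <- 0; hi <- 1
  best <- c(loss = NA_real_, rate = NA_real_)
  while (nrow(evals) < max_evals) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (is.na(best["rate"]) || abs(r - nu_ref) < abs(best["rate"] - nu_ref))
      best <- c(loss = mid, rate = r)
    if (abs(r - nu_ref) <= precision * nu_ref)
      return(list(loss_fraction = mid, achieved_rate = r,
                  converged = TRUE, evals = evals))
    if (r > nu_ref) lo <- mid else hi <- mid
    if ((hi - lo) * k0 < 0.5) break
  }
  list(loss_fraction = unname(best["loss"]),
       achieved_rate = unname(best["rate"]),
       converged = TRUE, evals = evals)
}

#' Local homeostasis (structural plasticity) configuration
#'
#' Parameters of the calcium-driven structural plasticity: each excitatory
#' neuron tracks its own low-pass filtered spiking activity (the calcium
#' trace, time constant `tau_lh`, intake `beta_lh` per spike) and grows or
#' removes incoming EE synapses so as to drive the trace towards the target
#' concentration `epsilon_lh`. The growth rate follows a Gaussian curve in
#' the calcium concentration (see [local_growth_rate()]): maximal growth at
#' `xi_lh = (eta_lh + epsilon_lh)/2`, zero at `eta_lh` (minimum calcium for
#' synapse creation) and at `epsilon_lh`, and removal beyond.
#'
#' The width convention `zeta_lh = (epsilon_lh - eta_lh)/(2 sqrt(ln 2))`
#' makes `eta_lh` and `epsilon_lh` exact zeros of the growth curve; the
#' alternative `"literal"` convention divides by `2 ln 2` instead.
#'
#' The calcium trace integrates the rate in spikes/ms, so a neuron firing
#' steadily at `nu` spikes/s has the stationary concentration
#' `beta_lh * tau_lh * nu / 1000`; `epsilon_lh` defaults are typically set
#' from the reference network's rate via [ca_target()].
#'
#' @param epsilon_lh target calcium concentration
#' @param eta_lh minimum calcium concentration for synapse creation
#' @param tau_lh calcium trace time constant (ms)
#' @param beta_lh calcium intake per spike
#' @param kappa_lh growth rate (synapses per connectivity update)
#' @param delta_t_lh connectivity-update interval (ms)
#' @param J_lh weight of newly created synapses (mV); the two presets of
#'   interest are `J_lh = J` (full-strength) and a nascent-synapse
#'   `J_lh = 6e-4` mV
#' @param duration length of the plasticity phase (ms)
#' @param zeta_convention `"zeros"` (default) or `"literal"`
#' @return an object of class `local_homeostasis_config`
#' @export
local_homeostasis_config <- function(epsilon_lh, eta_lh = 0.2 * epsilon_lh,
                                     tau_lh = 10000, beta_lh = 1,
                                     kappa_lh = 1, delta_t_lh = 100,
                                     J_lh = 0.85, duration = 1.2e6,
                                     zeta_convention = c("zeros",
                                                         "literal")) {
  zeta_convention <- match.arg(zeta_convention)
  stopifnot(epsilon_lh > 0, eta_lh >= 0, eta_lh < epsilon_lh,
            tau_lh > 0, beta_lh > 0, kappa_lh > 0, delta_t_lh > 0,
            J_lh >= 0, duration > 0)
  xi <- (eta_lh + epsilon_lh) / 2
  zeta <- if (zeta_convention == "zeros") {
    (epsilon_lh - eta_lh) / (2 * sqrt(log(2)))
  } else {
    (epsilon_lh - eta_lh) / (2 * log(2))
  }
  structure(list(epsilon_lh = epsilon_lh, eta_lh = eta_lh, xi_lh = xi,
                 zeta_lh = zeta, tau_lh = tau_lh, beta_lh = beta_lh,
                 kappa_lh = kappa_lh, delta_t_lh = delta_t_lh,
                 J_lh = J_lh, duration = duration,
                 zeta_convention = zeta_convention),
            class = "local_homeostasis_config")
}

#' Stationary calcium concentration at a given firing rate
#'
#' @param nu firing rate (spikes/s)
#' @param tau_lh calcium time constant (ms)
#' @param beta_lh calcium intake per spike
#' @return stationary trace value `beta_lh * tau_lh * nu / 1000`
#' @export
ca_target <- function(nu, tau_lh = 10000, beta_lh = 1) {
  beta_lh * tau_lh * nu / 1000
}

#' Gaussian growth curve of the structural plasticity
#'
#' `dz/dt = kappa_lh * (2 exp(-((Ca - xi_lh)/zeta_lh)^2) - 1)` in synapses
#' per connectivity update: maximal growth `+kappa_lh` at `Ca = xi_lh`,
#' zero at `eta_lh` and `epsilon_lh` (under the default width convention),
#' and removal (down to `-kappa_lh`) for very low or very high calcium.
#'
#' @param Ca calcium concentration(s)
#' @param cfg a [local_homeostasis_config()]
#' @return growth rate(s), synapses per update
#' @export
local_growth_rate <- function(Ca, cfg) {
  cfg$kappa_lh * (2 * exp(-((Ca - cfg$xi_lh) / cfg$zeta_lh)^2) - 1)
}

#' Run local structural-plasticity homeostasis
#'
#' Simulates the network in increments of `delta_t_lh`, carrying the exact
#' integrator state across increments. Each excitatory neuron's calcium
#' trace is updated from its spikes; at every connectivity update the
#' per-neuron synapse-count variable is advanced by the Gaussian growth
#' curve and its integer part creates (uniformly random excitatory
#' presynaptic partner, multapses allowed, weight `J_lh`) or deletes
#' (uniformly random existing incoming EE synapse) synapses. Inhibitory
#' connectivity is never touched.
#'
#' @param net a `network_realization`
#' @param cfg a [local_homeostasis_config()]
#' @param sim a [sim_config()] supplying `dt` and the seed; the plasticity
#'   phase length comes from `cfg$duration`
#' @return list with the final `net`, the population-`rate_trace`
#'   (data frame `t`, `rate` per update interval), the final calcium
#'   vector `ca`, and counters `created`, `deleted`, `deletion_noops`
#' @export
run_local_homeostasis <- function(net, cfg, sim) {
  spec <- net$spec
  n_updates <- ceiling(cfg$duration / cfg$delta_t_lh)
  # start the trace at the target concentration (neutral growth); it
  # relaxes to the neuron's true level within ~tau_lh, avoiding a spurious
  # deletion transient from an empty trace
  ca <- rep(cfg$epsilon_lh, spec$N_E)
  zfrac <- numeric(spec$N_E)
  decay <- exp(-cfg$delta_t_lh / cfg$tau_lh)
  state <- NULL
  created <- 0L; deleted <- 0L; noops <- 0L
  rate_trace <- data.frame(t = numeric(n_updates), rate = numeric(n_updates))
  chunk_cfg <- sim_config(duration = cfg$delta_t_lh, dt = sim$dt,
                          t_transient = 0, seed = sim$seed)
  for (u in seq_len(n_updates)) {
    t0 <- (u - 1) * cfg$delta_t_lh
    ext <- generate_external_input(net$drive, cfg$delta_t_lh,
                                   seed = derive_seed(sim$seed,
                                                      paste0("lh-ext", u)))
    res <- simulate_network(net, chunk_cfg, ext_input = ext,
                            state = state, t0 = t0, return_state = TRUE)
    state <- res$state
    sp <- res$spikes
    rate_trace$t[u] <- t0 + cfg$delta_t_lh
    rate_trace$rate[u] <- 1000 * length(sp$times) /
      (spec$N * cfg$delta_t_lh)
    # calcium: exponential decay plus per-spike intake, exact within chunk
    ca <- ca * decay
    e_spk <- sp$ids <= spec$N_E
    if (any(e_spk)) {
      rel <- (t0 + cfg$delta_t_lh) - sp$times[e_spk]
      inc <- vapply(split(exp(-rel / cfg$tau_lh), sp$ids[e_spk]), sum,
                    numeric(1))
      idx <- as.integer(names(inc))
      ca[idx] <- ca[idx] + cfg$beta_lh * inc
    }
    # structural update
    zfrac <- zfrac + local_growth_rate(ca, cfg)
    dn <- trunc(zfrac)
    zfrac <- zfrac - dn
    if (any(dn != 0)) {
      upd <- withr::with_seed(
        derive_seed(sim$seed, paste0("lh-struct", u)),
        update_ee_synapses(net, dn, cfg$J_lh))
      net <- upd$net
      created <- created + upd$created
      deleted <- deleted + upd$deleted
      noops <- noops + upd$noops
    }
  }
  list(net = net, rate_trace = rate_trace, ca = ca,
       created = created, deleted = deleted, deletion_noops = noops)
}

# Apply per-neuron integer synapse-count changes dn (length N_E): positive
# entries create incoming EE synapses (random excitatory source, multapses
# allowed), negative entries delete random existing incoming EE synapses.
update_ee_synapses <- function(net, dn, J_lh) {
  spec <- net$spec
  created <- 0L; deleted <- 0L; noops <- 0L
  grow <- which(dn > 0)
  if (length(grow)) {
    n_new <- dn[grow]
    tgt <- rep.int(grow, n_new)
    src <- vapply(tgt, function(i) {
      s <- sample.int(spec$N_E - 1L, 1L)
      if (s >= i) s + 1L else s  # exclude self
    }, integer(1))
    net$synapses <- rbind(net$synapses,
                          data.frame(source = src, target = tgt,
                                     weight = J_lh))
    created <- length(tgt)
  }
  shrink <- which(dn < 0)
  if (length(shrink)) {
    ee <- which(ee_rows(net))
    tgt_of <- net$synapses$target[ee]
    drop_idx <- integer(0)
    for (i in shrink) {
      mine <- ee[tgt_of == i]
      mine <- setdiff(mine, drop_idx)
      k <- min(-dn[i], length(mine))
      if (k < -dn[i]) noops <- noops + (-dn[i] - k)
      if (k > 0) {
        drop_idx <- c(drop_idx, mine[sample.int(length(mine), k)])
        deleted <- deleted + k
      }
    }
    if (length(drop_idx))
      net$synapses <- net$synapses[-drop_idx, , drop = FALSE]
  }
  rownames(net$synapses) <- NULL
  # K tracks the mean EE in-degree after structural changes
  net$spec$K["E", "E"] <- round(sum(ee_rows(net)) / spec$N_E)
  list(net = net, created = created, deleted = deleted, noops = noops)
}
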