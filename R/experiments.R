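#' Sweep configuration
#'
#' Describes a parameter-plane experiment over the reference weight `J`
#' and the degree of EE synapse loss, with `M` random network realizations
#' per cell and one of the compensation modes: no homeostasis, unlimited
#' or limited global homeostasis, or the hyperactivity protocol (EE weight
#' upscaling by `scale_grid` instead of loss-triggered homeostasis).
#'
#' @param J_grid reference weights (mV)
#' @param loss_grid EE loss fractions in `[0, 1]`
#' @param M realizations per cell
#' @param mode `"none"`, `"unlimited"`, `"limited"` or `"scale"`
#' @param cap_factor weight bound for `mode = "limited"`
#' @param scale_grid EE weight scale factors for `mode = "scale"`
#' @param base_seed base seed; every cell/realization derives its own
#'   seeds from it
#' @param duration observation time for the statistics/sensitivity
#'   simulations (ms)
#' @param compute_S also run the twin-simulation sensitivity protocol?
#' @param compute_rho also solve the mean-field spectral radius per cell?
#' @param T_homeo rate-measurement window of the homeostasis search (ms)
#' @return an object of class `sweep_config`
#' @export
sweep_config <- function(J_grid, loss_grid, M = 10,
                         mode = c("none", "unlimited", "limited", "scale"),
                         cap_factor = 1.2, scale_grid = 1,
                         base_seed = 1, duration = 10000,
                         compute_S = TRUE, compute_rho = TRUE,
                         T_homeo = 1000) {
  mode <- match.arg(mode)
  stopifnot(length(J_grid) >= 1, length(loss_grid) >= 1, M >= 1)
  structure(list(J_grid = J_grid, loss_grid = loss_grid, M = M,
                 mode = mode, cap_factor = cap_factor,
                 scale_grid = scale_grid, base_seed = base_seed,
                 duration = duration, compute_S = compute_S,
                 compute_rho = compute_rho, T_homeo = T_homeo),
            class = "sweep_config")
}

run_cell <- function(J, loss, scale, m, cfg, neuron, drive, spec_base) {
  # seeds are paired across the loss axis (same intact wiring, initial
  # conditions and drive per realization index), so loss effects are
  # measured against common random numbers
  cell_seed <- derive_seed(cfg$base_seed,
                           sprintf("cell-%g-%g-%d", J, scale, m))
  spec <- spec_base
  spec$J <- J
  spec$Jw <- matrix(c(J, J, -spec$g * J, -spec$g * J), 2, 2,
                    dimnames = dimnames(spec$Jw))
  ref <- build_network(spec, neuron, drive, seed = cell_seed)
  net <- ref
  J_EE <- J
  capped <- NA
  homeo_rate <- NA_real_
  if (loss > 0)
    net <- apply_ee_loss(net, loss,
                         seed = derive_seed(cell_seed, paste0("loss", loss)))
  if (cfg$mode %in% c("unlimited", "limited") && loss > 0 && J > 0) {
    nu_ref <- measure_rate(ref, seed = derive_seed(cell_seed, "refrate"),
                           T_measure = cfg$T_homeo)
    if (nu_ref > 0) {
      hcfg <- global_homeostasis_config(
        nu_ref = nu_ref,
        cap_factor = if (cfg$mode == "limited") cfg$cap_factor else NULL,
        T_measure = cfg$T_homeo)
      res <- calibrate_jee_global(net, hcfg,
                                  seed = derive_seed(cell_seed, "homeo"))
      net <- set_ee_weight(net, res$J_EE)
      J_EE <- res$J_EE
      capped <- res$capped
      homeo_rate <- res$achieved_rate / nu_ref
    }
  }
  if (cfg$mode == "scale" && scale != 1) {
    net <- scale_ee_weights(net, scale)
    J_EE <- net$spec$Jw["E", "E"]
  }
  scfg <- sim_config(duration = cfg$duration,
                     seed = derive_seed(cell_seed, "obs"))
  S <- NA_real_
  if (cfg$compute_S) {
    sens <- tryCatch(perturbation_sensitivity(net, scfg),
                     lifnet_undefined = function(e) NULL)
    spikes <- if (is.null(sens)) simulate_network(net, scfg)
              else sens$spikes
    if (!is.null(sens)) S <- sens$S
  } else {
    spikes <- simulate_network(net, scfg)
  }
  win <- c(scfg$t_transient, cfg$duration)
  sm <- activity_summary(net, spikes, reference = ref, window = win)
  st <- if (!cfg$compute_rho) NA_real_ else tryCatch({
    mf <- mf_params(net)
    state <- solve_selfconsistent_rates(mf,
                                        seed = derive_seed(cell_seed, "mf"))
    spectral_radius(mf, effective_weights(mf, state))$rho
  }, error = function(e) NA_real_)
  cbind(data.frame(J = J, loss = loss, scale = scale, realization = m,
                   mode = cfg$mode, seed = cell_seed, J_EE = J_EE,
                   capped = capped, homeo_rel_rate = homeo_rate, S = S,
                   rho_meanfield = st),
        sm)
}

#' Run a (J, loss) parameter sweep
#'
#' For each grid cell and realization: build the intact reference network,
#' apply EE synapse loss, apply the configured compensation mode, simulate
#' and compute the requested statistics. Deterministic given the base
#' seed; cells are independent.
#'
#' @param cfg a [sweep_config()]
#' @param neuron a [neuron_params()]
#' @param drive an [external_drive()] (use a calibrated drive)
#' @param spec_base the intact [network_spec()] template; its `J` is
#'   overridden by the grid
#' @return a long-format `data.frame`, one row per (J, loss, scale,
#'   realization), with columns `J_EE`, `capped`, `S`, `rho_meanfield`,
#'   `nu`, `nu_E`, `nu_I`, `CV`, `FF`, `B`, `rTSCA` and seeds
#' @export
run_sweep <- function(cfg, neuron = neuron_params(),
                      drive = external_drive(),
                      spec_base = network_spec()) {
  grid <- expand.grid(J = cfg$J_grid, loss = cfg$loss_grid,
                      scale = if (cfg$mode == "scale") cfg$scale_grid else 1,
                      m = seq_len(cfg$M))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tryCatch(run_cell(g$J, g$loss, g$scale, g$m, cfg, neuron, drive,
                      spec_base),
             error = function(e) {
               warning(sprintf("cell (J=%g, loss=%g, m=%d) failed: %s",
                               g$J, g$loss, g$m, conditionMessage(e)))
               NULL
             })
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Rate-sensitivity scatter (collapse check)
#'
#' Extracts `(nu_E, S)` and `(nu_E, rho)` pairs per mode from one or more
#' sweep results, the data behind the collapse of perturbation sensitivity
#' and spectral radius onto functions of the firing rate alone.
#'
#' @param ... sweep result data frames from [run_sweep()]
#' @return a data frame with columns `nu_E`, `S`, `rho`, `mode`
#' @export
rate_sensitivity_scatter <- function(...) {
  sw <- do.call(rbind, lapply(list(...), function(d)
    d[, c("nu_E", "S", "rho_meanfield", "mode")]))
  names(sw) <- c("nu_E", "S", "rho", "mode")
  rownames(sw) <- NULL
  sw
}

#' Residual spread around a pooled monotone rate-sensitivity curve
#'
#' Fits an isotonic (monotone non-decreasing) curve of `S` against `nu_E` —
#' pooled over all modes by default, or on the rows belonging to `fit_mode`
#' — and returns the residuals of all rows against that curve. A small
#' spread across modes means the sensitivity is a function of the firing
#' rate alone.
#'
#' @param scatter a [rate_sensitivity_scatter()] table
#' @param fit_mode mode used to fit the reference curve; `NULL` (default)
#'   pools all modes
#' @return list with `residuals` (per row of `scatter`) and the fit
#'   function `predict`
#' @export
collapse_residuals <- function(scatter, fit_mode = NULL) {
  ref <- scatter[!is.na(scatter$S), ]
  if (!is.null(fit_mode)) ref <- ref[ref$mode == fit_mode, ]
  ref <- ref[order(ref$nu_E), ]
  iso <- stats::isoreg(ref$nu_E, ref$S)
  pred <- stats::approxfun(iso$x, iso$yf, rule = 2)
  list(residuals = scatter$S - pred(scatter$nu_E), predict = pred)
}
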