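#' Gain integrand of the diffusion-approximation transfer function
#'
#' `f(u) = exp(u^2) (1 + erf(u))`, evaluated through the scaled
#' complementary error function (`f(u) = erfcx(-u)`) so that moderate
#' arguments do not overflow.
#'
#' @param u numeric vector
#' @return `f(u)`
#' @export
f_gain <- function(u) {
  out <- numeric(length(u))
  deep <- u < -15  # asymptotic series; erfcx overflows internally beyond ~27
  if (any(deep)) {
    x <- -u[deep]
    out[deep] <- (1 - 1 / (2 * x^2) + 3 / (4 * x^4) - 15 / (8 * x^6)) /
      (x * sqrt(pi))
  }
  if (any(!deep)) out[!deep] <- pracma::erfcx(-u[!deep])
  out
}

# Boundary correction for fast synaptic filtering: q/2 * sqrt(tau_s/tau_m)
# with q = sqrt(2) |zeta(1/2)|.
synaptic_shift <- function(neuron) {
  q <- sqrt(2) * abs(pracma::zeta(0.5))
  (q / 2) * sqrt(neuron$tau_s / neuron$tau_m)
}

# integral of f(u) du over [a, b]; asymptotic continuation beyond u = 8
# where f grows like 2 exp(u^2) (naive quadrature overflows).
siegert_integral <- function(a, b) {
  if (b <= a) return(0)
  cut <- 8
  main <- 0
  if (a < cut) {
    main <- stats::integrate(f_gain, a, min(b, cut), rel.tol = 1e-10,
                             abs.tol = 0, subdivisions = 400L)$value
  }
  tail <- 0
  if (b > cut) {
    a2 <- max(a, cut)
    # f(u) = 2 e^{u^2} - erfcx(u);  int 2 e^{u^2} = sqrt(pi) erfi(u) with
    # erfi(x) ~ e^{x^2}/(sqrt(pi) x) (1 + 1/(2x^2) + 3/(4x^4))
    erfi_part <- function(x)
      exp(x^2 + log((1 + 1 / (2 * x^2) + 3 / (4 * x^4)) / x))
    tail <- (erfi_part(b) - erfi_part(a2)) - log(b / a2) / sqrt(pi)
  }
  main + tail
}

#' Stationary firing rate of the LIF neuron (diffusion approximation)
#'
#' The Siegert-type transfer function with the boundary correction for fast
#' synaptic filtering:
#' `G(mu, sigma) = 1 / (tau_ref + tau_m sqrt(pi) * int_{y_r}^{y_theta} f(u) du)`
#' with `f(u) = exp(u^2)(1 + erf(u))`,
#' `y_r = (V_r - mu)/sigma + (q/2) sqrt(tau_s/tau_m)`,
#' `y_theta = (theta - mu)/sigma + (q/2) sqrt(tau_s/tau_m)` and
#' `q = sqrt(2) |zeta(1/2)|`.
#'
#' @param mu mean input (mV)
#' @param sigma input standard deviation (mV), `> 0`
#' @param neuron a [neuron_params()]
#' @return stationary rate in spikes/s
#' @export
transfer_rate <- function(mu, sigma, neuron = neuron_params()) {
  stopifnot(sigma > 0)
  sh <- synaptic_shift(neuron)
  y_r <- (neuron$V_r - mu) / sigma + sh
  y_th <- (neuron$theta - mu) / sigma + sh
  if (y_r >= 8) return(0)  # rate below ~1e-26 spikes/s; silent
  I <- siegert_integral(y_r, y_th)
  if (is.nan(I)) stop(sprintf("transfer rate failed at mu=%g, sigma=%g",
                              mu, sigma))
  if (is.infinite(I)) return(0)
  unname(1000 / (neuron$tau_ref + neuron$tau_m * sqrt(pi) * I))
}

#' Mean-field parameters of a network
#'
#' Collects the quantities entering the diffusion approximation: in-degree
#' matrix `K` (rows = target population, columns = source), rescaled weight
#' matrix `Jhat` (mV, signed), the average external in-degree
#' `K_X = p K_X_out / N`, the rescaled external weight, the external rate
#' and the neuron parameters.
#'
#' @param net a `network_realization`, or use `spec`, `neuron`, `drive`
#' @param spec,neuron,drive explicit components (ignored if `net` given)
#' @return an object of class `mf_params`
#' @export
mf_params <- function(net = NULL, spec = NULL, neuron = NULL, drive = NULL) {
  if (!is.null(net)) {
    spec <- net$spec; neuron <- net$neuron; drive <- net$drive
  }
  structure(list(N_E = spec$N_E, N_I = spec$N_I, N = spec$N,
                 K = spec$K, Jhat = rescaled_weight(spec$Jw, neuron),
                 K_X = drive$p * drive$K_X_out / spec$N,
                 Jhat_X = rescaled_weight(drive$J_X, neuron),
                 nu_X = drive$nu_X, neuron = neuron),
            class = "mf_params")
}

#' Input moments under the diffusion approximation
#'
#' Mean and SD of the total synaptic input current (in membrane-potential
#' units) to each population, given presynaptic population rates:
#' `mu_p = (K_pE Jhat_pE nu_E + K_pI Jhat_pI nu_I + K_X Jhat_X nu_X) tau_m`
#' and `sigma_p^2` with the squared weights.
#'
#' @param nu_E,nu_I presynaptic population rates (spikes/s)
#' @param mf an [mf_params()]
#' @return list with named vectors `mu` and `sigma` (mV) and
#'   `ext_var_share` (fraction of `sigma^2` from the external drive)
#' @export
input_moments <- function(nu_E, nu_I, mf) {
  tm <- mf$neuron$tau_m
  nu <- c(E = nu_E, I = nu_I) / 1000  # spikes/ms
  nux <- mf$nu_X / 1000
  mu <- as.numeric((mf$K * mf$Jhat) %*% nu + mf$K_X * mf$Jhat_X * nux) * tm
  v_rec <- as.numeric((mf$K * mf$Jhat^2) %*% nu) * tm
  v_ext <- mf$K_X * mf$Jhat_X^2 * nux * tm
  v <- v_rec + v_ext
  list(mu = stats::setNames(mu, c("E", "I")),
       sigma = stats::setNames(sqrt(v), c("E", "I")),
       ext_var_share = stats::setNames(ifelse(v > 0, v_ext / v, 0),
                                       c("E", "I")))
}

# Full mean-field state at given rates (not necessarily self-consistent).
mf_state_at <- function(nu_E, nu_I, mf) {
  mom <- input_moments(nu_E, nu_I, mf)
  sh <- synaptic_shift(mf$neuron)
  y_r <- (mf$neuron$V_r - mom$mu) / mom$sigma + sh
  y_th <- (mf$neuron$theta - mom$mu) / mom$sigma + sh
  G <- c(E = transfer_rate(mom$mu["E"], mom$sigma["E"], mf$neuron),
         I = transfer_rate(mom$mu["I"], mom$sigma["I"], mf$neuron))
  structure(list(nu_E = nu_E, nu_I = nu_I, G = G,
                 mu = mom$mu, sigma = mom$sigma,
                 y_r = y_r, y_theta = y_th,
                 ext_var_share = mom$ext_var_share,
                 converged = NA),
            class = "meanfield_state")
}

#' @export
print.meanfield_state <- function(x, ...) {
  cat(sprintf(paste0("<meanfield_state> nu_E=%.4g nu_I=%.4g spikes/s  ",
                     "mu=(%.3g, %.3g) mV  sigma=(%.3g, %.3g) mV\n"),
              x$nu_E, x$nu_I, x$mu["E"], x$mu["I"],
              x$sigma["E"], x$sigma["I"]))
  invisible(x)
}

mf_residual <- function(nu, mf) {
  # physical rates are bounded by 1/tau_ref; clamp the evaluation range so
  # Newton excursions cannot push the input moments out of floating range
  st <- mf_state_at(min(max(nu[1], 0), 1000), min(max(nu[2], 0), 1000), mf)
  c(nu[1] - st$G[["E"]], nu[2] - st$G[["I"]])
}

newton_rates <- function(start, mf, tol = 1e-9, maxit = 60) {
  r <- newton_core(start, mf, tol, maxit)
  if (r$ok) return(r)
  # near the refractory ceiling the finite-difference Jacobian degrades;
  # damped fixed-point iteration is a robust fallback, then polish
  x <- pmax(r$nu, 0)
  for (it in seq_len(400)) {
    st <- mf_state_at(min(x[1], 1000), min(x[2], 1000), mf)
    xn <- 0.5 * x + 0.5 * c(st$G[["E"]], st$G[["I"]])
    if (max(abs(xn - x)) < 1e-12) break
    x <- xn
  }
  newton_core(x, mf, tol, 30)
}

newton_core <- function(start, mf, tol = 1e-9, maxit = 60) {
  x <- pmax(start, 0)
  for (it in seq_len(maxit)) {
    F0 <- mf_residual(x, mf)
    if (max(abs(F0)) < tol) return(list(nu = pmax(x, 0), ok = TRUE))
    h <- pmax(1e-6, 1e-8 * abs(x))
    Jm <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + h[j]
      Jm[, j] <- (mf_residual(xp, mf) - F0) / h[j]
    }
    step <- tryCatch(solve(Jm, F0), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(nu = x, ok = FALSE))
    lam <- 1
    repeat {
      xn <- x - lam * step
      Fn <- mf_residual(xn, mf)
      if (sum(Fn^2) < sum(F0^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn
  }
  F0 <- mf_residual(x, mf)
  list(nu = pmax(x, 0), ok = max(abs(F0)) < tol)
}

#' Self-consistent stationary rates
#'
#' Solves the fixed-point equations `nu_E = G(mu_E(nu), sigma_E(nu))`,
#' `nu_I = G(mu_I(nu), sigma_I(nu))` by damped Newton iteration from
#' multiple random starting points (default 30 rate pairs uniform in
#' `[0, 50]` spikes/s). If several distinct fixed points coexist, the one
#' with the highest firing rates (lexicographically on `(nu_E, nu_I)`) is
#' returned.
#'
#' @param mf an [mf_params()]
#' @param n_starts number of random initial rate pairs
#' @param seed seed of the dedicated solver RNG stream
#' @param extra_starts optional matrix (rows = `(nu_E, nu_I)` pairs) of
#'   additional deterministic starts (used for warm starting)
#' @return a `meanfield_state` with `converged`, `residual`, and
#'   `fixed_points` (matrix of all distinct fixed points found)
#' @export
solve_selfconsistent_rates <- function(mf, n_starts = 30, seed = 1,
                                       extra_starts = NULL) {
  starts <- withr::with_seed(derive_seed(seed, "mf-starts"),
                             matrix(runif(2 * n_starts, 0, 50),
                                    ncol = 2))
  if (!is.null(extra_starts)) starts <- rbind(extra_starts, starts)
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_rates(starts[i, ], mf)
    if (r$ok) sols[[length(sols) + 1]] <- r$nu
  }
  if (length(sols) == 0) {
    best <- newton_rates(c(1, 1), mf)
    res <- mf_residual(best$nu, mf)
    stop(sprintf(paste0("no fixed point converged; best residual ",
                        "(%.3g, %.3g) spikes/s"), res[1], res[2]))
  }
  fp <- unique(round(do.call(rbind, sols), 6))
  o <- order(fp[, 1], fp[, 2], decreasing = TRUE)
  pick <- do.call(rbind, sols)[which.min(
    abs(do.call(rbind, sols)[, 1] - fp[o[1], 1]) +
      abs(do.call(rbind, sols)[, 2] - fp[o[1], 2])), ]
  st <- mf_state_at(pick[1], pick[2], mf)
  st$converged <- TRUE
  st$residual <- max(abs(mf_residual(pick, mf)))
  st$fixed_points <- fp[o, , drop = FALSE]
  st
}

#' Mean-field homeostatic EE weight
#'
#' Finds the rescaled EE weight `Jhat_EE` at which the self-consistent
#' excitatory rate equals the reference rate `nu_ref`, searching in
#' `[Jhat_ref, 10 Jhat_ref]`. For limited homeostasis the returned weight
#' is capped at `cap * Jhat_ref`.
#'
#' @param mf an [mf_params()] describing the network after synapse loss
#' @param nu_ref target excitatory rate (spikes/s)
#' @param limited apply the homeostatic bound?
#' @param cap bound as a multiple of the reference weight
#' @param seed solver seed
#' @return list with `Jhat_EE`, `capped`, `state` (the mean-field state at
#'   the returned weight) and `converged`
#' @export
meanfield_homeostatic_weight <- function(mf, nu_ref, limited = FALSE,
                                         cap = 1.2, seed = 1) {
  jref <- mf$Jhat["E", "E"]
  warm <- NULL
  nuE_at <- function(jee) {
    mf2 <- mf
    mf2$Jhat["E", "E"] <- jee
    st <- solve_selfconsistent_rates(mf2, n_starts = 8, seed = seed,
                                     extra_starts = warm)
    warm <<- matrix(c(st$nu_E, st$nu_I), 1)
    st
  }
  st0 <- nuE_at(jref)
  if (st0$nu_E >= nu_ref - 1e-9) {
    return(list(Jhat_EE = jref, capped = FALSE, state = st0,
                converged = TRUE))
  }
  hi <- 10 * jref
  sthi <- nuE_at(hi)
  if (sthi$nu_E < nu_ref) {
    return(list(Jhat_EE = NA_real_, capped = FALSE, state = sthi,
                converged = FALSE,
                message = sprintf("target %.3g spikes/s unreachable; %.3g at 10x weight",
                                  nu_ref, sthi$nu_E)))
  }
  root <- stats::uniroot(function(j) nuE_at(j)$nu_E - nu_ref,
                         lower = jref, upper = hi, tol = 1e-7 * jref)$root
  capped <- FALSE
  if (limited && root > cap * jref) {
    root <- cap * jref
    capped <- TRUE
  }
  list(Jhat_EE = root, capped = capped, state = nuE_at(root),
       converged = TRUE)
}

#' Rate factor of the effective weight
#'
#' `eta(nu) = sqrt(pi) (tau_m nu)^2 (f(y_theta) - f(y_r))`, the
#' working-point factor so that `w = eta(nu) * Jhat / sigma`.
#'
#' @param state a `meanfield_state`
#' @param neuron a [neuron_params()]
#' @param pop target population, `"E"` or `"I"`
#' @return dimensionless `eta`
#' @export
eta_nu <- function(state, neuron = neuron_params(), pop = "E") {
  nu_ms <- (if (pop == "E") state$nu_E else state$nu_I) / 1000
  sqrt(pi) * (neuron$tau_m * nu_ms)^2 *
    (f_gain(state$y_theta[[pop]]) - f_gain(state$y_r[[pop]]))
}

#' Effective synaptic weight (linear response gain)
#'
#' The number of excess output spikes of the target neuron per presynaptic
#' spike at the working point:
#' `w = (Jhat / sigma) sqrt(pi) (tau_m nu)^2 (f(y_theta) - f(y_r))`.
#' Only the DC susceptibility (derivative of the transfer function with
#' respect to the input mean) is included; the variance-modulation term is
#' deliberately neglected.
#'
#' @param J_hat rescaled synaptic weight (mV, signed)
#' @param state a `meanfield_state`
#' @param mf the [mf_params()] the state was computed from
#' @param pop target population, `"E"` or `"I"`
#' @return dimensionless effective weight (0, flagged, for a silent target)
#' @export
effective_weight <- function(J_hat, state, mf, pop = "E") {
  nu <- if (pop == "E") state$nu_E else state$nu_I
  if (nu <= 0) return(structure(0, silent = TRUE))
  nu_ms <- nu / 1000
  tm <- mf$neuron$tau_m
  (J_hat / state$sigma[[pop]]) * sqrt(pi) * (tm * nu_ms)^2 *
    (f_gain(state$y_theta[[pop]]) - f_gain(state$y_r[[pop]]))
}

#' Effective population weight matrix
#'
#' @param mf an [mf_params()]
#' @param state the self-consistent `meanfield_state`
#' @return 2x2 matrix `w[target, source]`
#' @export
effective_weights <- function(mf, state) {
  w <- mf$Jhat
  for (tp in c("E", "I"))
    for (sp in c("E", "I"))
      w[tp, sp] <- effective_weight(mf$Jhat[tp, sp], state, mf, tp)
  w
}

#' Spectral radius of the linearized dynamics
#'
#' Radius of the eigenvalue bulk of the effective connectivity matrix for a
#' random network with fixed in-degrees and population-wise constant
#' effective weights:
#' `rho^2 = N^-1 (K_EE N_E w_EE^2 + K_IE N_I w_IE^2 + K_EI N_E w_EI^2 +
#' K_II N_I w_II^2)`.
#' Also returns the per-source-population variances `v_E`, `v_I`
#' (`rho^2 = N_E v_E + N_I v_I`) and the mean-weight outlier eigenvalue
#' (negative in inhibition-dominated networks; it does not govern
#' stability).
#'
#' @param mf an [mf_params()] (only sizes and in-degrees are used)
#' @param w 2x2 effective weight matrix from [effective_weights()]
#' @return an object of class `stability_result` with `rho`, `v_E`,
#'   `v_I`, `lambda_outlier`, `w`
#' @export
spectral_radius <- function(mf, w) {
  K <- mf$K; N <- mf$N
  rho2 <- (K["E", "E"] * mf$N_E * w["E", "E"]^2 +
           K["I", "E"] * mf$N_I * w["I", "E"]^2 +
           K["E", "I"] * mf$N_E * w["E", "I"]^2 +
           K["I", "I"] * mf$N_I * w["I", "I"]^2) / N
  v_E <- (w["E", "E"]^2 * K["E", "E"] +
          w["I", "E"]^2 * K["I", "E"] * mf$N_I / mf$N_E) / N
  v_I <- (w["E", "I"]^2 * K["E", "I"] * mf$N_E / mf$N_I +
          w["I", "I"]^2 * K["I", "I"]) / N
  M <- matrix(c(K["E", "E"] * w["E", "E"], K["I", "E"] * w["I", "E"],
                K["E", "I"] * w["E", "I"], K["I", "I"] * w["I", "I"]),
              2, 2)
  ev <- eigen(M, only.values = TRUE)$values
  lam <- Re(ev[which.max(abs(ev))])
  structure(list(rho = sqrt(rho2), v_E = v_E, v_I = v_I,
                 lambda_outlier = lam, w = w),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> rho=%.4g  lambda_outlier=%.4g\n",
              x$rho, x$lambda_outlier))
  invisible(x)
}

#' Spectral radius predicted from the firing rate alone
#'
#' Under firing-rate homeostasis the excitatory and inhibitory rates
#' coincide and the external contribution to the input variance is small;
#' the spectral radius then collapses onto a function of the stationary
#' rate: `rho^2 = eta(nu*)^2 / (nu* tau_m)` with
#' `eta(nu) = sqrt(pi) (tau_m nu)^2 (f(y_theta) - f(y_r))`.
#'
#' @param nu_star stationary rate (spikes/s)
#' @param neuron a [neuron_params()]
#' @param state the `meanfield_state` supplying the integration bounds
#' @return predicted `rho`; warns when the homogeneity (`nu_E = nu_I`) or
#'   small-external-variance assumptions are violated
#' @export
rate_predicts_radius <- function(nu_star, neuron, state) {
  if (nu_star <= 0) return(0)
  if (state$nu_I > 0 && abs(state$nu_E / state$nu_I - 1) > 0.2)
    warning(sprintf("homogeneity assumption violated: nu_E/nu_I = %.3g",
                    state$nu_E / state$nu_I))
  if (max(state$ext_var_share) > 0.25)
    warning(sprintf("external variance share is %.2g; prediction degraded",
                    max(state$ext_var_share)))
  nu_ms <- nu_star / 1000
  eta <- sqrt(pi) * (neuron$tau_m * nu_ms)^2 *
    (f_gain(state$y_theta[["E"]]) - f_gain(state$y_r[["E"]]))
  sqrt(eta^2 / (nu_ms * neuron$tau_m))
}

#' Exponential approximation of the gain integrand
#'
#' Least-squares fit of `A exp(B y)` to `f(y)` on a dense grid over
#' `interval` (nonlinear least squares on `f` itself; a log-linear fit
#' supplies the starting values).
#'
#' @param interval fit range for `y`
#' @param n grid size
#' @return an object of class `exp_approx_fit` with `A`, `B`, `interval`
#' @export
fit_exp_approx <- function(interval = c(0.5, 1.5), n = 201) {
  y <- seq(interval[1], interval[2], length.out = n)
  fy <- f_gain(y)
  lin <- stats::lm(log(fy) ~ y)
  fit <- stats::nls(fy ~ A * exp(B * y), data = data.frame(y = y, fy = fy),
                    start = list(A = exp(unname(coef(lin)[1])),
                                 B = unname(coef(lin)[2])))
  cf <- coef(fit)
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 interval = interval),
            class = "exp_approx_fit")
}

#' @export
print.exp_approx_fit <- function(x, ...) {
  cat(sprintf("<exp_approx_fit> f(y) ~ %.4g * exp(%.4g y) on [%g, %g]\n",
              x$A, x$B, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Mean-field analysis of unspecific synapse loss
#'
#' Scales all four in-degrees by `(1 - loss_fraction)`; under homeostasis a
#' common factor `c >= 1` multiplying all weights is found such that the
#' excitatory rate regains `nu_ref` (for limited homeostasis `c` is capped
#' at `cap`).
#'
#' @param mf an [mf_params()] of the intact network
#' @param loss_fraction fraction of synapses removed from every connection
#'   type
#' @param homeostasis `"none"`, `"unlimited"` or `"limited"`
#' @param nu_ref reference excitatory rate (spikes/s); required unless
#'   `homeostasis = "none"`
#' @param cap weight bound for limited homeostasis
#' @param seed solver seed
#' @return list with `state`, `stability`, the scale factor `c` and
#'   `capped`
#' @export
unspecific_loss_meanfield <- function(mf, loss_fraction,
                                      homeostasis = c("none", "unlimited",
                                                      "limited"),
                                      nu_ref = NULL, cap = 1.2, seed = 1) {
  homeostasis <- match.arg(homeostasis)
  stopifnot(loss_fraction >= 0, loss_fraction <= 1)
  mf2 <- mf
  mf2$K <- mf$K * (1 - loss_fraction)
  cfac <- 1
  capped <- FALSE
  if (homeostasis != "none") {
    stopifnot(!is.null(nu_ref))
    warm <- NULL
    nuE_at <- function(cc) {
      mfc <- mf2
      mfc$Jhat <- mf2$Jhat * cc
      st <- solve_selfconsistent_rates(mfc, n_starts = 8, seed = seed,
                                       extra_starts = warm)
      warm <<- matrix(c(st$nu_E, st$nu_I), 1)
      st$nu_E
    }
    if (nuE_at(1) < nu_ref - 1e-9) {
      cfac <- stats::uniroot(function(cc) nuE_at(cc) - nu_ref,
                             lower = 1, upper = 10, tol = 1e-7)$root
    }
    if (homeostasis == "limited" && cfac > cap) {
      cfac <- cap
      capped <- TRUE
    }
    mf2$Jhat <- mf2$Jhat * cfac
  }
  st <- solve_selfconsistent_rates(mf2, seed = seed)
  stab <- spectral_radius(mf2, effective_weights(mf2, st))
  list(state = st, stability = stab, c = cfac, capped = capped)
}
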