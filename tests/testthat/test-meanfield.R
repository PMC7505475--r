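test_that("transfer function matches an independent high-precision oracle", {
  nrn <- neuron_params()
  # frozen values from 50-digit quadrature of the naive integrand
  # exp(u^2)(1+erf(u)) over [y_r, y_theta] at the default neuron parameters
  cases <- list(c(15, 5, 4.74370362642), c(10, 8, 2.94582812158),
                c(19, 2, 8.26089286806), c(5, 12, 3.11770907481),
                c(22, 4, 20.3730024716))
  for (case in cases) {
    expect_equal(transfer_rate(case[1], case[2], nrn), case[3],
                 tolerance = 1e-6,
                 info = sprintf("mu=%g sigma=%g", case[1], case[2]))
  }
})

test_that("transfer function limits: silence, refractory ceiling, monotonicity", {
  nrn <- neuron_params()
  expect_lt(transfer_rate(-200, 5, nrn), 1e-12)
  # the refractory ceiling is approached (logarithmically slowly) in mu
  expect_equal(transfer_rate(5000, 5, nrn), 1000 / nrn$tau_ref,
               tolerance = 0.05)
  expect_gt(transfer_rate(1e6, 5, nrn), transfer_rate(5000, 5, nrn))
  mus <- seq(-20, 60, 2)
  rates <- vapply(mus, transfer_rate, numeric(1), sigma = 6, neuron = nrn)
  expect_true(all(diff(rates) > -1e-12))
  # continuity in sigma
  r <- vapply(seq(2, 15, 0.5), function(s) transfer_rate(10, s, nrn),
              numeric(1))
  expect_true(all(is.finite(r)))
  expect_error(transfer_rate(10, -1, nrn))
})

test_that("input moments match hand arithmetic and sign structure", {
  nrn <- neuron_params()
  mf <- mf_params(spec = network_spec(), neuron = nrn,
                  drive = external_drive())
  z <- input_moments(0, 0, mf)
  ext_mu <- mf$K_X * mf$Jhat_X * (mf$nu_X / 1000) * nrn$tau_m
  expect_equal(unname(z$mu), rep(ext_mu, 2))
  m <- input_moments(10, 10, mf)
  # inhibition lowers the mean but raises the variance
  expect_lt(m$mu[["E"]] - z$mu[["E"]],
            mf$K["E", "E"] * mf$Jhat["E", "E"] * 0.01 * nrn$tau_m)
  expect_gt(m$sigma[["E"]], z$sigma[["E"]])
  # hand case: single EE pathway
  mf2 <- mf
  mf2$K[] <- 0; mf2$K["E", "E"] <- 2
  mf2$Jhat[] <- 0; mf2$Jhat["E", "E"] <- 1
  mf2$K_X <- 0
  h <- input_moments(10, 0, mf2)
  expect_equal(h$mu[["E"]], 2 * 1 * 0.01 * 20)
  expect_equal(h$sigma[["E"]]^2, 2 * 1 * 0.01 * 20)
  expect_equal(h$mu[["I"]], 0)
})

test_that("self-consistent rates: J = 0 decoupling and determinism", {
  nrn <- neuron_params()
  dr <- external_drive()
  mf0 <- mf_params(spec = network_spec(J = 0), neuron = nrn, drive = dr)
  st <- solve_selfconsistent_rates(mf0, seed = 4)
  mom <- input_moments(0, 0, mf0)
  direct <- transfer_rate(mom$mu[["E"]], mom$sigma[["E"]], nrn)
  expect_equal(st$nu_E, direct, tolerance = 1e-6)
  expect_equal(st$nu_I, direct, tolerance = 1e-6)
  expect_lt(st$residual, 1e-8)
  # duplicate solves converge to identical fixed points
  mf <- mf_params(spec = network_spec(J = 1.4), neuron = nrn, drive = dr)
  s1 <- solve_selfconsistent_rates(mf, seed = 9)
  s2 <- solve_selfconsistent_rates(mf, seed = 9)
  expect_identical(s1$nu_E, s2$nu_E)
  expect_lt(s1$residual, 1e-8)
})

test_that("effective weight equals the numerical susceptibility to rate", {
  nrn <- neuron_params()
  mf <- mf_params(spec = network_spec(J = 1.4), neuron = nrn,
                  drive = external_drive())
  st <- solve_selfconsistent_rates(mf, seed = 2)
  w <- effective_weight(mf$Jhat["E", "E"], st, mf, pop = "E")
  # oracle: central difference of G through mu only (sigma held fixed)
  dmu <- 1e-4
  gp <- transfer_rate(st$mu[["E"]] + dmu, st$sigma[["E"]], nrn)
  gm <- transfer_rate(st$mu[["E"]] - dmu, st$sigma[["E"]], nrn)
  # dG/dnu_j = dG/dmu * Jhat * tau_m (rates in spikes/ms)
  w_num <- (gp - gm) / (2 * dmu) / 1000 * mf$Jhat["E", "E"] * nrn$tau_m
  expect_equal(w, w_num, tolerance = 1e-4)
  expect_equal(effective_weight(0, st, mf), 0)
  expect_equal(sign(effective_weight(mf$Jhat["E", "I"], st, mf)), -1)
  wm <- effective_weights(mf, st)
  expect_true(all(wm[, "E"] > 0) && all(wm[, "I"] < 0))
})

test_that("spectral radius formula and outlier behave structurally", {
  mf <- mf_params(spec = network_spec(), neuron = neuron_params(),
                  drive = external_drive())
  w0 <- matrix(0, 2, 2, dimnames = dimnames(mf$Jhat))
  expect_equal(spectral_radius(mf, w0)$rho, 0)
  w <- matrix(c(0.02, 0.02, -0.12, -0.12), 2, 2,
              dimnames = dimnames(mf$Jhat))
  sr <- spectral_radius(mf, w)
  byhand <- sqrt((100 * 1000 * 0.02^2 + 100 * 250 * 0.02^2 +
                  25 * 1000 * 0.12^2 + 25 * 250 * 0.12^2) / 1250)
  expect_equal(sr$rho, byhand)
  expect_equal(1000 * sr$v_E + 250 * sr$v_I, sr$rho^2)
  expect_lt(sr$lambda_outlier, 0)
})

test_that("spectral radius matches a dense eigendecomposition oracle (small N)", {
  spec <- network_spec(N_E = 400, N_I = 100, epsilon = 0.1, J = 1.4)
  mf <- mf_params(spec = spec, neuron = neuron_params(),
                  drive = external_drive(p = 500))
  st <- solve_selfconsistent_rates(mf, seed = 3)
  w <- effective_weights(mf, st)
  rho <- spectral_radius(mf, w)$rho
  radii <- vapply(1:4, function(s) {
    withr::with_seed(s, {
      NE <- mf$N_E; NI <- mf$N_I
      W <- rbind(
        cbind(w["E", "E"] * (matrix(runif(NE * NE), NE) < mf$K["E", "E"] / NE),
              w["E", "I"] * (matrix(runif(NE * NI), NE) < mf$K["E", "I"] / NI)),
        cbind(w["I", "E"] * (matrix(runif(NI * NE), NI) < mf$K["I", "E"] / NE),
              w["I", "I"] * (matrix(runif(NI * NI), NI) < mf$K["I", "I"] / NI)))
      ev <- eigen(W, only.values = TRUE)$values
      ev <- ev[-which.min(Re(ev))]  # drop the mean-weight outlier
      max(abs(ev))
    })
  }, numeric(1))
  expect_lt(abs(mean(radii) - rho), 3 * max(sd(radii), 0.05 * rho))
})

test_that("the rate alone predicts the spectral radius under homogeneity", {
  nrn <- neuron_params()
  dr <- external_drive()
  for (J in c(0.85, 1.4, 2.2)) {
    mf <- mf_params(spec = network_spec(J = J), neuron = nrn, drive = dr)
    st <- solve_selfconsistent_rates(mf, n_starts = 12, seed = 1)
    rho_full <- spectral_radius(mf, effective_weights(mf, st))$rho
    rho_rate <- rate_predicts_radius(st$nu_E, nrn, st)
    expect_lt(abs(rho_rate - rho_full) / rho_full, 0.1,
              label = sprintf("J=%g", J))
  }
  expect_equal(rate_predicts_radius(0, nrn,
                                    solve_selfconsistent_rates(
                                      mf_params(spec = network_spec(J = 0.85),
                                                neuron = nrn, drive = dr),
                                      seed = 1)), 0)
})

test_that("rho increases with the stationary rate", {
  nrn <- neuron_params(); dr <- external_drive()
  rates <- rhos <- c()
  for (J in seq(0.6, 2.6, 0.4)) {
    mf <- mf_params(spec = network_spec(J = J), neuron = nrn, drive = dr)
    st <- solve_selfconsistent_rates(mf, n_starts = 12, seed = 1)
    rates <- c(rates, st$nu_E)
    rhos <- c(rhos, spectral_radius(mf, effective_weights(mf, st))$rho)
  }
  expect_true(all(diff(rates) > 0))
  expect_true(all(diff(rhos) > 0))
})

test_that("exponential fit of the gain integrand", {
  expect_equal(f_gain(0), 1)  # erf(0) = 0
  fit <- fit_exp_approx(c(0.5, 1.5))
  expect_gt(fit$A, 0); expect_gt(fit$B, 0)
  # shrinking the interval around y0 makes B approach the local log-slope
  y0 <- 1
  h <- 1e-3
  local_slope <- (log(f_gain(y0 + h)) - log(f_gain(y0 - h))) / (2 * h)
  fit_local <- fit_exp_approx(c(y0 - 0.01, y0 + 0.01))
  expect_equal(fit_local$B, local_slope, tolerance = 1e-3)
})

test_that("mean-field homeostatic weight: trivial case and monotone in loss", {
  nrn <- neuron_params(); dr <- external_drive()
  mf <- mf_params(spec = network_spec(J = 1.4), neuron = nrn, drive = dr)
  st0 <- solve_selfconsistent_rates(mf, seed = 1)
  # zero loss: reference weight is returned unchanged
  r0 <- meanfield_homeostatic_weight(mf, st0$nu_E, seed = 1)
  expect_equal(r0$Jhat_EE, mf$Jhat["E", "E"])
  sols <- c()
  for (loss in c(0.1, 0.3, 0.5, 0.7)) {
    mfl <- mf
    mfl$K["E", "E"] <- round(mf$K["E", "E"] * (1 - loss))
    r <- meanfield_homeostatic_weight(mfl, st0$nu_E, seed = 1)
    expect_true(r$converged)
    expect_equal(r$state$nu_E, st0$nu_E, tolerance = 1e-4)
    sols <- c(sols, r$Jhat_EE)
  }
  expect_true(all(diff(sols) > 0))
  # limited variant caps at 1.2 x reference
  mfl <- mf; mfl$K["E", "E"] <- 50
  rl <- meanfield_homeostatic_weight(mfl, st0$nu_E, limited = TRUE,
                                     cap = 1.2, seed = 1)
  expect_true(rl$capped)
  expect_equal(rl$Jhat_EE, 1.2 * mf$Jhat["E", "E"])
})

test_that("unspecific synapse loss is milder than EE-only loss", {
  nrn <- neuron_params(); dr <- external_drive()
  mf <- mf_params(spec = network_spec(J = 1.4), neuron = nrn, drive = dr)
  st0 <- solve_selfconsistent_rates(mf, seed = 1)
  # identity at zero loss
  u0 <- unspecific_loss_meanfield(mf, 0, "none", seed = 1)
  expect_equal(u0$state$nu_E, st0$nu_E, tolerance = 1e-8)
  expect_equal(u0$c, 1)
  # moderate unspecific loss barely moves the rate, while the same EE-only
  # loss clearly lowers it; at high loss both drop, unspecific less so
  u30 <- unspecific_loss_meanfield(mf, 0.3, "none", seed = 1)
  mf_ee <- mf; mf_ee$K["E", "E"] <- round(0.7 * mf$K["E", "E"])
  st_ee30 <- solve_selfconsistent_rates(mf_ee, seed = 1)
  expect_lt(abs(u30$state$nu_E - st0$nu_E) / st0$nu_E, 0.05)
  expect_lt(st_ee30$nu_E, 0.9 * st0$nu_E)
  u70 <- unspecific_loss_meanfield(mf, 0.7, "none", seed = 1)
  mf_ee$K["E", "E"] <- round(0.3 * mf$K["E", "E"])
  st_ee70 <- solve_selfconsistent_rates(mf_ee, seed = 1)
  expect_lt(u70$state$nu_E, st0$nu_E)
  expect_gt(u70$state$nu_E, st_ee70$nu_E)
  # homeostatic rescaling restores the rate; well inside the stable regime
  # (rho clearly below 1) it also restores the spectral radius
  mfs <- mf_params(spec = network_spec(J = 0.85), neuron = nrn, drive = dr)
  sts <- solve_selfconsistent_rates(mfs, seed = 1)
  rho0 <- spectral_radius(mfs, effective_weights(mfs, sts))$rho
  expect_lt(rho0, 1)
  uh <- unspecific_loss_meanfield(mfs, 0.6, "unlimited", nu_ref = sts$nu_E,
                                  seed = 1)
  expect_equal(uh$state$nu_E, sts$nu_E, tolerance = 1e-3)
  expect_lt(abs(uh$stability$rho - rho0) / rho0, 0.05)
})
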