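test_that("Gaussian growth curve: peak, zeros and limits", {
  cfg <- local_homeostasis_config(epsilon_lh = 10, eta_lh = 2, kappa_lh = 3)
  expect_equal(local_growth_rate(cfg$xi_lh, cfg), 3)           # peak
  expect_equal(local_growth_rate(cfg$epsilon_lh, cfg), 0)      # target
  expect_equal(local_growth_rate(cfg$eta_lh, cfg), 0)          # minimum
  expect_equal(local_growth_rate(1e9, cfg), -3)                # removal
  expect_equal(local_growth_rate(0, cfg),
               3 * (2 * exp(-(cfg$xi_lh / cfg$zeta_lh)^2) - 1))
  # the literal width convention does not zero the curve at epsilon
  lit <- local_homeostasis_config(epsilon_lh = 10, eta_lh = 2,
                                  zeta_convention = "literal")
  expect_gt(abs(local_growth_rate(10, lit)), 1e-3)
  expect_error(local_homeostasis_config(epsilon_lh = 1, eta_lh = 2))
})

test_that("calcium target matches the trace steady state", {
  # a neuron firing at nu for a long time accumulates beta*tau*nu/1000
  expect_equal(ca_target(1.2, tau_lh = 10000, beta_lh = 1), 12)
  net <- tiny_net(seed = 2)
  cfg <- local_homeostasis_config(epsilon_lh = 5, tau_lh = 500,
                                  delta_t_lh = 100, duration = 4000,
                                  kappa_lh = 1e-9)  # plasticity off
  res <- run_local_homeostasis(net, cfg, sim_config(duration = 100, seed = 3))
  rate <- mean(res$rate_trace$rate[-(1:10)])
  # population-average trace near the steady state for the measured rate
  expect_equal(mean(res$ca), ca_target(rate, 500, 1), tolerance = 0.5)
})

test_that("local homeostasis regrows lost EE synapses and spares inhibition", {
  net0 <- tiny_net(seed = 2)
  nu_ref <- measure_rate(net0, seed = 5, T_measure = 2000)
  net <- apply_ee_loss(net0, 0.5, seed = 3)
  ne <- net$spec$N_E
  non_ee <- net$synapses[!(net$synapses$source <= ne &
                           net$synapses$target <= ne), ]
  cfg <- local_homeostasis_config(epsilon_lh = ca_target(nu_ref, 2000),
                                  tau_lh = 2000, kappa_lh = 0.5,
                                  J_lh = 0.85, duration = 30000)
  res <- run_local_homeostasis(net, cfg, sim_config(duration = 100, seed = 7))
  # EE synapses were created (net growth from the degenerated state)
  expect_gt(res$created, 0)
  expect_gt(res$net$spec$K["E", "E"], net$spec$K["E", "E"])
  # inhibitory-related connectivity is bit-identical
  out_non_ee <- res$net$synapses[!(res$net$synapses$source <= ne &
                                   res$net$synapses$target <= ne), ]
  rownames(non_ee) <- rownames(out_non_ee) <- NULL
  expect_identical(out_non_ee, non_ee)
  # created synapses carry weight J_lh and respect the sign rule
  ee <- res$net$synapses[res$net$synapses$source <= ne &
                         res$net$synapses$target <= ne, ]
  expect_true(all(ee$weight %in% c(0.85)))
  expect_true(all(ee$source <= ne))
})

test_that("a network at its calcium target drifts far less than a lesioned one grows", {
  net <- build_network(tiny_spec(), neuron_params(), tiny_drive(nu_X = 6.5),
                       seed = 2)
  mk <- function(eps, kap)
    local_homeostasis_config(epsilon_lh = eps, tau_lh = 5000,
                             kappa_lh = kap, J_lh = 0.85, duration = 20000)
  # measure the rate under identical chunked-run conditions, plasticity off
  p0 <- run_local_homeostasis(net, mk(1, 1e-9),
                              sim_config(duration = 100, seed = 7))
  nu_run <- mean(p0$rate_trace$rate)
  cfg <- mk(ca_target(nu_run, 5000), 0.5)
  k0 <- sum(lifnet:::ee_rows(net))
  at_target <- run_local_homeostasis(net, cfg,
                                     sim_config(duration = 100, seed = 7))
  drift <- sum(lifnet:::ee_rows(at_target$net)) - k0
  lesioned <- apply_ee_loss(net, 0.5, seed = 3)
  kl <- sum(lifnet:::ee_rows(lesioned))
  regrown <- run_local_homeostasis(lesioned, cfg,
                                   sim_config(duration = 100, seed = 7))
  regrowth <- sum(lifnet:::ee_rows(regrown$net)) - kl
  expect_gt(regrowth, 0)
  expect_lt(abs(drift), 0.25 * regrowth)
  expect_lt(abs(drift) / k0, 0.2)
})

test_that("compensatory-loss search restores the target rate", {
  net <- tiny_net(seed = 6)
  nu0 <- measure_rate(net, seed = 4, T_measure = 1000)
  # already at target -> zero additional loss
  r0 <- find_compensatory_loss(net, nu0, seed = 4)
  expect_equal(r0$loss_fraction, 0)
  # upscaled network needs a positive compensatory loss
  up <- scale_ee_weights(net, 1.6)
  nu_up <- measure_rate(up, seed = 4, T_measure = 1000)
  expect_gt(nu_up, nu0)
  r <- find_compensatory_loss(up, nu0, seed = 4)
  expect_gt(r$loss_fraction, 0)
  expect_lt(abs(r$achieved_rate - nu0) / nu0, 0.15)
  # evaluations are monotone: higher loss, lower rate (rank correlation)
  ev <- r$evals[order(r$evals$loss), ]
  expect_lt(cor(ev$loss, ev$rate, method = "spearman"), 0)
  expect_error(find_compensatory_loss(apply_ee_loss(net, 0.9, seed = 1),
                                      nu0 * 2, seed = 4),
               "below the target")
})

test_that("global bisection homeostasis: cap semantics and eval log", {
  net0 <- tiny_net(seed = 10)
  nu_ref <- measure_rate(net0, seed = 3, T_measure = 1000)
  net <- apply_ee_loss(net0, 0.3, seed = 2)
  res <- calibrate_jee_global(net, global_homeostasis_config(nu_ref),
                              seed = 3)
  expect_gt(res$J_EE, net0$spec$J)   # upscaling needed after loss
  expect_false(res$capped)
  # capped variant never exceeds cap * J and flags binding caps
  cap <- 1.1
  resc <- calibrate_jee_global(net,
                               global_homeostasis_config(nu_ref,
                                                         cap_factor = cap),
                               seed = 3)
  expect_lte(resc$J_EE, cap * net0$spec$J + 1e-12)
  if (res$J_EE > cap * net0$spec$J) expect_true(resc$capped)
  # the evaluation log is rate-monotone in J_EE up to frozen-noise jitter
  ev <- res$evals[order(res$evals$J_EE), ]
  if (nrow(ev) >= 4)
    expect_gt(cor(ev$J_EE, ev$rate, method = "spearman"), 0.5)
  expect_error(calibrate_jee_global(apply_ee_loss(net, 1, seed = 1),
                                    global_homeostasis_config(nu_ref)),
               "no EE synapses")
})

test_that("drive calibration hits the requested working point", {
  net <- tiny_net(seed = 12)
  cal <- calibrate_drive(net, nu_target = 2, seed = 5, bounds = c(1, 40),
                         T_measure = 2000, n_realizations = 2)
  expect_lt(abs(cal$achieved_rate - 2) / 2, 0.02)
  expect_gt(nrow(cal$evals), 2)
})
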