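# lifnet

Synapse loss and firing-rate homeostasis in recurrent spiking networks.

Neurodegeneration — most prominently in Alzheimer's disease — removes
excitatory synapses between excitatory neurons, and the brain partly
compensates by strengthening the synapses that remain. `lifnet` is an R
package for studying what this loss/compensation interplay does to the
*dynamics* of a cortical-like circuit: the firing rate, the irregularity
(CV) and synchrony (Fano factor) of spiking, the total synaptic contact
area, and above all the network's sensitivity to tiny perturbations — the
"edge of chaos" property that is widely linked to computational capability.

## The model

The network is an inhibition-dominated random circuit of `N_E = 1000`
excitatory and `N_I = 250` inhibitory leaky integrate-and-fire neurons with
exponential postsynaptic currents. Every neuron receives exactly
`K_EE = K_IE = 100` excitatory and `K_EI = K_II = 25` inhibitory inputs;
excitatory weights are `J` (the EPSP peak amplitude, in mV), inhibitory
weights `-gJ` with `g = 6`. An ensemble of external Poisson sources drives
the network; its rate is calibrated once so that the intact reference
network at `J = 0.85` mV fires at 1.2 spikes/s.

Three ingredients are built on top of this synthetic-network generator and
a fast clock-driven simulator (Rcpp):

* **Degeneration and compensation.** EE synapse loss (rewiring at a reduced
  in-degree), global firing-rate homeostasis (bisection on `J_EE` until the
  population rate regains its reference, optionally capped at 120% of the
  reference weight), local structural plasticity (per-neuron calcium trace
  with a Gaussian growth rule creating/deleting EE synapses), and
  hyperactivity protocols (`J_EE > J_IE`).
* **Perturbation sensitivity.** Twin simulations with identical initial
  conditions and inputs, except that one external spike near `t* = 400` ms
  is delayed by 0.5 ms. The long-term sensitivity is
  `S = 1 - |R(t_obs)|`, with `R(t)` the population Pearson correlation of
  the low-pass filtered responses; `S = 0` is stable, `S = 1` chaotic.
* **Mean-field theory.** The diffusion-approximation transfer function
  `G(mu, sigma)` (with the fast-synapse boundary correction
  `q = sqrt(2)|zeta(1/2)|`), self-consistent stationary rates, effective
  (linear-response) weights `w = (Jhat/sigma) sqrt(pi) (tau_m nu)^2
  (f(y_theta) - f(y_r))`, and the spectral radius of the effective
  connectivity, `rho^2 = N^-1 (K_EE N_E w_EE^2 + K_IE N_I w_IE^2 +
  K_EI N_E w_EI^2 + K_II N_I w_II^2)`; `rho > 1` marks linear instability.
  Under firing-rate homeostasis the theory collapses to
  `rho^2 = eta(nu)^2 / (nu tau_m)` — the stationary rate alone predicts
  stability, which is why restoring the rate restores the dynamics.

## Worked example

```r
library(lifnet)

net  <- build_network(network_spec(J = 0.85), neuron_params(),
                      external_drive(), seed = 1)
spk  <- simulate_network(net, sim_config(duration = 10000, seed = 1))
population_rate(spk, window = c(100, 10000))
#> [1] 1.19402

# remove 30% of EE synapses, upscale the survivors by 50%
ad   <- scale_ee_weights(apply_ee_loss(net, 0.3, seed = 2), 1.5)
sens <- perturbation_sensitivity(ad, sim_config(duration = 10000, seed = 1))
population_rate(sens$spikes, window = c(100, 10000))
#> [1] 2.827475
sens$S
#> [1] 0
perturbation_sensitivity(ad, sim_config(duration = 10000, seed = 3))$S
#> [1] 0.2011107

# mean-field stability at the two working points
mf <- mf_params(ad)
st <- solve_selfconsistent_rates(mf)
spectral_radius(mf, effective_weights(mf, st))$rho
#> [1] 0.7393327
mf0 <- mf_params(net); st0 <- solve_selfconsistent_rates(mf0)
spectral_radius(mf0, effective_weights(mf0, st0))$rho
#> [1] 0.5668574
```

The intact network sits at the calibrated 1.2 spikes/s working point. After
30% EE loss overcompensated by 50% weight upscaling the rate rises to 2.8
spikes/s. Individual realizations either re-lock after the delayed spike
(`S = 0`, first run) or diverge (`S = 0.20`, second run) — near the edge of
chaos the sensitivity is bimodal across realizations and is reported as a
mean. The mean-field spectral radius at the hyperactive working point, 0.74,
remains below the instability line but well above the intact network's 0.57.

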