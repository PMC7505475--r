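# Default network configuration: inhibition-dominated E/I LIF network at
# the calibrated 1.2 spikes/s working point (units as in the R docs).
neuron:
  tau_m: 20        # membrane time constant (ms)
  tau_s: 2         # synaptic time constant (ms)
  tau_ref: 2       # absolute refractory period (ms)
  C_m: 250         # membrane capacitance (pF)
  V_r: 0           # reset potential (mV)
  theta: 20        # firing threshold (mV)
network:
  N_E: 1000        # excitatory neurons (N_I = N_E / 4)
  epsilon: 0.1     # connection probability (K_EE = epsilon * N_E = 100)
  g: 6             # relative inhibitory weight
  J: 0.85          # reference synaptic weight (mV, PSP peak)
  delay: 1         # synaptic delay (ms)
drive:
  p: 1250          # number of external Poisson sources
  nu_X: 5.42        # rate per source (spikes/s); see calibrate_drive()
  K_X_out: 100     # targets per source (K_X = p * K_X_out / N = 100)
  J_X: 0.85        # external synaptic weight (mV)
protocol:
  dt: 0.1          # integration step (ms)
  t_transient: 100 # discarded warm-up (ms)
  nu_target: 1.2   # reference working-point rate (spikes/s)
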