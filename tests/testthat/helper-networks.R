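# Small network fixtures built in code.

# Single unconnected HH neuron with the benchmark synapse models attached.
single_hh_net <- function(i_inj = 0, init = list(v = -65), duration = 100,
                          dt = 0.05, ...) {
  spiking_network("hh", 1L, edge_list(n_pre = 1, n_post = 1),
                  hh_params(i_inj = i_inj), dt = dt, duration = duration,
                  syn_inh = double_exp_params(), syn_exc = single_exp_params(),
                  init = init, ...)
}

# Tiny LIF network from an explicit edge table (no generators).
tiny_lif_net <- function(n, pre, post, weight, delay, init_v = 0,
                         dt = 0.1, duration = 10,
                         params = lif_params()) {
  spiking_network("lif", n,
                  edge_list(pre, post, weight, delay, n_pre = n, n_post = n),
                  params, dt = dt, duration = duration,
                  init = list(v = init_v))
}

# Hold a single HH neuron at a current for a while, return its final state.
hh_held_state <- function(i_inj, hold_ms = 100) {
  run_network(single_hh_net(i_inj = i_inj, duration = hold_ms), seed = 1)$state
}
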