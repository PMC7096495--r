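# Small shared fixtures; everything is generated in code.

tiny_params <- function(...) {
  args <- utils::modifyList(list(n_in = 10, n_out = 3), list(...))
  do.call(sim_params, args)
}

# deterministic raster with a handful of spikes
toy_raster <- function(n_neurons = 3, duration = 100) {
  spike_raster(neuron = c(1, 2, 1, 3),
               time = c(5.5, 10.5, 40.5, 80.5),
               n_neurons = n_neurons, duration = duration)
}

# brute-force all-pairs iSTDP oracle (no clipping assumed to bind)
brute_istdp <- function(G, pre, post, sp) {
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    tp <- post$events$time[post$events$neuron == i]
    tq <- pre$events$time[pre$events$neuron == j]
    if (length(tp) && length(tq)) {
      dd <- outer(tq, tp, "-")
      G[i, j] <- G[i, j] + sum(istdp_kernel(dd, sp))
    }
  }
  if (nrow(G) == ncol(G)) diag(G) <- 0
  pmin(pmax(G, 0), sp$Gmax)
}
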