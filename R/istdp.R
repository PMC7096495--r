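#' Inhibitory STDP window function
#'
#' Weight change for a single pre/post spike pair with timing difference
#' `delta_t = t_pre - t_post`:
#' `dG = Cp * exp(-|delta_t|/tau_p) - Cd * exp(-|delta_t|/tau_d)`.
#' The kernel is symmetric in `delta_t` and, for the default constants
#' (`Cd = 2 * Cp`, `tau_p = 2 * tau_d`), net-depressing at synchrony with a
#' zero crossing at `|delta_t| = log(Cd/Cp) / (1/tau_d - 1/tau_p)`
#' (40 * log 2 ~ 27.7 ms): near-coincident firing weakens inhibition between
#' the pair (anti-Hebbian), widely separated firing strengthens it.
#' `mode = "conventional"` negates the kernel (synchrony strengthens
#' inhibition) and serves as a control.
#'
#' @param delta_t spike timing difference(s) in ms (sign irrelevant).
#' @param sp a [stdp_params()] object.
#' @return Weight change(s) `dG`.
#' @export
istdp_kernel <- function(delta_t, sp) {
  a <- abs(delta_t)
  k <- sp$Cp * exp(-a / sp$tau_p) - sp$Cd * exp(-a / sp$tau_d)
  if (sp$mode == "conventional") -k else k
}

#' Apply inhibitory STDP to a lateral weight matrix
#'
#' Accumulates the pairwise kernel over all pre/post spike pairs using two
#' exponential traces per neuron (one per kernel time constant), which is
#' exact for exponential kernels, and clips the result to `[0, Gmax]` after
#' every spike event.  The diagonal is forced to zero.
#'
#' `G[i, j]` is the inhibitory weight from (pre) neuron `j` onto (post)
#' neuron `i`; every pair of a post spike of `i` and a pre spike of `j`
#' contributes `istdp_kernel(t_pre - t_post)` to it.  For lateral all-to-all
#' plasticity pass the same raster as `pre_raster` and `post_raster`: each
#' spike then acts both as a presynaptic and a postsynaptic event.
#'
#' @param G current weight matrix (`n_post` x `n_pre`), entries in
#'   `[0, Gmax]`.
#' @param pre_raster,post_raster [spike_raster()]s over the same window.
#' @param sp a [stdp_params()] object.
#' @return The updated weight matrix.
#' @export
apply_istdp <- function(G, pre_raster, post_raster, sp) {
  stopifnot(inherits(pre_raster, "spike_raster"),
            inherits(post_raster, "spike_raster"))
  n_post <- nrow(G); n_pre <- ncol(G)
  if (pre_raster$n_neurons != n_pre || post_raster$n_neurons != n_post)
    stop("raster population sizes do not match dim(G)")
  lateral <- identical(pre_raster, post_raster)
  if (lateral) {
    ev <- pre_raster$events
    role <- rep(3L, nrow(ev))             # 3 = both pre and post
    t_ev <- ev$time; n_ev <- ev$neuron
  } else {
    t_ev <- c(pre_raster$events$time, post_raster$events$time)
    n_ev <- c(pre_raster$events$neuron, post_raster$events$neuron)
    role <- rep(c(1L, 2L), c(nrow(pre_raster$events), nrow(post_raster$events)))
    o <- order(t_ev, role, n_ev)
    t_ev <- t_ev[o]; n_ev <- n_ev[o]; role <- role[o]
  }
  sgn <- if (sp$mode == "conventional") -1 else 1
  pre_p <- numeric(n_pre); pre_d <- numeric(n_pre)     # traces of pre spikes
  post_p <- numeric(n_post); post_d <- numeric(n_post) # traces of post spikes
  t_last <- 0
  for (k in seq_along(t_ev)) {
    dtk <- t_ev[k] - t_last
    if (dtk > 0) {
      dp <- exp(-dtk / sp$tau_p); dd <- exp(-dtk / sp$tau_d)
      pre_p <- pre_p * dp; pre_d <- pre_d * dd
      post_p <- post_p * dp; post_d <- post_d * dd
      t_last <- t_ev[k]
    }
    i <- n_ev[k]
    if (role[k] != 1L) {  # a post spike of neuron i: pair with past pre spikes
      G[i, ] <- G[i, ] + sgn * (sp$Cp * pre_p - sp$Cd * pre_d)
    }
    if (role[k] != 2L) {  # a pre spike of neuron i: pair with past post spikes
      G[, i] <- G[, i] + sgn * (sp$Cp * post_p - sp$Cd * post_d)
    }
    if (role[k] != 1L && n_post == n_pre) G[i, i] <- 0
    G[G < 0] <- 0
    G[G > sp$Gmax] <- sp$Gmax
    if (role[k] != 2L) { pre_p[i] <- pre_p[i] + 1; pre_d[i] <- pre_d[i] + 1 }
    if (role[k] != 1L) { post_p[i] <- post_p[i] + 1; post_d[i] <- post_d[i] + 1 }
  }
  if (n_post == n_pre) diag(G) <- 0
  G
}
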