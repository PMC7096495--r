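#' Initial dynamical state of a network
#'
#' Somatic and dendritic potentials start at rest (0); the running mean of
#' the somatic potential starts at 0 and the running second moment at 1, so
#' the adaptive response function begins in the identity regime
#' (`beta = beta0`, `theta = theta0`).
#'
#' @param params a [sim_params()] object.
#' @return A list with elements `u`, `v`, `mu`, `m2`, `sigma` (length
#'   `n_out`) and `I`, `e` (length `n_in`).
#' @export
init_state <- function(params) {
  no <- params$n_out; ni <- params$n_in
  list(u = numeric(no), v = numeric(no),
       mu = numeric(no), m2 = rep(1, no), sigma = rep(1, no),
       I = numeric(ni), e = numeric(ni))
}

#' Exact one-step propagator of the synaptic cascade
#'
#' Advances the synaptic current `I` (decay `tau_syn`) and the postsynaptic
#' potential `e` (decay `tau_mem`, driven by `e0 * I`) by one step `dt`,
#' using the closed-form solution of the linear cascade so no discretization
#' error accrues between spike arrivals.
#'
#' @keywords internal
propagate_traces <- function(I, e, params) {
  ts <- params$tau_syn; tm <- params$tau_mem; dt <- params$dt
  Es <- exp(-dt / ts); Em <- exp(-dt / tm)
  if (abs(1 / tm - 1 / ts) < 1e-12) {
    e_new <- (e + params$e0 * I * dt) * Em
  } else {
    A <- params$e0 * I / (1 / tm - 1 / ts)
    e_new <- (e - A) * Em + A * Es
  }
  list(I = I * Es, e = e_new)
}

#' Filter a spike raster into synaptic current and PSP traces
#'
#' Discretizes the cascade `tau_syn * dI/dt = -I + X/tau_mem`,
#' `de/dt = -e/tau_mem + e0 * I`, where `X` is the spike train (sum of Dirac
#' deltas).  A spike arriving in bin `k` adds `1/(tau_mem * tau_syn)` to `I`
#' at that bin, so a single spike contributes area `1/tau_mem` to the
#' integral of `I`, matching the continuous-time driving term.  Between
#' arrivals the exact exponential propagator is used, so trace values at bin
#' boundaries match the continuous solution.
#'
#' @param raster a [spike_raster()].
#' @param params a [sim_params()] object (uses `tau_syn`, `tau_mem`, `e0`,
#'   `dt`).
#' @return A list with matrices `I` and `e` (`n_neurons` x `n_bins`);
#'   column `k` holds the trace values at time `(k-1) * dt`, after spikes of
#'   bin `k` have been injected into `I`.
#' @export
synaptic_filter <- function(raster, params) {
  stopifnot(inherits(raster, "spike_raster"))
  dt <- params$dt
  n <- raster$n_neurons
  nb <- as.integer(ceiling(raster$duration / dt))
  bin <- pmin(nb, floor(raster$events$time / dt) + 1L)
  Imat <- matrix(0, n, nb)
  emat <- matrix(0, n, nb)
  I <- numeric(n); e <- numeric(n)
  inj <- 1 / (params$tau_mem * params$tau_syn)
  sp_by_bin <- split(raster$events$neuron, bin)
  for (k in seq_len(nb)) {
    s <- sp_by_bin[[as.character(k)]]
    if (!is.null(s)) for (j in s) I[j] <- I[j] + inj
    Imat[, k] <- I
    emat[, k] <- e
    p <- propagate_traces(I, e, params)
    I <- p$I; e <- p$e
  }
  list(I = Imat, e = emat)
}

#' Dendritic membrane potential
#'
#' Weighted sum of unit postsynaptic potentials: `v_i = sum_j w_ij e_j`.
#'
#' @param w feedforward weight matrix (`n_out` x `n_in`).
#' @param e PSP trace vector (length `n_in`) or matrix (`n_in` x time).
#' @return Vector (or matrix) of dendritic potentials.
#' @export
dendritic_potential <- function(w, e) {
  if (is.matrix(e)) {
    if (ncol(w) != nrow(e)) stop("shape mismatch between w and e")
  } else if (ncol(w) != length(e)) stop("shape mismatch between w and e")
  drop(w %*% e)
}

#' Attenuated dendritic potential
#'
#' `v* = alpha * v` with `alpha = g_D / (g_D + 1/tau_mem)`: the stationary
#' somatic potential a frozen dendritic potential would impose.
#'
#' @param v dendritic potential(s).
#' @param params a [sim_params()] object.
#' @return Attenuated potential(s), same shape as `v`.
#' @export
attenuated_potential <- function(v, params) attenuation_factor(params) * v

#' Sigmoidal response function
#'
#' `phi(x) = phi0 / (1 + exp(beta * (theta - x)))`, strictly inside
#' `(0, phi0)` and increasing in `x`.  With `beta = beta0` and
#' `theta = theta0` this is the dendritic response function shared by all
#' neurons; with the adaptive per-neuron `(beta_i, theta_i)` from
#' [adapt_response_params()] it is the somatic one.
#'
#' @param x membrane potential(s).
#' @param beta slope(s), strictly positive.
#' @param theta threshold(s).
#' @param phi0 maximal rate (events/ms).
#' @return Firing rate(s) in `(0, phi0)`.
#' @export
response_function <- function(x, beta, theta, phi0) {
  if (any(beta <= 0)) stop("beta must be strictly positive")
  if (phi0 <= 0) stop("phi0 must be strictly positive")
  phi0 / (1 + exp(beta * (theta - x)))
}

#' Dendritic response function
#'
#' [response_function()] with the fixed parameters `(beta0, theta0, phi0)`.
#' @param x potential(s).
#' @param params a [sim_params()] object.
#' @export
phi_dend <- function(x, params) {
  response_function(x, params$beta0, params$theta0, params$phi0)
}

#' Somatic response function
#'
#' [response_function()] with the adaptive per-neuron parameters derived
#' from the running moments of the somatic potential.  Equivalent to
#' applying the fixed sigmoid to the standardized potential
#' `(u - mu) / sigma`.
#'
#' @param u somatic potential vector.
#' @param mu,sigma running mean and s.d. of `u`.
#' @param params a [sim_params()] object.
#' @export
phi_som <- function(u, mu, sigma, params) {
  ap <- adapt_response_params(mu, sigma, params)
  response_function(u, ap$beta, ap$theta, params$phi0)
}

#' Adaptive slope and threshold of the somatic response
#'
#' `beta_i = beta0 / sigma_i` and `theta_i = mu_i + sigma_i * theta0`, so
#' that the somatic rate depends on the potential only through its
#' standardized value.  `sigma` is clamped from below at `sigma_floor`.
#'
#' @param mu running mean vector.
#' @param sigma running s.d. vector.
#' @param params a [sim_params()] object.
#' @return List with vectors `beta` and `theta`.
#' @export
adapt_response_params <- function(mu, sigma, params) {
  s <- pmax(sigma, params$sigma_floor)
  list(beta = params$beta0 / s, theta = mu + s * params$theta0)
}

#' Update the running moments of the somatic potential
#'
#' Exponential moving averages of the first and second moments with time
#' constant `t0` (an O(1)-memory stand-in for a boxcar average over the last
#' `t0` ms, with the same fixed points):
#' `mu <- mu + (dt/t0) * (u - mu)`, `m2 <- m2 + (dt/t0) * (u^2 - m2)`,
#' `sigma = sqrt(max(m2 - mu^2, sigma_floor^2))`.
#'
#' @param mu,m2 current first and second moment estimates.
#' @param u_new somatic potential vector after the current step.
#' @param params a [sim_params()] object.
#' @return List with updated `mu`, `m2`, `sigma`.
#' @export
update_running_moments <- function(mu, m2, u_new, params) {
  lam <- params$dt / params$t0
  mu2 <- mu + lam * (u_new - mu)
  m22 <- m2 + lam * (u_new^2 - m2)
  sig <- sqrt(pmax(m22 - mu2^2, params$sigma_floor^2))
  list(mu = mu2, m2 = m22, sigma = sig)
}

#' One Euler step of the somatic dynamics
#'
#' `du/dt = -u/tau_mem + g_D * (v - u) - sum_j G_ij * phi_som(u_j)/phi0`.
#' The lateral inhibition term is computed from the instantaneous somatic
#' firing rates (not from sampled spikes).
#'
#' @param state list with `u`, `v`, `mu`, `sigma` (see [init_state()]).
#' @param weights list with lateral matrix `G` (`n_out` x `n_out`).
#' @param params a [sim_params()] object.
#' @return Updated somatic potential vector `u_new`.
#' @export
somatic_step <- function(state, weights, params) {
  u <- state$u
  rate <- phi_som(u, state$mu, state$sigma, params) / params$phi0
  inhib <- drop(weights$G %*% rate)
  u + params$dt * (-u / params$tau_mem +
                     params$g_D * (state$v - u) - inhib)
}
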