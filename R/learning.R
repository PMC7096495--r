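#' Log-derivative of the dendritic response function
#'
#' `psi(x) = d/dx log(phi_dend(x))`, which for the sigmoid has the closed
#' form `beta0 * (1 - phi_dend(x)/phi0)`.  Positive everywhere and
#' decreasing in `x`: weight changes are gated most strongly when the
#' dendrite predicts a low rate.
#'
#' @param x (attenuated) dendritic potential(s).
#' @param params a [sim_params()] object.
#' @return `psi(x)`, same shape as `x`.
#' @export
psi <- function(x, params) {
  params$beta0 * (1 - phi_dend(x, params) / params$phi0)
}

#' Kullback-Leibler divergence between two Poisson distributions
#'
#' For rates `phi_a` (reference) and `phi_b` (model):
#' `D = phi_a * log(phi_a/phi_b) + phi_b - phi_a`.  Nonnegative, zero iff
#' the rates coincide.  This pointwise divergence, time-averaged, is the
#' objective the synaptic learning rule descends.
#'
#' @param phi_a,phi_b strictly positive rates (vectorized).
#' @return Divergence value(s).
#' @export
kl_poisson <- function(phi_a, phi_b) {
  if (any(phi_a <= 0) || any(phi_b <= 0)) stop("rates must be strictly positive")
  phi_a * log(phi_a / phi_b) + phi_b - phi_a
}

#' One online MRIL weight update for a single output neuron
#'
#' `dw = eta * dt * ( psi(v*) * [phi_som(u) - phi_dend(v*)]/phi0 * e
#'                    - gamma * w )`.
#' The somatic rate uses the adaptive `(beta_i, theta_i)` derived from
#' `(mu, sigma)` and is treated as a constant with respect to the weights
#' (no gradient flows through the soma or its adaptation); the dendritic
#' rate uses the fixed `(beta0, theta0)`.
#'
#' @param w_row weight row vector of the neuron (length `n_in`).
#' @param v_star attenuated dendritic potential (scalar).
#' @param u somatic potential (scalar).
#' @param mu,sigma running moments of `u` (scalars).
#' @param e PSP trace vector (length `n_in`).
#' @param lp a [learning_params()] object.
#' @param params a [sim_params()] object.
#' @return The weight increment `dw` (length `n_in`).
#' @export
mril_step <- function(w_row, v_star, u, mu, sigma, e, lp, params) {
  stopifnot(length(w_row) == length(e))
  ps <- phi_som(u, mu, sigma, params)
  pd <- phi_dend(v_star, params)
  err <- (ps - pd) / params$phi0
  lp$eta * params$dt * (psi(v_star, params) * err * e - lp$gamma * w_row)
}

#' Noise-augmented MRIL update
#'
#' As [mril_step()] but the somatic rate in the error term is replaced by
#' `f(phi_som + phi0 * g_noise * xi)` with `xi` standard normal and `f` the
#' piecewise-linear clip to `[0, phi0]` ([clip_linear()]).  Clipping at zero
#' removes negative teaching signals, suppressing learning during
#' noise-dominated epochs.  With `g_noise = 0` the update is identical to
#' [mril_step()].
#'
#' @inheritParams mril_step
#' @param seed optional seed for the noise draw (restores RNG state).
#' @param xi optional pre-drawn standard normal deviate(s); overrides `seed`.
#' @return The weight increment `dw`.
#' @export
noisy_mril_step <- function(w_row, v_star, u, mu, sigma, e, lp, params,
                            seed = NULL, xi = NULL) {
  stopifnot(length(w_row) == length(e))
  if (is.null(xi)) {
    xi <- if (is.null(seed)) stats::rnorm(1) else with_seed(seed, stats::rnorm(1))
  }
  ps <- phi_som(u, mu, sigma, params)
  ps_noisy <- clip_linear(ps + params$phi0 * lp$g_noise * xi, params$phi0)
  pd <- phi_dend(v_star, params)
  err <- (ps_noisy - pd) / params$phi0
  lp$eta * params$dt * (psi(v_star, params) * err * e - lp$gamma * w_row)
}

#' Piecewise-linear clip of a rate to its admissible range
#'
#' `f(x) = 0` for `x < 0`, `x` for `0 <= x < phi0`, `phi0` for `x >= phi0`.
#'
#' @param x rate value(s).
#' @param phi0 maximal rate, strictly positive.
#' @return Clipped value(s).
#' @export
clip_linear <- function(x, phi0) {
  if (phi0 <= 0) stop("phi0 must be strictly positive")
  pmin(pmax(x, 0), phi0)
}

#' Time-averaged somato-dendritic consistency cost
#'
#' Mean over time (and neurons) of the Poisson KL divergence between the
#' somatic rate `phi_som(u)` and the dendritic prediction `phi_dend(v*)`:
#' the empirical value of the objective the learning rule minimizes.  Used
#' for learning-curve diagnostics.
#'
#' @param u somatic potential trace: vector or matrix (neurons x time).
#' @param v_star attenuated dendritic potential trace, same shape.
#' @param params a [sim_params()] object.
#' @param mu,sigma running-moment traces (same shape as `u`, or scalars);
#'   default to the standardized identity regime (0, 1).
#' @return Scalar mean divergence.
#' @export
consistency_cost <- function(u, v_star, params, mu = 0, sigma = 1) {
  if (length(u) != length(v_star)) stop("trace length mismatch")
  ps <- phi_som(u, mu, sigma, params)
  pd <- phi_dend(v_star, params)
  mean(kl_poisson(ps, pd))
}
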