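#' Model constants for a two-compartment network simulation
#'
#' Bundles every scalar constant of the neuron and network dynamics into a
#' validated list.  Times are in milliseconds, rates in events/ms (so a
#' `phi0` of 0.05 corresponds to a 50 Hz ceiling on the somatic firing rate).
#'
#' The somatic and dendritic compartments are coupled by the dimensionless
#' conductance `g_D`; the somatic leak time constant is `tau_mem`.  The
#' attenuation factor relating the dendritic to the stationary somatic
#' potential is `g_D / (g_D + 1/tau_mem)` (see [attenuation_factor()]).
#'
#' `phi0` and `theta0` set the ceiling and the (standardized) threshold of
#' the sigmoidal response function; they are task-dependent and experiment
#' presets override them.  `beta0 = 5` is used throughout.
#'
#' @param n_in number of input (Poisson) neurons.
#' @param n_out number of output (two-compartment) neurons.
#' @param tau_mem somatic membrane time constant (ms).
#' @param g_D soma-dendrite coupling conductance (dimensionless).
#' @param tau_syn synaptic current time constant (ms); 5 by default, 50 for
#'   tasks that need integration over longer timescales (overlapping chunks).
#' @param e0 unit amplitude of the postsynaptic potential.
#' @param phi0 maximal firing rate (events/ms).
#' @param beta0 slope of the response nonlinearity.
#' @param theta0 standardized threshold offset.
#' @param t0 averaging window (ms) for the running mean/s.d. of the somatic
#'   potential (implemented as an exponential moving average with this time
#'   constant).
#' @param dt integration step (ms); must satisfy
#'   `dt <= min(tau_syn, tau_mem)/5`.
#' @param sigma_floor smallest admissible running s.d. (guards the division
#'   in the adaptive slope at initialization).
#'
#' @return An object of class `"mril_sim_params"` (a named list).
#' @export
#' @examples
#' p <- sim_params(n_in = 100, n_out = 5)
#' attenuation_factor(p)
sim_params <- function(n_in, n_out,
                       tau_mem = 15, g_D = 0.7, tau_syn = 5,
                       e0 = 25, phi0 = 0.05, beta0 = 5, theta0 = 1,
                       t0 = 10000, dt = 1, sigma_floor = 0.01) {
  stopifnot(
    is.numeric(n_in), length(n_in) == 1L, n_in >= 1,
    is.numeric(n_out), length(n_out) == 1L, n_out >= 1
  )
  for (nm in c("tau_mem", "g_D", "tau_syn", "e0", "phi0", "beta0",
               "t0", "dt", "sigma_floor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  if (!is.numeric(theta0) || length(theta0) != 1L || !is.finite(theta0))
    stop("'theta0' must be a single finite number")
  if (dt > min(tau_syn, tau_mem) / 5 + 1e-12)
    stop(sprintf("dt = %g too coarse: require dt <= min(tau_syn, tau_mem)/5 = %g",
                 dt, min(tau_syn, tau_mem) / 5))
  structure(
    list(n_in = as.integer(n_in), n_out = as.integer(n_out),
         tau_mem = tau_mem, g_D = g_D, tau_syn = tau_syn, e0 = e0,
         phi0 = phi0, beta0 = beta0, theta0 = theta0, t0 = t0, dt = dt,
         sigma_floor = sigma_floor),
    class = "mril_sim_params"
  )
}

#' Somato-dendritic attenuation factor
#'
#' The stationary ratio between somatic and dendritic membrane potential,
#' `alpha = g_D / (g_D + g_L)` with leak conductance `g_L = 1/tau_mem`.
#' The dendritic prediction compared against the soma is `v* = alpha * v`.
#'
#' @param params a [sim_params()] object.
#' @return A scalar in (0, 1).
#' @export
attenuation_factor <- function(params) {
  params$g_D / (params$g_D + 1 / params$tau_mem)
}

#' Parameters of the MRIL synaptic learning rule
#'
#' @param eta learning rate (per ms).
#' @param gamma L2 regularization strength; pulls weights towards zero and
#'   prevents divergent growth.  Task-dependent.
#' @param g_noise strength of the Gaussian rate noise injected into the
#'   somatic teaching signal by the noise-augmented rule (0.6 where used).
#' @param noise_enabled logical; if `TRUE` the somatic rate in the weight
#'   update is replaced by `f(phi_som + phi0 * g_noise * xi)` with standard
#'   normal `xi` drawn per neuron per step and `f` the clip to `[0, phi0]`.
#' @return An object of class `"mril_learning_params"`.
#' @export
learning_params <- function(eta = 1e-5, gamma = 1, g_noise = 0,
                            noise_enabled = FALSE) {
  stopifnot(
    is.numeric(eta), length(eta) == 1L, eta > 0,
    is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
    is.numeric(g_noise), length(g_noise) == 1L, g_noise >= 0,
    is.logical(noise_enabled), length(noise_enabled) == 1L
  )
  structure(list(eta = eta, gamma = gamma, g_noise = g_noise,
                 noise_enabled = noise_enabled),
            class = "mril_learning_params")
}

#' Parameters of the inhibitory STDP rule
#'
#' The lateral inhibitory weights change by
#' `Cp * exp(-|dt|/tau_p) - Cd * exp(-|dt|/tau_d)` for every pre/post spike
#' pair, a kernel that is symmetric in the spike-timing difference and
#' net-depressing at synchrony (anti-Hebbian for inhibition).  The
#' `"conventional"` mode negates the kernel and serves as a control.
#'
#' @param Cp potentiation amplitude.
#' @param Cd depression amplitude.
#' @param tau_p potentiation decay constant (ms).
#' @param tau_d depression decay constant (ms).
#' @param Gmax upper bound on each inhibitory weight; scales like
#'   `1/sqrt(n_out)` (see [default_gmax()]).
#' @param mode `"anti_hebbian"` (as derived) or `"conventional"`
#'   (sign-reversed control).
#' @return An object of class `"mril_stdp_params"`.
#' @export
stdp_params <- function(Cp = 0.00525, Cd = 0.0105, tau_p = 40, tau_d = 20,
                        Gmax = 0.3, mode = c("anti_hebbian", "conventional")) {
  mode <- match.arg(mode)
  for (nm in c("Cp", "Cd", "tau_p", "tau_d", "Gmax")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  structure(list(Cp = Cp, Cd = Cd, tau_p = tau_p, tau_d = tau_d,
                 Gmax = Gmax, mode = mode),
            class = "mril_stdp_params")
}

#' Default inhibitory weight bound
#'
#' `Gmax = c / sqrt(n_out)`: the bound shrinks with network size so that the
#' total inhibition received by a neuron stays comparable across sizes.
#'
#' @param n_out number of output neurons.
#' @param c proportionality constant.
#' @return A scalar bound.
#' @export
default_gmax <- function(n_out, c = 1.0) c / sqrt(n_out)
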