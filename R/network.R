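#' Initialize feedforward and lateral weights
#'
#' Feedforward weights start from a Gaussian with mean zero and standard
#' deviation `1/sqrt(n_in)`; lateral inhibitory weights start uniform at
#' `Gmax/2` with a zero diagonal.
#'
#' @param params a [sim_params()] object.
#' @param sp a [stdp_params()] object (for `Gmax`).
#' @param seed optional integer seed (RNG state is restored).
#' @return A list with matrices `w` (`n_out` x `n_in`) and `G`
#'   (`n_out` x `n_out`), plus `Gmax`.
#' @export
init_weights <- function(params, sp, seed = NULL) {
  draw <- function() {
    matrix(stats::rnorm(params$n_out * params$n_in, 0, 1 / sqrt(params$n_in)),
           params$n_out, params$n_in)
  }
  w <- if (is.null(seed)) draw() else with_seed(seed, draw())
  G <- matrix(sp$Gmax / 2, params$n_out, params$n_out)
  diag(G) <- 0
  list(w = w, G = G, Gmax = sp$Gmax)
}

#' Simulate the network over an input spike raster
#'
#' Runs the full two-compartment dynamics: synaptic filtering of the input
#' spikes, dendritic and somatic integration with lateral inhibition,
#' adaptive response functions, online MRIL learning of the feedforward
#' weights, Poisson sampling of output spikes and event-driven inhibitory
#' STDP on the lateral weights.
#'
#' @param raster input [spike_raster()] with `n_neurons == params$n_in`.
#' @param params a [sim_params()] object.
#' @param weights list with matrices `w` and `G` (see [init_weights()]).
#' @param lp a [learning_params()] object.
#' @param sp a [stdp_params()] object.
#' @param learn logical: update feedforward weights?
#' @param istdp logical: update lateral weights?
#' @param sample_spikes logical: sample somatic Poisson spikes? (required
#'   for iSTDP; off by default only in deterministic diagnostics).
#' @param record_every record the state every this many integration steps.
#' @param adapt logical: adapt the somatic response parameters to the
#'   running moments of the potential?  `FALSE` freezes them at
#'   `(beta0, theta0)` — the negative control in which selectivity fails
#'   to self-organize.
#' @param seed optional integer seed (RNG state is restored).
#' @param state optional state list from a previous run (resumes traces and
#'   running moments).
#' @param engine `"cpp"` (fast, default) or `"r"` (plain-R reference loop,
#'   step-for-step identical when spike sampling is off).
#' @return A list with final `w`, `G`, the final dynamical `state`, the
#'   recorded traces `rec` (matrices `u`, `v_star`, `phi_som`, `phi_dend`,
#'   `mu`, `sigma` of size `n_out` x n_rec and the vector `time`), and the
#'   sampled output raster `out_raster`.
#' @export
run_network <- function(raster, params, weights, lp = learning_params(),
                        sp = stdp_params(Gmax = default_gmax(params$n_out)),
                        learn = TRUE, istdp = FALSE, sample_spikes = istdp,
                        record_every = 2L, seed = NULL, state = NULL,
                        adapt = TRUE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(raster, "spike_raster"),
            raster$n_neurons == params$n_in,
            nrow(weights$w) == params$n_out, ncol(weights$w) == params$n_in,
            nrow(weights$G) == params$n_out, ncol(weights$G) == params$n_out)
  if (istdp && !sample_spikes)
    stop("istdp requires sample_spikes = TRUE")
  n_steps <- as.integer(ceiling(raster$duration / params$dt))
  bin <- pmin(n_steps, as.integer(floor(raster$events$time / params$dt)) + 1L)
  par <- unclass(params)
  par$adapt <- isTRUE(adapt)
  if (!is.null(state)) par$state0 <- state
  spl <- list(Cp = sp$Cp, Cd = sp$Cd, tau_p = sp$tau_p, tau_d = sp$tau_d,
              Gmax = sp$Gmax, conventional = (sp$mode == "conventional"))
  runner <- function() {
    if (engine == "cpp") {
      sim_run_cpp(bin, raster$events$neuron, n_steps, par, weights$w,
                  weights$G, unclass(lp), spl, learn, istdp, sample_spikes,
                  as.integer(record_every))
    } else {
      sim_run_r(bin, raster$events$neuron, n_steps, par, weights$w,
                weights$G, lp, spl, learn, istdp, sample_spikes,
                as.integer(record_every))
    }
  }
  res <- if (is.null(seed)) runner() else with_seed(seed, runner())
  out <- spike_raster(res$out_neuron, (res$out_bin - 0.5) * params$dt,
                      params$n_out, n_steps * params$dt)
  list(
    w = res$w, G = res$G,
    state = list(u = res$u, mu = res$mu, m2 = res$m2, sigma = res$sigma,
                 I = res$I, e = res$e),
    rec = list(time = res$rec_time, u = res$rec_u, v_star = res$rec_vstar,
               phi_som = res$rec_phi_som, phi_dend = res$rec_phi_dend,
               mu = res$rec_mu, sigma = res$rec_sigma),
    out_raster = out
  )
}

# Plain-R reference loop, mirroring sim_run_cpp step for step.  Used to
# validate the compiled core on small problems; identical draw order.
sim_run_r <- function(bin, neuron, n_steps, par, w, G, lp, spl,
                      learn, istdp_on, sample_spikes, record_every) {
  n_in <- par$n_in; n_out <- par$n_out
  dt <- par$dt; phi0 <- par$phi0; beta0 <- par$beta0; theta0 <- par$theta0
  alpha <- par$g_D / (par$g_D + 1 / par$tau_mem)
  inj <- 1 / (par$tau_mem * par$tau_syn)
  lam <- dt / par$t0
  sgn <- if (spl$conventional) -1 else 1
  u <- numeric(n_out); mu <- numeric(n_out); m2 <- rep(1, n_out)
  sigma <- rep(1, n_out)
  I <- numeric(n_in); e <- numeric(n_in)
  if (!is.null(par$state0)) {
    st <- par$state0
    u <- st$u; mu <- st$mu; m2 <- st$m2
    sigma <- sqrt(pmax(m2 - mu^2, par$sigma_floor^2))
    I <- st$I; e <- st$e
  }
  zp <- numeric(n_out); zd <- numeric(n_out); trace_bin <- 0
  n_rec <- ceiling(n_steps / record_every)
  rec <- list(time = numeric(n_rec),
              u = matrix(0, n_out, n_rec), v_star = matrix(0, n_out, n_rec),
              phi_som = matrix(0, n_out, n_rec),
              phi_dend = matrix(0, n_out, n_rec),
              mu = matrix(0, n_out, n_rec), sigma = matrix(0, n_out, n_rec))
  out_neuron <- integer(0); out_bin <- integer(0)
  sp_by_bin <- split(neuron, bin)
  ri <- 0L
  for (k in seq_len(n_steps)) {
    s <- sp_by_bin[[as.character(k)]]
    if (!is.null(s)) for (j in s) I[j] <- I[j] + inj
    v <- drop(w %*% e)
    vs <- alpha * v
    sgm <- pmax(sigma, par$sigma_floor)
    uhat <- (u - mu) / sgm
    ps <- phi0 / (1 + exp(beta0 * (theta0 - uhat)))
    pd <- phi0 / (1 + exp(beta0 * (theta0 - vs)))
    psif <- beta0 * (1 - pd / phi0)
    inh <- drop(G %*% (ps / phi0))
    if ((k - 1L) %% record_every == 0L) {
      ri <- ri + 1L
      rec$time[ri] <- (k - 1) * dt
      rec$u[, ri] <- u; rec$v_star[, ri] <- vs
      rec$phi_som[, ri] <- ps; rec$phi_dend[, ri] <- pd
      rec$mu[, ri] <- mu; rec$sigma[, ri] <- sigma
    }
    if (learn) {
      teach <- ps
      if (lp$noise_enabled)
        teach <- clip_linear(ps + phi0 * lp$g_noise * stats::rnorm(n_out), phi0)
      coef <- lp$eta * dt * psif * (teach - pd) / phi0
      w <- w + outer(coef, e) - lp$eta * dt * lp$gamma * w
    }
    u <- u + dt * (-u / par$tau_mem + par$g_D * (v - u) - inh)
    if (!isFALSE(par$adapt)) {
      mu <- mu + lam * (u - mu)
      m2 <- m2 + lam * (u^2 - m2)
      sigma <- sqrt(pmax(m2 - mu^2, par$sigma_floor^2))
    }
    if (sample_spikes) {
      spiked <- which(stats::runif(n_out) < ps * dt)
      if (length(spiked)) {
        if (istdp_on) {
          gap <- (k - trace_bin) * dt
          if (gap > 0) {
            zp <- zp * exp(-gap / spl$tau_p)
            zd <- zd * exp(-gap / spl$tau_d)
          }
          trace_bin <- k
          for (i in spiked) {
            dg <- sgn * (spl$Cp * zp - spl$Cd * zd)
            dg[i] <- 0
            G[i, ] <- pmin(pmax(G[i, ] + dg, 0), spl$Gmax)
            G[, i] <- pmin(pmax(G[, i] + dg, 0), spl$Gmax)
            G[i, i] <- 0
            zp[i] <- zp[i] + 1; zd[i] <- zd[i] + 1
          }
        }
        out_neuron <- c(out_neuron, spiked)
        out_bin <- c(out_bin, rep.int(k, length(spiked)))
      }
    }
    pr <- propagate_traces(I, e, par)
    I <- pr$I; e <- pr$e
  }
  list(w = w, G = G, u = u, mu = mu, m2 = m2, sigma = sigma, I = I, e = e,
       rec_time = rec$time, rec_u = rec$u, rec_vstar = rec$v_star,
       rec_phi_som = rec$phi_som, rec_phi_dend = rec$phi_dend,
       rec_mu = rec$mu, rec_sigma = rec$sigma,
       out_neuron = out_neuron, out_bin = out_bin)
}

#' Save network weights as plain text
#'
#' Writes the feedforward matrix `w` and lateral matrix `G` into one file
#' with full double precision, so that [load_weights()] round-trips
#' bit-identically.  Enables training on one stimulus ensemble and testing
#' (or resuming) on another.
#'
#' @param weights list with matrices `w`, `G` and scalar `Gmax`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mrilnet weights v1 n_out=%d n_in=%d Gmax=%.17g",
                     nrow(weights$w), ncol(weights$w),
                     if (is.null(weights$Gmax)) NA_real_ else weights$Gmax), con)
  writeLines(apply(weights$w, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines("# G", con)
  writeLines(apply(weights$G, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Load network weights written by [save_weights()]
#'
#' @param path file path.
#' @param params optional [sim_params()]; if given, dimensions are checked
#'   against `n_out` and `n_in` and a mismatch is an error.
#' @return A list with matrices `w`, `G` and scalar `Gmax`.
#' @export
load_weights <- function(path, params = NULL) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1], regexec(
    "^# mrilnet weights v1 n_out=(\\d+) n_in=(\\d+) Gmax=([-0-9.eEgNA+]+)$",
    lines[1]))[[1]]
  if (length(hdr) != 4) stop("unrecognized weights file version: ", lines[1])
  n_out <- as.integer(hdr[2]); n_in <- as.integer(hdr[3])
  gmax <- suppressWarnings(as.numeric(hdr[4]))
  parse_rows <- function(rows, ncols) {
    m <- t(vapply(strsplit(rows, " ", fixed = TRUE),
                  function(p) as.numeric(p), numeric(ncols)))
    matrix(m, length(rows), ncols)
  }
  w <- parse_rows(lines[2:(1 + n_out)], n_in)
  stopifnot(lines[2 + n_out] == "# G")
  G <- parse_rows(lines[(3 + n_out):(2 + 2 * n_out)], n_out)
  if (!is.null(params) && (n_out != params$n_out || n_in != params$n_in))
    stop(sprintf("weights are %d x %d but network expects %d x %d",
                 n_out, n_in, params$n_out, params$n_in))
  list(w = w, G = G, Gmax = gmax)
}
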