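test_that("synaptic filter reproduces the closed-form single-spike response", {
  p <- sim_params(n_in = 1, n_out = 1, tau_syn = 5, tau_mem = 15, e0 = 25)
  r <- spike_raster(1, 0.5, 1, 200)
  f <- synaptic_filter(r, p)
  tt <- 0:199
  I_expected <- exp(-tt / 5) / (5 * 15)
  expect_lt(max(abs(f$I[1, ] - I_expected)), 1e-3)
  # integral of I equals 1/tau_mem (one spike's area); trapezoidal rule on
  # the exact bin-boundary samples
  area <- (sum(f$I[1, ]) - 0.5 * (f$I[1, 1] + f$I[1, 200])) * p$dt
  expect_equal(area, 1 / 15, tolerance = 1e-2)
  # e matches the two-exponential closed form
  e_expected <- 25 / (5 * 15) * (exp(-tt / 15) - exp(-tt / 5)) / (1 / 5 - 1 / 15)
  expect_lt(max(abs(f$e[1, ] - e_expected)), 1e-3)
})

test_that("synaptic filtering is linear in the input", {
  p <- sim_params(n_in = 2, n_out = 1)
  r1 <- spike_raster(c(1, 2, 1), c(3.5, 20.5, 61.5), 2, 100)
  # doubling every spike doubles the traces exactly
  r2 <- spike_raster(rep(c(1, 2, 1), each = 2),
                     rep(c(3.5, 20.5, 61.5), each = 2), 2, 100)
  f1 <- synaptic_filter(r1, p)
  f2 <- synaptic_filter(r2, p)
  expect_lt(max(abs(f2$I - 2 * f1$I)), 1e-10)
  expect_lt(max(abs(f2$e - 2 * f1$e)), 1e-10)
  # no spikes: identically zero
  f0 <- synaptic_filter(spike_raster(integer(0), numeric(0), 2, 100), p)
  expect_true(all(f0$I == 0) && all(f0$e == 0))
})

test_that("dendritic potential is the weighted PSP sum", {
  w <- diag(3)
  expect_equal(dendritic_potential(w, c(5, 7, 9)), c(5, 7, 9))
  expect_equal(dendritic_potential(matrix(0, 2, 4), rep(1, 4)), c(0, 0))
  set.seed(1)
  w <- matrix(rnorm(12), 3, 4); e <- rnorm(4)
  oracle <- vapply(1:3, function(i) sum(sapply(1:4, function(j) w[i, j] * e[j])),
                   numeric(1))
  expect_equal(dendritic_potential(w, e), oracle, tolerance = 1e-12)
  expect_error(dendritic_potential(w, rnorm(5)), "shape")
})

test_that("attenuated potential scales by alpha", {
  p <- sim_params(n_in = 1, n_out = 1)
  expect_equal(attenuated_potential(0, p), 0)
  expect_equal(attenuated_potential(c(1, -2), p), 0.9130435 * c(1, -2),
               tolerance = 1e-6)
})

test_that("response function has sigmoid midpoint, range and baseline", {
  phi0 <- 0.05
  expect_equal(response_function(1, 5, 1, phi0), phi0 / 2)
  expect_equal(response_function(-1e3, 5, 1, phi0), 0, tolerance = 1e-12)
  expect_equal(response_function(1e3, 5, 1, phi0), phi0, tolerance = 1e-12)
  x <- seq(-5, 5, length.out = 101)
  y <- response_function(x, 5, 1, phi0)
  expect_true(all(diff(y) > 0))       # monotone increasing
  expect_true(all(y > 0 & y < phi0))  # strict range
  expect_error(response_function(0, -1, 0, phi0), "positive")
  # standardized baseline: phi_som(u)/phi0 at u_hat = 0 is 1/(1 + e^(b0*th0))
  p <- sim_params(n_in = 1, n_out = 1, beta0 = 5, theta0 = 1)
  expect_equal(phi_som(0, mu = 0, sigma = 1, p) / p$phi0,
               1 / (1 + exp(5 * 1)), tolerance = 1e-12)
})

test_that("adaptive response parameters standardize the potential", {
  p <- sim_params(n_in = 1, n_out = 1, beta0 = 5, theta0 = 1)
  ap <- adapt_response_params(0, 1, p)
  expect_equal(ap$beta, 5); expect_equal(ap$theta, 1)
  ap <- adapt_response_params(3, 2, p)
  expect_equal(ap$beta, 2.5); expect_equal(ap$theta, 5)
  # composing with the response equals the fixed sigmoid on (u - mu)/sigma
  u <- seq(-4, 8, length.out = 50); mu <- 1.7; sig <- 2.3
  expect_equal(phi_som(u, mu, sig, p),
               phi_dend((u - mu) / sig, p), tolerance = 1e-12)
  # sigma below the floor is clamped, never divided through
  ap <- adapt_response_params(0, 1e-9, p)
  expect_equal(ap$beta, p$beta0 / p$sigma_floor)
})

test_that("running moments track a stationary stream", {
  p <- sim_params(n_in = 1, n_out = 1, t0 = 500, dt = 1)
  mu <- 0; m2 <- 1
  set.seed(5)
  for (k in 1:(20 * 500)) {
    up <- update_running_moments(mu, m2, rnorm(1, 2, 3), p)
    mu <- up$mu; m2 <- up$m2
  }
  expect_equal(up$mu, 2, tolerance = 0.05 * 3 / 2 * 2)  # within ~5% of scale
  expect_equal(up$sigma, 3, tolerance = 0.15)
  # degenerate: constant input drives sigma to the floor
  mu <- 0; m2 <- 1
  for (k in 1:(30 * 500)) {
    up <- update_running_moments(mu, m2, 4, p)
    mu <- up$mu; m2 <- up$m2
  }
  expect_equal(up$mu, 4, tolerance = 1e-3)
  expect_equal(up$sigma, p$sigma_floor, tolerance = 1e-3)
  # homogeneity: scaling u scales sigma (above the floor)
  expect_equal(update_running_moments(0, 1, 5, p)$sigma * 2,
               update_running_moments(0, 4, 10, p)$sigma, tolerance = 1e-9)
})

test_that("somatic dynamics relax to the attenuated dendritic potential", {
  p <- sim_params(n_in = 1, n_out = 2)
  G0 <- matrix(0, 2, 2)
  v <- c(1.5, -0.8)
  state <- list(u = c(0, 0), v = v, mu = c(0, 0), sigma = c(1, 1))
  for (k in 1:(20 * p$tau_mem)) state$u <- somatic_step(state, list(G = G0), p)
  expect_equal(state$u, attenuated_potential(v, p), tolerance = 1e-3)
  # pure decay at rate 1/tau + g_D when v = 0, G = 0
  state <- list(u = c(1, 1), v = c(0, 0), mu = c(0, 0), sigma = c(1, 1))
  u1 <- somatic_step(state, list(G = G0), p)
  expect_equal(u1[1], 1 + p$dt * (-(1 / p$tau_mem + p$g_D)), tolerance = 1e-12)
  # inhibition can only lower the next potential
  state <- list(u = c(0.5, 0.5), v = c(1, 1), mu = c(0, 0), sigma = c(1, 1))
  u_free <- somatic_step(state, list(G = matrix(0, 2, 2)), p)
  u_inh <- somatic_step(state, list(G = matrix(c(0, 1, 1, 0), 2, 2)), p)
  expect_true(all(u_inh <= u_free))
})
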