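test_that("compiled and plain-R engines produce identical trajectories", {
  p <- tiny_params(n_in = 15, n_out = 4)
  prog <- frozen_pattern_stream(15, 2, duration = 2000, seed = 3)
  ras <- realize_spikes(prog, seed = 5)
  sp <- stdp_params(Gmax = 0.5)
  w0 <- init_weights(p, sp, seed = 7)
  lp <- learning_params(eta = 1e-3, gamma = 1)
  a <- run_network(ras, p, w0, lp, sp, learn = TRUE, istdp = FALSE,
                   sample_spikes = FALSE, engine = "cpp")
  b <- run_network(ras, p, w0, lp, sp, learn = TRUE, istdp = FALSE,
                   sample_spikes = FALSE, engine = "r")
  expect_lt(max(abs(a$w - b$w)), 1e-12)
  expect_lt(max(abs(a$state$u - b$state$u)), 1e-12)
  expect_lt(max(abs(a$rec$phi_som - b$rec$phi_som)), 1e-12)
  # stochastic path (spiking + iSTDP + learning noise): same seed, same draws
  lpn <- learning_params(eta = 1e-3, gamma = 1, g_noise = 0.6,
                         noise_enabled = TRUE)
  a2 <- run_network(ras, p, w0, lpn, sp, istdp = TRUE, seed = 11)
  b2 <- run_network(ras, p, w0, lpn, sp, istdp = TRUE, seed = 11, engine = "r")
  expect_lt(max(abs(a2$G - b2$G)), 1e-12)
  expect_lt(max(abs(a2$w - b2$w)), 1e-12)
  expect_identical(a2$out_raster$events, b2$out_raster$events)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  p <- tiny_params(n_in = 12, n_out = 3)
  prog <- chunk_char_stream("abc", 12, duration = 3000, seed = 2)
  ras <- realize_spikes(prog, seed = 4)
  sp <- stdp_params(Gmax = 0.4)
  w0 <- init_weights(p, sp, seed = 6)
  r1 <- run_network(ras, p, w0, learning_params(), sp, istdp = TRUE, seed = 9)
  r2 <- run_network(ras, p, w0, learning_params(), sp, istdp = TRUE, seed = 9)
  expect_identical(r1$w, r2$w)
  expect_identical(r1$G, r2$G)
  expect_identical(r1$out_raster$events, r2$out_raster$events)
})

test_that("online iSTDP equals the standalone operator on the same spikes", {
  p <- tiny_params(n_in = 10, n_out = 5, phi0 = 0.05, theta0 = 0.5)
  prog <- frozen_pattern_stream(10, 1, duration = 4000, seed = 8)
  ras <- realize_spikes(prog, seed = 10)
  sp <- stdp_params(Gmax = 0.4)
  w0 <- init_weights(p, sp, seed = 12)
  res <- run_network(ras, p, w0, learning_params(), sp, learn = FALSE,
                     istdp = TRUE, seed = 14)
  expect_gt(nrow(res$out_raster$events), 0)
  G_off <- apply_istdp(w0$G, res$out_raster, res$out_raster, sp)
  expect_lt(max(abs(res$G - G_off)), 1e-12)
})

test_that("rates stay inside (0, phi0) and the state stays finite", {
  p <- tiny_params(n_in = 20, n_out = 6, phi0 = 0.05)
  prog <- frozen_pattern_stream(20, 3, duration = 20000, seed = 1)
  ras <- realize_spikes(prog, seed = 2)
  sp <- stdp_params(Gmax = 0.4)
  w0 <- init_weights(p, sp, seed = 3)
  res <- run_network(ras, p, w0, learning_params(eta = 1e-3, gamma = 0.5),
                     sp, istdp = TRUE, seed = 4)
  expect_true(all(is.finite(res$rec$phi_som)))
  expect_true(all(res$rec$phi_som > 0 & res$rec$phi_som < p$phi0))
  expect_true(all(is.finite(res$w)))
  expect_true(all(res$G >= 0 & res$G <= sp$Gmax))
  expect_true(all(diag(res$G) == 0))
  expect_true(all(res$state$sigma >= p$sigma_floor))
})

test_that("frozen dendritic drive converges to alpha * v (0.1% after 10 tau)", {
  # one input neuron firing regularly; weights fixed; G = 0; after the
  # traces settle the somatic potential tracks alpha * v
  p <- sim_params(n_in = 1, n_out = 1, t0 = 1e7)
  ras <- spike_raster(rep(1, 500), seq(0.5, 4999.5, by = 10), 1, 5000)
  w <- matrix(2.5, 1, 1)
  res <- run_network(ras, p, list(w = w, G = matrix(0, 1, 1)),
                     learning_params(), stdp_params(Gmax = 1), learn = FALSE,
                     istdp = FALSE, sample_spikes = FALSE, record_every = 1L)
  tail_idx <- res$rec$time > 5000 - 10 * p$tau_mem
  u_tail <- res$rec$u[1, tail_idx]
  vs_tail <- res$rec$v_star[1, tail_idx]
  # ripple from 10 ms-periodic input leaves a small tracking lag
  expect_lt(max(abs(u_tail - vs_tail) / pmax(abs(vs_tail), 1e-12)), 0.1)
  # with strictly constant drive the bound tightens to 0.1%
  p2 <- sim_params(n_in = 1, n_out = 1, t0 = 1e7)
  st <- init_state(p2); st$m2 <- 1
  G0 <- list(G = matrix(0, 1, 1))
  v_const <- 1.7
  state <- list(u = 0, v = v_const, mu = 0, sigma = 1)
  for (k in 1:(10 * p2$tau_mem)) state$u <- somatic_step(state, G0, p2)
  expect_lt(abs(state$u - attenuation_factor(p2) * v_const) /
              (attenuation_factor(p2) * v_const), 1e-3)
})

test_that("standardization holds after long stationary input", {
  p <- tiny_params(n_in = 30, n_out = 3, t0 = 2000)
  prog <- frozen_pattern_stream(30, 1, duration = 20 * 2000, occupancy = 0,
                                seed = 5)
  ras <- realize_spikes(prog, seed = 6)
  w0 <- init_weights(p, stdp_params(Gmax = 1), seed = 7)
  res <- run_network(ras, p, w0, learning_params(), stdp_params(Gmax = 1),
                     learn = FALSE, istdp = FALSE, sample_spikes = FALSE)
  late <- res$rec$time > 10 * 2000
  for (i in 1:3) {
    uhat <- (res$rec$u[i, late] - res$rec$mu[i, late]) / res$rec$sigma[i, late]
    expect_gt(mean(uhat), -0.1)
    expect_lt(mean(uhat), 0.1)
    expect_gt(stats::var(uhat), 0.8)
    expect_lt(stats::var(uhat), 1.2)
  }
})

test_that("frozen response adaptation disables the standardization", {
  p <- tiny_params(n_in = 20, n_out = 2, t0 = 500)
  prog <- frozen_pattern_stream(20, 1, duration = 10000, seed = 3)
  ras <- realize_spikes(prog, seed = 4)
  w0 <- init_weights(p, stdp_params(Gmax = 1), seed = 5)
  on <- run_network(ras, p, w0, learning_params(), stdp_params(Gmax = 1),
                    learn = FALSE, istdp = FALSE, sample_spikes = FALSE,
                    adapt = TRUE)
  off <- run_network(ras, p, w0, learning_params(), stdp_params(Gmax = 1),
                     learn = FALSE, istdp = FALSE, sample_spikes = FALSE,
                     adapt = FALSE)
  # with adaptation the moments move; frozen they stay at (0, 1)
  expect_gt(max(abs(on$state$mu)), 0)
  expect_identical(off$state$mu, c(0, 0))
  expect_identical(off$state$m2, c(1, 1))
  # frozen adaptation means the somatic rate is the fixed sigmoid of u
  expect_equal(off$rec$phi_som,
               response_function(off$rec$u, p$beta0, p$theta0, p$phi0),
               tolerance = 1e-12)
})

test_that("weights round-trip losslessly and reject mismatched networks", {
  p <- tiny_params(n_in = 8, n_out = 3)
  sp <- stdp_params(Gmax = 0.7)
  w <- init_weights(p, sp, seed = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  save_weights(w, path)
  w2 <- load_weights(path)
  expect_identical(w2$w, w$w)
  expect_identical(w2$G, w$G)
  expect_identical(w2$Gmax, w$Gmax)
  expect_error(load_weights(path, params = tiny_params(n_in = 9, n_out = 3)),
               "expects")
})
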