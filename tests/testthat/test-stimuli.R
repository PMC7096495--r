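test_that("generators are seed-deterministic and label-complete", {
  progs <- list(
    frozen_pattern_stream(50, 3, duration = 5000, seed = 4),
    chunk_char_stream(c("abcd", "efgh"), 50, duration = 5000, seed = 4),
    community_walk_stream(50, steps = 100, seed = 4),
    bar_image_stream(8, 4, n_images = 20, seed = 4)
  )
  for (prog in progs) {
    expect_length(prog$labels, prog$duration)
    expect_true(all(prog$labels >= 0))
    r1 <- realize_spikes(prog, seed = 9)
    r2 <- realize_spikes(prog, seed = 9)
    expect_identical(r1$events, r2$events)
  }
  # same generator seed, fresh call: identical structure
  pa <- frozen_pattern_stream(50, 3, duration = 5000, seed = 4)
  pb <- frozen_pattern_stream(50, 3, duration = 5000, seed = 4)
  expect_identical(pa$labels, pb$labels)
  expect_identical(pa$fixed_events, pb$fixed_events)
})

test_that("frozen patterns replay identically and preserve mean rates", {
  prog <- frozen_pattern_stream(100, 2, duration = 60000, pattern_ms = 50,
                                base_rate = 0.01, occupancy = 0.5,
                                assembly_fraction = 0.5, seed = 7)
  # every occurrence of a pattern replays the same within-epoch spikes
  ev <- prog$fixed_events
  lab_of <- prog$labels[pmin(length(prog$labels), floor(ev$time) + 1L)]
  occ1 <- which(prog$labels == 1)
  slots1 <- unique((occ1 - 1) %/% 50)
  sig <- lapply(slots1[1:3], function(sl) {
    sel <- ev$time >= sl * 50 & ev$time < (sl + 1) * 50 & lab_of == 1
    data.frame(neuron = ev$neuron[sel], off = round(ev$time[sel] - sl * 50, 9))
  })
  expect_identical(sig[[1]][order(sig[[1]]$off), ], sig[[2]][order(sig[[2]]$off), ],
                   ignore_attr = TRUE)
  # participant and non-participant populations have equal average rates
  r <- realize_spikes(prog, seed = 3)
  part <- prog$meta$participants[[1]]
  in1 <- tabulate(r$events$neuron, 100)
  rate_part <- mean(in1[part]); rate_rest <- mean(in1[-part])
  expect_lt(abs(rate_part - rate_rest) / rate_rest, 0.02 + 3 / sqrt(60000 * 0.01 * 50))
})

test_that("population mean rate of participants matches non-participants", {
  # long stream, tight check of the 2% equality invariant
  prog <- frozen_pattern_stream(200, 1, duration = 200000, base_rate = 0.01,
                                occupancy = 0.4, assembly_fraction = 0.25,
                                seed = 12)
  r <- realize_spikes(prog, seed = 5)
  part <- prog$meta$participants[[1]]
  cnt <- tabulate(r$events$neuron, 200)
  expect_lt(abs(mean(cnt[part]) / mean(cnt[-part]) - 1), 0.02)
})

test_that("corrupt_stream degrades pattern spikes as specified", {
  prog <- frozen_pattern_stream(60, 2, duration = 30000, seed = 2)
  n_tgt <- nrow(prog$fixed_events)
  # identity corruption
  same <- corrupt_stream(prog, 0, 0, 0)
  expect_identical(realize_spikes(same, seed = 8)$events,
                   realize_spikes(prog, seed = 8)$events)
  # total failure removes every frozen spike (identified by exact times:
  # frozen times are continuous, Poisson spikes sit at bin centers)
  dead <- corrupt_stream(prog, 0, 1, 0)
  r <- realize_spikes(dead, seed = 8)
  expect_equal(sum(r$events$time %in% prog$fixed_events$time), 0)
  # 50% failure: binomial count of surviving frozen spikes
  half <- corrupt_stream(prog, 0, 0.5, 0)
  survived <- vapply(1:20, function(s)
    sum(realize_spikes(half, seed = s)$events$time %in%
          prog$fixed_events$time), numeric(1))
  expect_lt(abs(mean(survived) - 0.5 * n_tgt), 4 * sqrt(0.25 * n_tgt / 20))
  # background contamination adds ~ratio * n_target spikes
  noisy <- corrupt_stream(prog, background_ratio = 2, 0, 0)
  extra <- nrow(realize_spikes(noisy, seed = 8)$events) -
    nrow(realize_spikes(prog, seed = 8)$events)
  expect_lt(abs(extra - 2 * n_tgt), 4 * sqrt(2 * n_tgt))
})

test_that("chunk streams encode characters as assigned bursts", {
  prog <- chunk_char_stream("abcd", n_in = 40, duration = 12000,
                            char_ms = 30, burst_rate = 0.01, seed = 6)
  # one repeated chunk: all labels are chunk 1
  expect_true(all(prog$labels == 1L))
  r <- realize_spikes(prog, seed = 2)
  # neurons whose preferred character is in the chunk fire; others silent
  pref <- prog$meta$preferred
  active <- sort(unique(r$events$neuron))
  expect_true(all(pref[active] %in% c("a", "b", "c", "d")))
  silent <- setdiff(which(!pref %in% c("a", "b", "c", "d")), active)
  expect_length(intersect(active, silent), 0)
  # bursts land in the correct 30 ms slots
  slot_char <- prog$meta$sequence[floor(r$events$time / 30) + 1]
  expect_true(all(pref[r$events$neuron] == slot_char))
})

test_that("community walk follows the degree-4 graph uniformly", {
  g <- community_graph()
  expect_true(all(rowSums(g$adjacency) == 4))
  expect_true(all(g$adjacency == t(g$adjacency)))
  prog <- community_walk_stream(10, steps = 20000, seed = 9)
  walk <- prog$meta$walk
  # never jumps to a non-neighbor
  expect_true(all(g$adjacency[cbind(walk[-length(walk)], walk[-1])] == 1))
  # empirical transition frequencies ~ 0.25 to each neighbor
  tr <- table(factor(walk[-length(walk)], 1:15), factor(walk[-1], 1:15))
  freq <- tr / rowSums(tr)
  nz <- freq[g$adjacency == 1]
  expect_true(all(abs(nz - 0.25) < 4 * sqrt(0.25 * 0.75 / (20000 / 15))))
  # stationary occupancy uniform over the 15 nodes (chi-square)
  expect_gt(chisq.test(table(factor(walk, 1:15)))$p.value, 1e-4)
})

test_that("bar image stream times presentations and encodes orientation", {
  prog <- bar_image_stream(8, 4, noise_level = 0, n_images = 30,
                           present_ms = 40, gap_ms = 30, seed = 3)
  # exact 40 ms epochs separated by 30 ms gaps
  lab <- prog$labels
  runs <- rle(lab > 0)
  expect_true(all(runs$lengths[runs$values] == 40))
  expect_true(all(runs$lengths[!runs$values] == 30))
  # with no noise, rates are a deterministic function of orientation
  rb <- prog$rate_block(0, 70, 1)
  ori1 <- prog$meta$orientations[1]
  expect_equal(rb[, 1], prog$meta$masks[, ori1] * 0.01)
  expect_true(all(rb[, 41:70] == 0))
  # orthogonal thin bars share few pixels
  m0 <- bar_mask(16, 0); m90 <- bar_mask(16, pi / 2)
  overlap <- sum(m0 * m90) / sqrt(sum(m0^2) * sum(m90^2))
  expect_lt(overlap, 0.25)
})

test_that("synthetic sources hit their target envelope correlations", {
  rs <- vapply(1:6, function(s) {
    x <- synth_correlated_sources(60, 100, "dependent", seed = s)
    cor(x$env1, x$env2)
  }, numeric(1))
  expect_true(all(rs > 0.4 & rs < 0.8))
  ri <- vapply(1:6, function(s) {
    x <- synth_correlated_sources(60, 100, "independent", seed = s)
    cor(x$env1, x$env2)
  }, numeric(1))
  expect_lt(max(abs(ri)), 0.15)
  a <- synth_correlated_sources(10, 100, "dependent", seed = 1)
  b <- synth_correlated_sources(10, 100, "dependent", seed = 1)
  expect_identical(a$x1, b$x1)
})

test_that("mixing behaves as rotation-like cross-talk", {
  set.seed(2)
  x1 <- rnorm(500); x2 <- rnorm(500)
  # theta = 0: mixtures equal sources
  m0 <- mix_sources(x1, x2, 0)
  expect_equal(m0$m1, x1); expect_equal(m0$m2, x2)
  expect_equal(m0$config$crosstalk, 0)
  # theta = pi/4: both mixtures identical, crosstalk 1
  m45 <- mix_sources(x1, x2, pi / 4)
  expect_equal(m45$m1, m45$m2)
  expect_equal(m45$config$crosstalk, 1)
  # unmixing with the matrix inverse recovers the sources
  th <- pi / 6
  m <- mix_sources(x1, x2, th)
  rec <- solve(m$config$matrix) %*% rbind(m$m1, m$m2)
  expect_lt(max(abs(rec[1, ] - x1)), 1e-10)
  expect_lt(max(abs(rec[2, ] - x2)), 1e-10)
  # fixed-matrix preset
  mf <- mix_sources(x1, x2, theta = NULL)
  expect_equal(mf$m1, x1 + 0.5 * x2)
  expect_error(mix_sources(x1, x2[-1], 0.1), "equal length")
})

test_that("amplitude encoding maps peak to max rate, scale-invariantly", {
  x <- synth_correlated_sources(20, 100, "dependent", seed = 5)
  prog <- amplitude_to_rate(list(x$x1, x$x2), n_in = 20, sample_rate = 100)
  rb <- prog$rate_block(0, prog$duration, 1)
  expect_equal(max(rb), 0.01, tolerance = 1e-12)
  expect_true(all(rb >= 0))
  # population split evenly between the two signals
  expect_equal(sum(prog$meta$split == 1), 10)
  # doubling both signals leaves rates unchanged
  prog2 <- amplitude_to_rate(list(2 * x$x1, 2 * x$x2), 20, 100)
  expect_equal(prog2$rate_block(0, prog$duration, 1), rb)
  # zero stretches encode as silence; all-zero input is an error
  expect_error(amplitude_to_rate(list(numeric(100), numeric(100)), 10, 100),
               "zero")
})
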