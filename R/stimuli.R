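#' Stimulus program container
#'
#' A rate schedule over time for the input population plus a ground-truth
#' label track for evaluation.  Generators freeze all structural randomness
#' (sequences, preferred characters, frozen patterns) at construction time;
#' [realize_spikes()] then draws only the Poisson spiking noise, so the same
#' program can be realized many times over the same ground truth.
#'
#' @param n_in input population size.
#' @param duration program length (ms).
#' @param labels integer vector with one label per ms (0 = no label).
#' @param label_names character names for labels `1..K`.
#' @param rate_block `function(t0, t1, dt)` returning the rate matrix
#'   (events/ms, `n_in` x bins) for bins covering `[t0, t1)`; may be `NULL`
#'   when `realize` is fully custom.
#' @param realize `function(dt)` returning a [spike_raster()]; defaults to
#'   block-wise Poisson sampling of `rate_block`.
#' @param fixed_events optional data.frame (`neuron`, `time`) of
#'   deterministic spikes merged into every realization (frozen patterns).
#' @param meta list of generator parameters (provenance).
#' @return An object of class `"stimulus_program"`.
#' @export
stimulus_program <- function(n_in, duration, labels, label_names = NULL,
                             rate_block = NULL, realize = NULL,
                             fixed_events = NULL, meta = list()) {
  stopifnot(length(labels) == as.integer(duration))
  prog <- structure(
    list(n_in = as.integer(n_in), duration = duration,
         labels = as.integer(labels), label_names = label_names,
         rate_block = rate_block, realize = realize,
         fixed_events = fixed_events, meta = meta),
    class = "stimulus_program")
  if (is.null(prog$realize)) {
    if (is.null(rate_block)) stop("either rate_block or realize is required")
    prog$realize <- function(dt) default_realize(prog, dt)
  }
  prog
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat(sprintf("<stimulus_program> %d inputs, %.6g ms, %d label classes (%s)\n",
              x$n_in, x$duration, length(x$label_names),
              paste(utils::head(x$label_names, 6), collapse = ", ")))
  invisible(x)
}

# Block-wise Poisson realization of a rate schedule plus frozen events.
# Bernoulli-per-bin sampling is done by drawing the binomial number of
# successes per distinct rate level and sampling bins without replacement
# (the exact same distribution, far fewer RNG draws for near-constant
# schedules).
default_realize <- function(prog, dt, block_ms = 5000) {
  neuron <- integer(0); time <- numeric(0)
  t0 <- 0
  while (t0 < prog$duration) {
    t1 <- min(t0 + block_ms, prog$duration)
    rates <- prog$rate_block(t0, t1, dt)
    if (min(rates) < 0) stop("negative rate in schedule")
    if (max(rates) * dt > 1) stop("rate * dt exceeds 1: bin too coarse")
    nz <- which(rates > 0)
    pv <- rates[nz] * dt
    lv <- prog$meta$rate_levels
    lv <- if (is.null(lv)) unique(pv) else lv[lv > 0] * dt
    if (length(lv) == 1) {
      k <- stats::rbinom(1, length(nz), lv)
      hit <- if (k > 0) nz[sample.int(length(nz), k)] else integer(0)
    } else if (length(lv) <= 8) {
      hit <- integer(0)
      for (p1 in lv) {
        idx <- nz[pv == p1]
        k <- stats::rbinom(1, length(idx), p1)
        if (k > 0) hit <- c(hit, idx[sample.int(length(idx), k)])
      }
    } else {
      hit <- nz[stats::runif(length(nz)) < pv]
    }
    n <- nrow(rates)
    neuron <- c(neuron, ((hit - 1L) %% n) + 1L)
    time <- c(time, t0 + (((hit - 1L) %/% n)) * dt + dt / 2)
    t0 <- t1
  }
  if (!is.null(prog$fixed_events) && nrow(prog$fixed_events)) {
    neuron <- c(neuron, prog$fixed_events$neuron)
    time <- c(time, prog$fixed_events$time)
  }
  spike_raster(neuron, time, prog$n_in, prog$duration)
}

#' Realize a stimulus program as a spike raster
#'
#' Draws one Poisson realization of the program's rate schedule (merging
#' any frozen deterministic events).  With a `seed` the draw is reproducible
#' and the caller's RNG state is untouched.
#'
#' @param prog a [stimulus_program()].
#' @param dt bin width (ms).
#' @param seed optional integer seed.
#' @return A [spike_raster()].
#' @export
realize_spikes <- function(prog, dt = 1, seed = NULL) {
  stopifnot(inherits(prog, "stimulus_program"))
  if (is.null(seed)) prog$realize(dt) else with_seed(seed, prog$realize(dt))
}

#' Labels resampled at the simulation recording resolution
#'
#' @param prog a [stimulus_program()].
#' @param times vector of times (ms) at which labels are needed.
#' @return Integer labels at those times (0 = unlabeled).
#' @export
labels_at <- function(prog, times) {
  idx <- pmin(length(prog$labels), floor(times) + 1L)
  prog$labels[idx]
}

# ---------------------------------------------------------------------------
# Frozen spatiotemporal patterns

#' Frozen spatiotemporal pattern stream
#'
#' Background Poisson firing at `base_rate` everywhere; at pattern epochs, a
#' frozen spike realization (identical at every occurrence) replaces the
#' background activity of the participating neurons.  The timeline is
#' divided into slots of `pattern_ms`; each slot is a pattern epoch with
#' probability `occupancy` (the pattern drawn uniformly), otherwise
#' background.  Each frozen pattern contains exactly
#' `round(n_participants * base_rate * pattern_ms)` spikes placed uniformly,
#' so participating and non-participating neurons have the same average
#' firing rate and detection cannot rely on rate differences.
#'
#' @param n_in input population size.
#' @param n_patterns number of distinct frozen patterns.
#' @param duration stream length (ms).
#' @param pattern_ms pattern length (ms).
#' @param base_rate background rate (events/ms).
#' @param occupancy probability that a slot carries a pattern.
#' @param assembly_fraction fraction of the population participating in each
#'   pattern (participants drawn independently per pattern).
#' @param seed integer seed freezing patterns, participants and the slot
#'   sequence.
#' @return A [stimulus_program()]; labels give the pattern id per ms.
#' @export
frozen_pattern_stream <- function(n_in, n_patterns = 3, duration = 100000,
                                  pattern_ms = 50, base_rate = 0.01,
                                  occupancy = 0.5, assembly_fraction = 1,
                                  seed = 1) {
  stopifnot(assembly_fraction > 0, assembly_fraction <= 1)
  n_part <- max(1L, round(assembly_fraction * n_in))
  if (assembly_fraction * n_in < 1) stop("assembly_fraction * n_in < 1")
  n_slots <- floor(duration / pattern_ms)
  duration <- n_slots * pattern_ms
  s <- with_seed(seed, {
    participants <- lapply(seq_len(n_patterns), function(p)
      sort(sample.int(n_in, n_part)))
    k_spk <- max(1L, round(n_part * base_rate * pattern_ms))
    patterns <- lapply(seq_len(n_patterns), function(p)
      data.frame(neuron = participants[[p]][sample.int(n_part, k_spk, replace = TRUE)],
                 offset = stats::runif(k_spk, 0, pattern_ms)))
    slot_lab <- ifelse(stats::runif(n_slots) < occupancy,
                       sample.int(n_patterns, n_slots, replace = TRUE), 0L)
    list(participants = participants, patterns = patterns,
         slot_lab = as.integer(slot_lab))
  })
  labels <- rep(s$slot_lab, each = pattern_ms)[seq_len(duration)]
  fixed <- do.call(rbind, lapply(which(s$slot_lab > 0), function(sl) {
    pat <- s$patterns[[s$slot_lab[sl]]]
    data.frame(neuron = pat$neuron, time = (sl - 1) * pattern_ms + pat$offset)
  }))
  if (is.null(fixed)) fixed <- data.frame(neuron = integer(0), time = numeric(0))
  # participant x slot mask: participants are silent (background off) during
  # their pattern epochs; the frozen events carry their activity there
  part_mask <- matrix(FALSE, n_in, n_patterns)
  for (p in seq_len(n_patterns)) part_mask[s$participants[[p]], p] <- TRUE
  rate_block <- function(t0, t1, dt) {
    nb <- round((t1 - t0) / dt)
    rates <- matrix(base_rate, n_in, nb)
    bin_slot <- pmin(n_slots, floor((t0 + (seq_len(nb) - 1) * dt) / pattern_ms) + 1L)
    lab <- s$slot_lab[bin_slot]
    for (p in seq_len(n_patterns)) {
      cols <- which(lab == p)
      if (length(cols)) rates[part_mask[, p], cols] <- 0
    }
    rates
  }
  stimulus_program(
    n_in, duration, labels,
    label_names = paste0("pattern", seq_len(n_patterns)),
    rate_block = rate_block, fixed_events = fixed,
    meta = list(generator = "frozen_pattern_stream", rate_levels = c(0, base_rate),
                n_patterns = n_patterns,
                pattern_ms = pattern_ms, base_rate = base_rate,
                occupancy = occupancy, assembly_fraction = assembly_fraction,
                participants = s$participants, seed = seed))
}

#' Corrupt a stimulus program
#'
#' Degrades the pattern-specific (frozen) spikes of a program by synaptic
#' transmission failure and timing jitter, and contaminates the stream with
#' extra background spikes.  Corruption is drawn freshly at every
#' realization, emulating trial-to-trial noise:
#' each frozen spike is deleted with probability `failure_prob`, survivors
#' receive Gaussian jitter (s.d. `jitter_sd_ms`, reflected back into the
#' pattern epoch), and independent Poisson background is added uniformly so
#' the expected number of added spikes is `background_ratio` times the
#' number of pattern spikes.
#'
#' @param prog a [stimulus_program()] (typically a frozen-pattern stream).
#' @param background_ratio background-to-target spike count ratio (>= 0).
#' @param failure_prob per-spike deletion probability in `[0, 1]`.
#' @param jitter_sd_ms s.d. of the timing jitter (ms).
#' @return A new [stimulus_program()].
#' @export
corrupt_stream <- function(prog, background_ratio = 0, failure_prob = 0,
                           jitter_sd_ms = 0) {
  stopifnot(failure_prob >= 0, failure_prob <= 1,
            jitter_sd_ms >= 0, background_ratio >= 0)
  base <- prog
  epoch_ms <- base$meta$pattern_ms
  out <- base
  out$meta <- c(base$meta, list(background_ratio = background_ratio,
                                failure_prob = failure_prob,
                                jitter_sd_ms = jitter_sd_ms))
  out$realize <- function(dt) {
    fe <- base$fixed_events
    n_tgt <- nrow(fe)
    if (n_tgt && failure_prob > 0)
      fe <- fe[stats::runif(n_tgt) >= failure_prob, , drop = FALSE]
    if (nrow(fe) && jitter_sd_ms > 0) {
      slot0 <- floor(fe$time / epoch_ms) * epoch_ms
      tj <- fe$time + stats::rnorm(nrow(fe), 0, jitter_sd_ms)
      # reflect into the epoch so jitter cannot move a spike outside it
      rel <- (tj - slot0) %% (2 * epoch_ms)
      rel <- ifelse(rel > epoch_ms, 2 * epoch_ms - rel, rel)
      fe$time <- pmin(slot0 + rel, base$duration - 1e-9)
    }
    tmp <- base
    tmp$fixed_events <- fe
    r <- default_realize(tmp, dt)
    if (background_ratio > 0 && n_tgt) {
      n_bg <- stats::rpois(1, background_ratio * n_tgt)
      if (n_bg > 0) {
        r <- spike_raster(c(r$events$neuron, sample.int(base$n_in, n_bg, replace = TRUE)),
                          c(r$events$time, stats::runif(n_bg, 0, base$duration)),
                          base$n_in, base$duration)
      }
    }
    r
  }
  out
}

# ---------------------------------------------------------------------------
# Character chunks

#' Character-chunk sequence stream
#'
#' A random concatenation of character chunks (equal probabilities),
#' optionally interleaved with distractor strings of random letters (a-z)
#' of length 3-7.  Each input neuron is randomly assigned one preferred
#' character and fires a Poisson burst (`burst_rate`, default 10 Hz) for
#' `char_ms` whenever that character appears; it is silent otherwise.
#'
#' @param chunks character vector of chunk strings (e.g.
#'   `c("abcd", "efgh", "ijkl")`); characters may be shared between chunks.
#' @param n_in input population size.
#' @param duration stream length (ms).
#' @param char_ms presentation time per character (ms).
#' @param burst_rate firing rate during the preferred character (events/ms).
#' @param distractor_prob probability that the next element of the sequence
#'   is a distractor string rather than a chunk.
#' @param seed integer seed freezing preferred characters and the sequence.
#' @return A [stimulus_program()]; labels give the chunk id per ms (0 during
#'   distractors).  `meta$preferred` maps neurons to characters.
#' @export
chunk_char_stream <- function(chunks, n_in, duration = 100000, char_ms = 30,
                              burst_rate = 0.01, distractor_prob = 0,
                              seed = 1) {
  stopifnot(length(chunks) >= 1, all(nchar(chunks) >= 1))
  chunk_chars <- strsplit(chunks, "")
  alphabet <- if (distractor_prob > 0) letters else sort(unique(unlist(chunk_chars)))
  if (!length(alphabet)) stop("empty alphabet")
  n_slots <- floor(duration / char_ms)
  duration <- n_slots * char_ms
  s <- with_seed(seed, {
    preferred <- sample(alphabet, n_in, replace = TRUE)
    seq_chars <- character(0); seq_lab <- integer(0)
    while (length(seq_chars) < n_slots) {
      if (stats::runif(1) < distractor_prob) {
        len <- sample(3:7, 1)
        seq_chars <- c(seq_chars, sample(letters, len, replace = TRUE))
        seq_lab <- c(seq_lab, rep.int(0L, len))
      } else {
        k <- sample.int(length(chunks), 1)
        seq_chars <- c(seq_chars, chunk_chars[[k]])
        seq_lab <- c(seq_lab, rep.int(k, length(chunk_chars[[k]])))
      }
    }
    list(preferred = preferred, seq_chars = seq_chars[seq_len(n_slots)],
         seq_lab = seq_lab[seq_len(n_slots)])
  })
  labels <- rep(s$seq_lab, each = char_ms)[seq_len(duration)]
  pref_idx <- match(s$preferred, letters)
  char_idx <- match(s$seq_chars, letters)
  rate_block <- function(t0, t1, dt) {
    nb <- round((t1 - t0) / dt)
    rates <- matrix(0, n_in, nb)
    bin_slot <- pmin(n_slots, floor((t0 + (seq_len(nb) - 1) * dt) / char_ms) + 1L)
    cur <- char_idx[bin_slot]
    for (ci in unique(cur)) {
      rows <- which(pref_idx == ci)
      if (length(rows)) rates[rows, cur == ci] <- burst_rate
    }
    rates
  }
  stimulus_program(
    n_in, duration, labels, label_names = chunks, rate_block = rate_block,
    meta = list(generator = "chunk_char_stream", rate_levels = c(0, burst_rate),
                chunks = chunks,
                char_ms = char_ms, burst_rate = burst_rate,
                distractor_prob = distractor_prob, preferred = s$preferred,
                sequence = s$seq_chars, seed = seed))
}

# ---------------------------------------------------------------------------
# Community-structured random walk

#' Graph with three 5-node communities, every node of degree 4
#'
#' Each community is a near-clique of five nodes: all pairs are connected
#' except the two boundary nodes, and each boundary node connects to the
#' adjacent community's boundary node, closing a ring of communities.  All
#' nodes have degree 4, so a random walk with uniform transition
#' probabilities moves to each neighbor with probability 1/4 and community
#' membership is not signaled by transition probabilities.
#'
#' @return A list with the 15x15 `adjacency` matrix and the `community`
#'   id (1-3) of each node.
#' @export
community_graph <- function() {
  A <- matrix(0L, 15, 15)
  community <- rep(1:3, each = 5)
  for (cm in 0:2) {
    idx <- cm * 5 + 1:5
    A[idx, idx] <- 1L
    diag(A)[idx] <- 0L
    A[idx[1], idx[5]] <- A[idx[5], idx[1]] <- 0L  # boundary pair not linked
  }
  for (cm in 0:2) {
    b2 <- cm * 5 + 5
    b1 <- (((cm + 1) %% 3) * 5) + 1
    A[b2, b1] <- A[b1, b2] <- 1L
  }
  list(adjacency = A, community = community)
}

#' Random-walk stream on the community graph
#'
#' A random walk with uniform transition probabilities on the
#' [community_graph()]; each visited node is presented as a character-like
#' burst stimulus (as in [chunk_char_stream()]): every input neuron has one
#' preferred node and fires at `burst_rate` for `char_ms` when it is
#' visited.  Labels give the community (temporal cluster) of the current
#' node.
#'
#' @param n_in input population size.
#' @param steps number of walk steps.
#' @param char_ms presentation time per node (ms).
#' @param burst_rate firing rate during the preferred node (events/ms).
#' @param seed integer seed.
#' @return A [stimulus_program()]; `meta$walk` holds the node sequence.
#' @export
community_walk_stream <- function(n_in, steps = 3000, char_ms = 30,
                                  burst_rate = 0.01, seed = 1) {
  g <- community_graph()
  nbrs <- apply(g$adjacency, 1, function(r) which(r == 1L), simplify = FALSE)
  s <- with_seed(seed, {
    walk <- integer(steps)
    walk[1] <- sample.int(15, 1)
    for (k in 2:steps) walk[k] <- sample(nbrs[[walk[k - 1]]], 1)
    preferred <- sample.int(15, n_in, replace = TRUE)
    list(walk = walk, preferred = preferred)
  })
  duration <- steps * char_ms
  labels <- rep(g$community[s$walk], each = char_ms)
  rate_block <- function(t0, t1, dt) {
    nb <- round((t1 - t0) / dt)
    rates <- matrix(0, n_in, nb)
    bin_slot <- pmin(steps, floor((t0 + (seq_len(nb) - 1) * dt) / char_ms) + 1L)
    cur <- s$walk[bin_slot]
    for (nd in unique(cur)) {
      rows <- which(s$preferred == nd)
      if (length(rows)) rates[rows, cur == nd] <- burst_rate
    }
    rates
  }
  stimulus_program(
    n_in, duration, labels, label_names = paste0("community", 1:3),
    rate_block = rate_block,
    meta = list(generator = "community_walk_stream", rate_levels = c(0, burst_rate),
                walk = s$walk,
                preferred = s$preferred, char_ms = char_ms,
                burst_rate = burst_rate, graph = g, seed = seed))
}

# ---------------------------------------------------------------------------
# Oriented bars

#' Oriented-bar mask
#'
#' Binary-ish intensity image (values in `[0, 1]`) of a bar through the
#' image center at the given angle; intensity falls off with the
#' perpendicular distance from the bar axis.
#'
#' @param image_px image side length (pixels).
#' @param angle orientation (radians).
#' @param width bar half-width (pixels).
#' @return An `image_px` x `image_px` matrix.
#' @export
bar_mask <- function(image_px, angle, width = 1) {
  ctr <- (image_px + 1) / 2
  xy <- expand.grid(x = seq_len(image_px) - ctr, y = seq_len(image_px) - ctr)
  d <- abs(-sin(angle) * xy$x + cos(angle) * xy$y)
  matrix(pmax(0, 1 - d / width), image_px, image_px)
}

#' Random sequence of noisy oriented-bar images
#'
#' Images of bars at `n_orientations` evenly spaced angles, each corrupted
#' by additive Gaussian pixel noise (clipped to `[0, 1]`), presented for
#' `present_ms` in random order with blank gaps of `gap_ms`.  Pixel
#' intensities map linearly to input rates in `[0, max_rate]` (one input
#' neuron per pixel).
#'
#' @param image_px image side length; `n_in = image_px^2`.
#' @param n_orientations number of orientation classes.
#' @param noise_level s.d. of the additive pixel noise.
#' @param n_images number of presentations.
#' @param present_ms presentation time (ms).
#' @param gap_ms blank interval between images (ms).
#' @param max_rate rate of a full-intensity pixel (events/ms).
#' @param seed integer seed (freezes order and noise).
#' @return A [stimulus_program()]; labels give the orientation id during
#'   presentations and 0 during gaps.
#' @export
bar_image_stream <- function(image_px = 16, n_orientations = 8,
                             noise_level = 0.1, n_images = 1000,
                             present_ms = 40, gap_ms = 30, max_rate = 0.01,
                             seed = 1) {
  n_in <- image_px^2
  angles <- (seq_len(n_orientations) - 1) * pi / n_orientations
  masks <- vapply(angles, function(a) as.vector(bar_mask(image_px, a)),
                  numeric(n_in))
  s <- with_seed(seed, {
    ori <- sample.int(n_orientations, n_images, replace = TRUE)
    imgs <- masks[, ori, drop = FALSE] +
      matrix(stats::rnorm(n_in * n_images, 0, noise_level), n_in, n_images)
    imgs[imgs < 0] <- 0; imgs[imgs > 1] <- 1
    list(ori = ori, imgs = imgs)
  })
  cycle <- present_ms + gap_ms
  duration <- n_images * cycle
  labels <- rep(as.vector(rbind(matrix(rep(s$ori, each = present_ms), present_ms),
                                matrix(0L, gap_ms, n_images))), 1)
  rate_block <- function(t0, t1, dt) {
    nb <- round((t1 - t0) / dt)
    rates <- matrix(0, n_in, nb)
    tt <- t0 + (seq_len(nb) - 1) * dt
    img_idx <- pmin(n_images, floor(tt / cycle) + 1L)
    in_img <- (tt - (img_idx - 1) * cycle) < present_ms
    for (ii in unique(img_idx[in_img])) {
      cols <- which(img_idx == ii & in_img)
      rates[, cols] <- s$imgs[, ii] * max_rate
    }
    rates
  }
  stimulus_program(
    n_in, duration, labels,
    label_names = sprintf("%.0fdeg", angles * 180 / pi),
    rate_block = rate_block,
    meta = list(generator = "bar_image_stream", image_px = image_px,
                n_orientations = n_orientations, noise_level = noise_level,
                present_ms = present_ms, gap_ms = gap_ms,
                max_rate = max_rate, orientations = s$ori, masks = masks,
                seed = seed))
}

# ---------------------------------------------------------------------------
# Correlated harmonic sources and mixing

#' Synthetic pair of harmonic sources with a shared or independent score
#'
#' Stand-in for two instruments: each source is a sequence of notes with
#' piecewise-constant amplitude envelopes (with brief silences).  In
#' `"dependent"` mode the two sources share note onsets (the same score
#' rhythm) and have correlated note amplitudes, giving envelope correlation
#' around 0.4-0.8; in `"independent"` mode schedules and amplitudes are
#' unrelated (|correlation| below ~0.1).  At sample rates of 4 kHz and
#' above the waveforms carry harmonic carriers (fundamental plus two
#' partials); below that an envelope-only mode is returned, which is what
#' the rate encoder consumes anyway and keeps tests fast.
#'
#' @param duration_s length in seconds.
#' @param sample_rate samples per second (>= 4000 for audio mode; e.g. 100
#'   for envelope mode).
#' @param correlation_mode `"dependent"` or `"independent"`.
#' @param seed integer seed.
#' @return A list with waveforms `x1`, `x2`, envelopes `env1`, `env2`,
#'   `sample_rate` and `mode`.
#' @export
synth_correlated_sources <- function(duration_s = 60, sample_rate = 100,
                                     correlation_mode = c("dependent", "independent"),
                                     seed = 1) {
  correlation_mode <- match.arg(correlation_mode)
  n <- round(duration_s * sample_rate)
  gen_schedule <- function(onsets = NULL) {
    if (is.null(onsets)) {
      t <- 0; onsets <- numeric(0)
      while (t < duration_s) {
        onsets <- c(onsets, t)
        t <- t + stats::runif(1, 0.2, 0.5)
      }
    }
    onsets
  }
  build <- function() {
    if (correlation_mode == "dependent") {
      on1 <- gen_schedule()
      on2 <- on1
      z <- stats::rnorm(length(on1))
      rho <- 0.75
      a1 <- pmax(0, 0.6 + 0.3 * (rho * z + sqrt(1 - rho^2) * stats::rnorm(length(on1))))
      a2 <- pmax(0, 0.6 + 0.3 * (rho * z + sqrt(1 - rho^2) * stats::rnorm(length(on1))))
      sil <- stats::runif(length(on1)) < 0.12   # shared rests in the score
      a1[sil] <- 0; a2[sil] <- 0
      a1[stats::runif(length(on1)) < 0.05] <- 0 # own rests of each part
      a2[stats::runif(length(on1)) < 0.05] <- 0
    } else {
      on1 <- gen_schedule()
      on2 <- gen_schedule()
      a1 <- pmax(0, 0.6 + 0.3 * stats::rnorm(length(on1)))
      a2 <- pmax(0, 0.6 + 0.3 * stats::rnorm(length(on2)))
      a1[stats::runif(length(on1)) < 0.15] <- 0
      a2[stats::runif(length(on2)) < 0.15] <- 0
    }
    tt <- (seq_len(n) - 1) / sample_rate
    env_of <- function(onsets, amps) amps[findInterval(tt, onsets)]
    env1 <- env_of(on1, a1); env2 <- env_of(on2, a2)
    freqs <- 220 * 2^((c(0, 2, 4, 7, 9)) / 12)  # pentatonic fundamentals
    carrier <- function(onsets) {
      f <- sample(freqs, length(onsets), replace = TRUE)
      fi <- f[findInterval(tt, onsets)]
      sin(2 * pi * fi * tt) + 0.5 * sin(4 * pi * fi * tt) +
        0.25 * sin(6 * pi * fi * tt)
    }
    if (sample_rate >= 4000) {
      list(x1 = env1 * carrier(on1), x2 = env2 * carrier(on2),
           env1 = env1, env2 = env2)
    } else {
      # low-rate proxy for incoherent carriers: independent random signs
      # per sample, so mixtures combine like interfering waveforms (their
      # envelopes add sublinearly), not like coherent amplitude sums
      list(x1 = env1 * sample(c(-1, 1), n, replace = TRUE),
           x2 = env2 * sample(c(-1, 1), n, replace = TRUE),
           env1 = env1, env2 = env2)
    }
  }
  out <- with_seed(seed, build())
  c(out, list(sample_rate = sample_rate, mode = correlation_mode))
}

#' Mix two sources linearly
#'
#' Angular mode uses the rotation-like matrix
#' `[[cos(theta), sin(theta)], [sin(theta), cos(theta)]]`, whose cross-talk
#' noise is `tan(theta)`: the mixtures equal the sources at `theta = 0` and
#' coincide with each other at `theta = pi/4`.  With `theta = NULL` the
#' fixed matrix `[[1, 0.5], [0.5, 1]]` is used.
#'
#' @param x1,x2 equal-length source signals.
#' @param theta mixing angle in `[0, pi/4]`, or `NULL` for the fixed preset.
#' @return A list with mixtures `m1`, `m2` and `config` (a `MixingConfig`:
#'   `theta`, `matrix`, `crosstalk`).
#' @export
mix_sources <- function(x1, x2, theta = NULL) {
  if (length(x1) != length(x2)) stop("sources must have equal length")
  if (is.null(theta)) {
    M <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
    cfg <- list(theta = NA_real_, matrix = M, crosstalk = 0.5)
  } else {
    stopifnot(theta >= 0, theta <= pi / 4)
    M <- matrix(c(cos(theta), sin(theta), sin(theta), cos(theta)), 2, 2)
    cfg <- list(theta = theta, matrix = M, crosstalk = tan(theta))
  }
  list(m1 = M[1, 1] * x1 + M[1, 2] * x2,
       m2 = M[2, 1] * x1 + M[2, 2] * x2,
       config = cfg)
}

#' Amplitude envelope of a signal
#'
#' Full-wave rectification followed by a moving average of `smooth_ms`.
#'
#' @param x signal.
#' @param sample_rate samples per second.
#' @param smooth_ms averaging window (ms).
#' @return Nonnegative envelope, same length as `x`.
#' @export
amplitude_envelope <- function(x, sample_rate, smooth_ms = 10) {
  w <- max(1L, round(smooth_ms * sample_rate / 1000))
  if (w == 1L) return(abs(x))
  k <- rep(1 / w, w)
  y <- as.numeric(stats::filter(abs(x), k, sides = 2, circular = FALSE))
  y[is.na(y)] <- abs(x)[is.na(y)]
  y
}

#' Encode mixed signals as Poisson input rates
#'
#' Each input neuron encodes exactly one of the signals: the population is
#' split evenly between them.  The amplitude envelopes are jointly
#' normalized (by their common maximum, so relative amplitudes between the
#' mixtures are preserved) and mapped linearly to rates in
#' `[0, max_rate]` (peak amplitude -> `max_rate`, i.e. 10 Hz by default).
#'
#' @param signals list of equal-length signals (typically the two mixtures).
#' @param n_in input population size (split evenly across signals).
#' @param sample_rate samples per second of the signals.
#' @param max_rate rate of the peak amplitude (events/ms).
#' @param smooth_ms envelope smoothing window (ms).
#' @return A [stimulus_program()]; `meta$split` gives each neuron's signal,
#'   `meta$envelopes` the normalized envelopes.
#' @export
amplitude_to_rate <- function(signals, n_in, sample_rate, max_rate = 0.01,
                              smooth_ms = 10) {
  stopifnot(is.list(signals), length(signals) >= 1)
  len <- unique(vapply(signals, length, integer(1)))
  if (length(len) != 1) stop("signals must have equal length")
  envs <- lapply(signals, amplitude_envelope, sample_rate = sample_rate,
                 smooth_ms = smooth_ms)
  peak <- max(unlist(envs))
  if (!is.finite(peak) || peak <= 0)
    stop("cannot normalize: all signals are identically zero")
  envs <- lapply(envs, function(e) e / peak)
  K <- length(signals)
  split_id <- rep(seq_len(K), each = ceiling(n_in / K))[seq_len(n_in)]
  duration <- floor(len * 1000 / sample_rate)
  rate_block <- function(t0, t1, dt) {
    nb <- round((t1 - t0) / dt)
    tt <- t0 + (seq_len(nb) - 1) * dt
    si <- pmin(len, floor(tt * sample_rate / 1000) + 1L)
    rates <- matrix(0, n_in, nb)
    for (k in seq_len(K))
      rates[split_id == k, ] <- matrix(envs[[k]][si] * max_rate,
                                       sum(split_id == k), nb, byrow = TRUE)
    rates
  }
  stimulus_program(
    n_in, duration, labels = rep(0L, duration), label_names = character(0),
    rate_block = rate_block,
    meta = list(generator = "amplitude_to_rate", split = split_id,
                envelopes = envs, sample_rate = sample_rate,
                max_rate = max_rate, smooth_ms = smooth_ms))
}
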