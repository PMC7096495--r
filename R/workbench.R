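#' Experiment presets
#'
#' Named, self-contained configurations reproducing each studied setting at
#' desk scale: stimulus generator, model constants, learning and plasticity
#' parameters, training duration and the metrics to report.  Population
#' sizes and durations are reduced relative to the original settings so a
#' preset runs in seconds to minutes on one core; the stimulus statistics
#' (pattern lengths, burst rates, chunk structure, mixing) are unchanged.
#' Any field can be overridden through `run_experiment(overrides = ...)`.
#'
#' @param name one of `"fig1_single_neuron"`, `"fig2_assemblies"`,
#'   `"fig3_detection"`, `"fig4_chunks"`, `"fig4_overlap"`,
#'   `"fig5_community"`, `"fig6_orientation"`, `"fig7_bss"`,
#'   `"fig8_crosstalk"`.
#' @return A preset configuration list.
#' @export
experiment_preset <- function(name) {
  presets <- list(
    fig1_single_neuron = function() {
      params <- sim_params(n_in = 500, n_out = 1, phi0 = 0.05, theta0 = 2)
      list(
        stimulus = list(generator = "frozen_pattern_stream",
                        n_patterns = 3, pattern_ms = 50, base_rate = 0.01,
                        occupancy = 0.5, assembly_fraction = 1),
        params = params,
        lp = learning_params(eta = 2e-5, gamma = 0.1),
        sp = stdp_params(Gmax = default_gmax(1)),
        istdp = FALSE,
        train_ms = 200000, eval_ms = 30000, smooth_ms = 10,
        metrics = c("selectivity", "soma_dendrite_cor", "consistency_cost"))
    },
    fig2_assemblies = function() {
      params <- sim_params(n_in = 500, n_out = 10, phi0 = 0.05, theta0 = 1.5)
      list(
        stimulus = list(generator = "frozen_pattern_stream",
                        n_patterns = 3, pattern_ms = 50, base_rate = 0.01,
                        occupancy = 0.5, assembly_fraction = 1),
        params = params,
        lp = learning_params(eta = 2e-5, gamma = 0.1),
        sp = stdp_params(Gmax = default_gmax(10)),
        istdp = TRUE,
        train_ms = 200000, eval_ms = 30000, smooth_ms = 10,
        metrics = c("selectivity", "reference_cor", "g_within_between",
                    "soma_dendrite_cor"))
    },
    fig3_detection = function() {
      params <- sim_params(n_in = 500, n_out = 5, phi0 = 0.05, theta0 = 2)
      list(
        stimulus = list(generator = "frozen_pattern_stream",
                        n_patterns = 1, pattern_ms = 50, base_rate = 0.01,
                        occupancy = 0.2, assembly_fraction = 0.1),
        params = params,
        lp = learning_params(eta = 5e-5, gamma = 0.1),
        sp = stdp_params(Gmax = default_gmax(5)),
        istdp = TRUE,
        train_ms = 300000, eval_ms = 30000, smooth_ms = 10,
        metrics = c("reference_cor"))
    },
    fig4_chunks = function() {
      params <- sim_params(n_in = 1000, n_out = 10, phi0 = 0.05, theta0 = 1)
      list(
        stimulus = list(generator = "chunk_char_stream",
                        chunks = c("abcd", "efgh", "ijkl"), char_ms = 30,
                        burst_rate = 0.01, distractor_prob = 0),
        params = params,
        lp = learning_params(eta = 5e-5, gamma = 0.5),
        sp = stdp_params(Gmax = default_gmax(10)),
        istdp = TRUE,
        train_ms = 200000, eval_ms = 30000, smooth_ms = 30,
        onset_skip_ms = 30,
        metrics = c("selectivity", "pc_var_top3", "reference_cor"))
    },
    fig4_overlap = function() {
      params <- sim_params(n_in = 1000, n_out = 10, tau_syn = 50,
                           phi0 = 0.05, theta0 = 1)
      list(
        stimulus = list(generator = "chunk_char_stream",
                        chunks = c("abcd", "befg", "ehij"), char_ms = 30,
                        burst_rate = 0.01, distractor_prob = 0),
        params = params,
        lp = learning_params(eta = 5e-5, gamma = 0.5),
        sp = stdp_params(Gmax = default_gmax(10)),
        istdp = TRUE,
        train_ms = 200000, eval_ms = 30000, smooth_ms = 30,
        onset_skip_ms = 30,
        metrics = c("selectivity", "reference_cor"))
    },
    fig5_community = function() {
      params <- sim_params(n_in = 500, n_out = 10, tau_syn = 50,
                           phi0 = 0.05, theta0 = 1)
      list(
        stimulus = list(generator = "community_walk_stream",
                        char_ms = 30, burst_rate = 0.01),
        params = params,
        lp = learning_params(eta = 5e-5, gamma = 0.5),
        sp = stdp_params(Gmax = default_gmax(10)),
        istdp = TRUE,
        train_ms = 200000, eval_ms = 30000, smooth_ms = 30,
        onset_skip_ms = 30,
        metrics = c("selectivity", "reference_cor"))
    },
    fig6_orientation = function() {
      params <- sim_params(n_in = 256, n_out = 10, phi0 = 0.05, theta0 = 1)
      list(
        stimulus = list(generator = "bar_image_stream", image_px = 16,
                        n_orientations = 8, noise_level = 0.1,
                        present_ms = 40, gap_ms = 30, max_rate = 0.01),
        params = params,
        lp = learning_params(eta = 5e-5, gamma = 0.5),
        sp = stdp_params(Gmax = default_gmax(10)),
        istdp = TRUE,
        train_ms = 200000, eval_ms = 30000, smooth_ms = 10,
        metrics = c("selectivity"))
    },
    fig7_bss = function() {
      params <- sim_params(n_in = 500, n_out = 10, phi0 = 0.05, theta0 = 1.5)
      list(
        stimulus = list(generator = "mixed_sources", duration_s = 120,
                        sample_rate = 100, correlation_mode = "dependent",
                        theta = NULL, max_rate = 0.01),
        params = params,
        lp = learning_params(eta = 2e-5, gamma = 0.2),
        sp = stdp_params(Gmax = default_gmax(10)),
        istdp = TRUE,
        train_ms = NA, eval_ms = NA, smooth_ms = 100,
        train_passes = 2,
        metrics = c("separation", "negentropy"))
    },
    fig8_crosstalk = function() {
      params <- sim_params(n_in = 500, n_out = 10, phi0 = 0.05, theta0 = 1.5)
      list(
        stimulus = list(generator = "mixed_sources", duration_s = 120,
                        sample_rate = 100, correlation_mode = "dependent",
                        theta = 0.3, max_rate = 0.01),
        params = params,
        lp = learning_params(eta = 2e-5, gamma = 0.2, g_noise = 0.6,
                             noise_enabled = FALSE),
        sp = stdp_params(Gmax = default_gmax(10)),
        istdp = TRUE,
        train_ms = NA, eval_ms = NA, smooth_ms = 100,
        train_passes = 2,
        metrics = c("separation"))
    }
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  cfg <- presets[[name]]()
  cfg$name <- name
  cfg
}

# derive a child seed from a master seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483629 + 1)
}

apply_overrides <- function(cfg, overrides) {
  for (key in names(overrides)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    for (d in seq_along(path)) {
      if (!path[d] %in% names(node))
        stop("unknown config key '", key, "' (no element '",
             paste(path[1:d], collapse = "."), "')")
      if (d < length(path)) node <- node[[path[d]]]
    }
    cfg[[path]] <- overrides[[key]]
  }
  cfg
}

build_program <- function(cfg, seed) {
  st <- cfg$stimulus
  dur <- cfg$train_ms + cfg$eval_ms
  switch(st$generator,
    frozen_pattern_stream = frozen_pattern_stream(
      n_in = cfg$params$n_in, n_patterns = st$n_patterns, duration = dur,
      pattern_ms = st$pattern_ms, base_rate = st$base_rate,
      occupancy = st$occupancy, assembly_fraction = st$assembly_fraction,
      seed = seed),
    chunk_char_stream = chunk_char_stream(
      chunks = st$chunks, n_in = cfg$params$n_in, duration = dur,
      char_ms = st$char_ms, burst_rate = st$burst_rate,
      distractor_prob = st$distractor_prob, seed = seed),
    community_walk_stream = community_walk_stream(
      n_in = cfg$params$n_in, steps = ceiling(dur / st$char_ms),
      char_ms = st$char_ms, burst_rate = st$burst_rate, seed = seed),
    bar_image_stream = bar_image_stream(
      image_px = st$image_px, n_orientations = st$n_orientations,
      noise_level = st$noise_level,
      n_images = ceiling(dur / (st$present_ms + st$gap_ms)),
      present_ms = st$present_ms, gap_ms = st$gap_ms,
      max_rate = st$max_rate, seed = seed),
    mixed_sources = {
      src <- synth_correlated_sources(duration_s = st$duration_s,
                                      sample_rate = st$sample_rate,
                                      correlation_mode = st$correlation_mode,
                                      seed = seed)
      mix <- mix_sources(src$x1, src$x2, theta = st$theta)
      prog <- amplitude_to_rate(list(mix$m1, mix$m2), n_in = cfg$params$n_in,
                                sample_rate = st$sample_rate,
                                max_rate = st$max_rate)
      prog$meta$sources <- rbind(src$env1, src$env2)
      prog$meta$mixing <- mix$config
      prog$meta$correlation_mode <- st$correlation_mode
      prog
    },
    stop("unknown stimulus generator: ", st$generator))
}

#' Run an experiment preset end to end
#'
#' Builds the preset's stimulus program, initializes weights, trains the
#' network, re-runs it with frozen weights on a held-out stimulus segment
#' (or a fresh realization, for source-mixture presets), computes the
#' preset's metrics and optionally writes all artifacts (metrics CSV,
#' learning-curve CSV, input raster, weights, resolved configuration with
#' an md5 provenance hash) into `out_dir`.
#'
#' @param preset preset name (see [experiment_preset()]) or a config list.
#' @param seed master integer seed; all structural, spiking and learning
#'   randomness derives from it.
#' @param out_dir optional output directory.
#' @param overrides named list of config overrides with dot paths, e.g.
#'   `list("lp.eta" = 1e-4, "stimulus.theta" = 0.2)`.  Unknown keys are
#'   rejected.
#' @return A list with `metrics` (tidy data.frame: experiment, seed,
#'   metric, value), `train`, `eval` (raw [run_network()] results),
#'   `program`, `cfg`, and per-preset extras.
#' @export
run_experiment <- function(preset, seed = 1, out_dir = NULL,
                           overrides = list()) {
  cfg <- if (is.character(preset)) experiment_preset(preset) else preset
  cfg <- apply_overrides(cfg, overrides)
  params <- cfg$params
  is_bss <- identical(cfg$stimulus$generator, "mixed_sources")
  if (is_bss) {
    cfg$train_ms <- 0; cfg$eval_ms <- 0  # duration set by the source length
  }
  prog <- build_program(cfg, derive_seed(seed, 1))
  weights <- init_weights(params, cfg$sp, seed = derive_seed(seed, 2))

  if (is_bss) {
    passes <- cfg$train_passes %||% 2
    state <- NULL
    tr <- NULL
    for (p in seq_len(passes)) {
      ras <- realize_spikes(prog, dt = params$dt, seed = derive_seed(seed, 10 + p))
      tr <- run_network(ras, params, weights, cfg$lp, cfg$sp, learn = TRUE,
                        istdp = cfg$istdp, record_every = 2L,
                        seed = derive_seed(seed, 20 + p), state = state)
      weights$w <- tr$w; weights$G <- tr$G
      state <- tr$state
    }
    ev_ras <- realize_spikes(prog, dt = params$dt, seed = derive_seed(seed, 30))
    ev <- run_network(ev_ras, params, weights, cfg$lp, cfg$sp, learn = FALSE,
                      istdp = FALSE, sample_spikes = FALSE, record_every = 2L,
                      seed = derive_seed(seed, 31), state = state)
    lab_ev <- NULL
  } else {
    ras <- realize_spikes(prog, dt = params$dt, seed = derive_seed(seed, 10))
    split_t <- cfg$train_ms
    tr_ras <- window_raster(ras, 0, split_t)
    ev_ras <- window_raster(ras, split_t, prog$duration)
    tr <- run_network(tr_ras, params, weights, cfg$lp, cfg$sp, learn = TRUE,
                      istdp = cfg$istdp, record_every = 2L,
                      seed = derive_seed(seed, 20))
    weights$w <- tr$w; weights$G <- tr$G
    ev <- run_network(ev_ras, params, weights, cfg$lp, cfg$sp, learn = FALSE,
                      istdp = FALSE, sample_spikes = FALSE, record_every = 2L,
                      seed = derive_seed(seed, 21), state = tr$state)
    lab_ev <- labels_at(prog, split_t + ev$rec$time)
  }

  resp <- smooth_trace(ev$rec$phi_som,
                       round(cfg$smooth_ms / (params$dt * 2)))
  skip <- round((cfg$onset_skip_ms %||% 0) / (params$dt * 2))
  extras <- list()
  rows <- list()
  add <- function(metric, value) rows[[length(rows) + 1]] <<-
    data.frame(experiment = cfg$name %||% "custom", seed = seed,
               metric = metric, value = value)

  for (m in cfg$metrics) {
    if (m == "selectivity") {
      asg <- selectivity_assignment(resp, lab_ev, onset_skip = skip)
      extras$assignment <- asg
      add("n_selective", sum(asg != "others"))
      add("n_classes_covered", length(unique(asg[asg != "others"])))
    } else if (m == "soma_dendrite_cor") {
      sdc <- soma_dendrite_correlation(tr$rec$phi_som, tr$rec$phi_dend,
                                       tr$rec$time)
      extras$learning_curve <- sdc
      add("final_soma_dendrite_cor", mean(sdc$cor[, ncol(sdc$cor)], na.rm = TRUE))
    } else if (m == "consistency_cost") {
      n <- ncol(tr$rec$phi_som)
      late <- seq(max(1, n - 999), n)
      add("final_cost", mean(kl_poisson(pmax(tr$rec$phi_som[, late], 1e-12),
                                        pmax(tr$rec$phi_dend[, late], 1e-12))))
    } else if (m == "reference_cor") {
      asg <- extras$assignment %||%
        selectivity_assignment(resp, lab_ev, onset_skip = skip)
      rc <- tryCatch(reference_correlation(resp, lab_ev, asg),
                     error = function(e) NULL)
      if (is.null(rc)) rc <- reference_correlation(resp, lab_ev, NULL)
      extras$reference_cor <- rc
      add("mean_reference_cor", mean(rc$best))
    } else if (m == "g_within_between") {
      asg <- extras$assignment %||%
        selectivity_assignment(resp, lab_ev, onset_skip = skip)
      gw <- g_within_between(weights$G, asg)
      extras$g_within_between <- gw
      add("g_within", gw$within)
      add("g_between", gw$between)
    } else if (m == "pc_var_top3") {
      pv <- pc_variance(resp)
      add("pc_var_top3", sum(pv[1:3]) * 100)
    } else if (m == "separation") {
      srcs <- resample_sources(prog, ev$rec$time)
      asg <- source_assignment(resp, srcs)
      extras$source_assignment <- asg
      sc <- tryCatch({
        dec <- decode_sources(resp, asg,
                              smooth_bins = round(cfg$smooth_ms / (params$dt * 2)))
        separation_score(dec, srcs)
      }, error = function(e) NULL)
      extras$separation <- sc
      if (is.null(sc)) {
        # fewer than two assemblies emerged: the separation failed outright
        add("separation_cor_1", 0)
        add("separation_cor_2", 0)
      } else {
        add("separation_cor_1", sc$cor[1])
        add("separation_cor_2", sc$cor[2])
      }
      mixs <- resample_mixtures(prog, ev$rec$time)
      base <- separation_score(mixs, srcs)
      add("mixture_cor_1", base$cor[1])
      add("mixture_cor_2", base$cor[2])
    } else if (m == "negentropy") {
      srcs <- resample_sources(prog, ev$rec$time)
      add("negentropy_source_1", negentropy(srcs[1, ]))
      add("negentropy_source_2", negentropy(srcs[2, ]))
    } else stop("unknown metric: ", m)
  }
  metrics <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    save_weights(weights, file.path(out_dir, "weights.txt"))
    if (!is.null(extras$learning_curve)) {
      lc <- extras$learning_curve
      utils::write.csv(
        data.frame(time_ms = rep(lc$time, each = nrow(lc$cor)),
                   neuron = rep(seq_len(nrow(lc$cor)), ncol(lc$cor)),
                   soma_dendrite_correlation = as.vector(lc$cor)),
        file.path(out_dir, "learning_curve.csv"), row.names = FALSE)
    }
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(serializable_cfg(cfg, seed), cfg_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    hash <- unname(tools::md5sum(cfg_path))
    writeLines(c(sprintf("config_md5 %s", hash), sprintf("seed %d", seed)),
               file.path(out_dir, "provenance.txt"))
  }
  list(metrics = metrics, train = tr, eval = ev, program = prog, cfg = cfg,
       weights = weights, extras = extras)
}

# restrict a raster to [t0, t1), re-zeroing time
window_raster <- function(raster, t0, t1) {
  keep <- raster$events$time >= t0 & raster$events$time < t1
  spike_raster(raster$events$neuron[keep], raster$events$time[keep] - t0,
               raster$n_neurons, t1 - t0)
}

# mean within- vs between-assembly lateral weight
g_within_between <- function(G, assignment) {
  assignment <- as.character(assignment)
  same <- outer(assignment, assignment, "==")
  diag(same) <- NA
  ok <- assignment != "others"
  same[!ok, ] <- NA; same[, !ok] <- NA
  list(within = mean(G[which(same)], na.rm = TRUE),
       between = mean(G[which(!same)], na.rm = TRUE))
}

resample_sources <- function(prog, times) {
  src <- prog$meta$sources
  sr <- prog$meta$sample_rate
  idx <- pmin(ncol(src), floor(times * sr / 1000) + 1L)
  src[, idx, drop = FALSE]
}

resample_mixtures <- function(prog, times) {
  envs <- prog$meta$envelopes
  sr <- prog$meta$sample_rate
  m <- do.call(rbind, envs)
  idx <- pmin(ncol(m), floor(times * sr / 1000) + 1L)
  m[, idx, drop = FALSE]
}

serializable_cfg <- function(cfg, seed) {
  list(name = cfg$name, seed = seed, stimulus = cfg$stimulus,
       onset_skip_ms = cfg$onset_skip_ms %||% 0,
       params = unclass(cfg$params), lp = unclass(cfg$lp),
       sp = unclass(cfg$sp), istdp = cfg$istdp,
       train_ms = cfg$train_ms, eval_ms = cfg$eval_ms,
       smooth_ms = cfg$smooth_ms, metrics = cfg$metrics)
}
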