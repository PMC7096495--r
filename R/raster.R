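#' Spike raster container
#'
#' The universal event format of the package: a set of timestamped spikes
#' for a population of `n_neurons` neurons observed over `[0, duration)` ms.
#' Events are kept in canonical form, sorted by time (ties by neuron index).
#'
#' @param neuron integer vector of 1-based neuron indices.
#' @param time numeric vector of spike times (ms), same length as `neuron`.
#' @param n_neurons population size.
#' @param duration observation window length (ms).
#' @return An object of class `"spike_raster"`: a list with `events`
#'   (data.frame with columns `neuron`, `time`), `n_neurons`, `duration`.
#' @export
spike_raster <- function(neuron, time, n_neurons, duration) {
  stopifnot(length(neuron) == length(time),
            n_neurons >= 1, duration > 0)
  neuron <- as.integer(neuron)
  if (length(neuron) && (any(neuron < 1L) || any(neuron > n_neurons)))
    stop("neuron index out of range [1, n_neurons]")
  if (length(time) && (any(time < 0) || any(time >= duration)))
    stop("spike time out of range [0, duration)")
  o <- order(time, neuron)
  structure(
    list(events = data.frame(neuron = neuron[o], time = time[o]),
         n_neurons = as.integer(n_neurons), duration = duration),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons, %.6g ms, %d spikes (mean rate %.3g Hz)\n",
              x$n_neurons, x$duration, nrow(x$events),
              1000 * nrow(x$events) / (x$n_neurons * x$duration)))
  invisible(x)
}

#' Generate Poisson spike trains from a rate schedule
#'
#' Bernoulli approximation of an inhomogeneous Poisson process: in every bin
#' of width `dt`, neuron `i` fires with probability `rate[i, bin] * dt`,
#' independently across bins and neurons.
#'
#' @param rates matrix of nonnegative rates (events/ms) with one row per
#'   neuron and one column per time bin of width `dt`.
#' @param dt bin width (ms).
#' @param seed optional integer seed; if supplied, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A [spike_raster()] of duration `ncol(rates) * dt`.  Spikes are
#'   stamped at bin centers.
#' @export
#' @examples
#' r <- poisson_spikes(matrix(0.01, 1, 1000), dt = 1, seed = 1)
poisson_spikes <- function(rates, dt, seed = NULL) {
  stopifnot(is.matrix(rates), dt > 0)
  if (any(rates < 0)) stop("negative rate in schedule")
  if (any(rates * dt > 1)) stop("rate * dt exceeds 1: bin too coarse for the Bernoulli approximation")
  draw <- function() {
    nz <- which(rates > 0)
    hit <- nz[stats::runif(length(nz)) < rates[nz] * dt]
    n <- nrow(rates)
    neuron <- ((hit - 1L) %% n) + 1L
    bin <- ((hit - 1L) %/% n) + 1L
    list(neuron = neuron, time = (bin - 0.5) * dt)
  }
  ev <- if (is.null(seed)) draw() else with_seed(seed, draw())
  spike_raster(ev$neuron, ev$time, nrow(rates), ncol(rates) * dt)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the previous RNG
#' state afterwards, so library code never perturbs the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a spike raster as plain text
#'
#' Two whitespace-delimited columns (`neuron_index time_ms`) preceded by a
#' header line `# n_neurons=<N> duration_ms=<D>`.  [read_raster()] inverts it.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d duration_ms=%.17g",
                     raster$n_neurons, raster$duration), con)
  if (nrow(raster$events))
    writeLines(sprintf("%d %.17g", raster$events$neuron, raster$events$time), con)
  invisible(path)
}

#' Read a spike raster written by [write_raster()]
#'
#' @param path file path.
#' @return A [spike_raster()].
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1],
                    regexec("^# n_neurons=(\\d+) duration_ms=([-0-9.eE+]+)$", lines[1]))[[1]]
  if (length(hdr) != 3) stop("malformed raster header: ", lines[1])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "[[:space:]]+")
    neuron <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    time <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  } else {
    neuron <- integer(0); time <- numeric(0)
  }
  spike_raster(neuron, time, as.integer(hdr[2]), as.numeric(hdr[3]))
}

#' Sample output spike trains from somatic rates
#'
#' Thin wrapper over [poisson_spikes()]: the soma of each output neuron
#' emits a Poisson spike train at its instantaneous firing rate.  These
#' spikes drive inhibitory STDP only; the lateral inhibition term of the
#' somatic dynamics reads the rates directly.
#'
#' @param rates matrix of somatic rates (events/ms), neurons x bins.
#' @inheritParams poisson_spikes
#' @return A [spike_raster()].
#' @export
sample_output_spikes <- function(rates, dt, seed = NULL) {
  poisson_spikes(rates, dt, seed)
}
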