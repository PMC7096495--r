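#' Boxcar-smooth response traces
#'
#' Centered moving average along time of a neurons x time matrix.
#'
#' @param x matrix (neurons x time) or vector.
#' @param window_bins window length in samples (>= 1).
#' @return Smoothed matrix/vector, same shape (edges padded with the raw
#'   values).
#' @export
smooth_trace <- function(x, window_bins) {
  window_bins <- max(1L, as.integer(window_bins))
  if (window_bins == 1L) return(x)
  sm1 <- function(v) {
    y <- as.numeric(stats::filter(v, rep(1 / window_bins, window_bins), sides = 2))
    y[is.na(y)] <- v[is.na(y)]
    y
  }
  if (is.matrix(x)) t(apply(x, 1, sm1)) else sm1(x)
}

#' Sliding-window correlation between somatic and dendritic activity
#'
#' Pearson correlation of the somatic rate `phi_som(u)` and the dendritic
#' prediction `phi_dend(v*)` per neuron, in consecutive windows of
#' `window_ms` — the learning curve of the somato-dendritic consistency
#' check.  Windows in which either trace has zero variance give `NA`.
#'
#' @param phi_s,phi_d rate traces (neurons x time matrices, aligned).
#' @param times sample times (ms) of the columns.
#' @param window_ms window length (ms; 15 s by default).
#' @return A list with `time` (window centers, ms) and `cor` (neurons x
#'   windows matrix).
#' @export
soma_dendrite_correlation <- function(phi_s, phi_d, times,
                                      window_ms = 15000) {
  stopifnot(all(dim(phi_s) == dim(phi_d)), ncol(phi_s) == length(times))
  win <- floor(times / window_ms)
  uw <- sort(unique(win))
  cmat <- matrix(NA_real_, nrow(phi_s), length(uw))
  for (k in seq_along(uw)) {
    idx <- which(win == uw[k])
    if (length(idx) < 3) next
    for (i in seq_len(nrow(phi_s))) {
      a <- phi_s[i, idx]; b <- phi_d[i, idx]
      if (stats::sd(a) > 0 && stats::sd(b) > 0)
        cmat[i, k] <- stats::cor(a, b)
    }
  }
  list(time = (uw + 0.5) * window_ms, cor = cmat)
}

#' Assign each neuron its preferred stimulus class
#'
#' The preferred class of a neuron is the label whose epoch-averaged
#' response has the largest peak: the epochs (runs of the label in time)
#' are aligned at onset and averaged, and the peak of that mean response is
#' taken, so chance excursions outside the preferred stimulus average out.
#' A neuron is classed as `"others"` when the peak response to its
#' second-best label exceeds 50% of the peak response to the best one (no
#' clear single preference), or when it never responds.
#'
#' @param responses neurons x time rate matrix (smooth before calling if
#'   desired).
#' @param labels integer label per time sample (0 = unlabeled).
#' @param label_names optional class names (defaults to `chunk<k>`).
#' @param threshold the "others" criterion ratio (0.5).
#' @param onset_skip samples dropped at each epoch onset before taking the
#'   peak (see [label_psth()]); useful when stimuli abut in time and the
#'   synaptic trace of the previous stimulus bleeds into the epoch.
#' @return A factor of length `n_neurons` with levels
#'   `c(label_names, "others")`; attribute `"peaks"` holds the peak matrix.
#' @export
selectivity_assignment <- function(responses, labels,
                                   label_names = NULL, threshold = 0.5,
                                   onset_skip = 0) {
  stopifnot(ncol(responses) == length(labels))
  classes <- sort(unique(labels[labels > 0]))
  if (length(classes) < 1) stop("no labeled epochs")
  if (is.null(label_names)) label_names <- paste0("chunk", classes)
  peaks <- vapply(classes, function(cl)
    apply(label_psth(responses, labels, cl, skip = onset_skip), 1, max),
    numeric(nrow(responses)))
  peaks <- matrix(peaks, nrow(responses), length(classes))
  out <- character(nrow(responses))
  for (i in seq_len(nrow(responses))) {
    p <- peaks[i, ]
    if (max(p) <= 0) { out[i] <- "others"; next }
    o <- order(p, decreasing = TRUE)
    out[i] <- if (length(p) > 1 && p[o[2]] > threshold * p[o[1]])
      "others" else label_names[o[1]]
  }
  structure(factor(out, levels = c(label_names, "others")),
            peaks = peaks)
}

#' Onset-aligned average response to one label class
#'
#' Collects the runs (epochs) of `class` in the label track, aligns them at
#' onset, truncates to the shortest run and averages across runs: the
#' peristimulus time histogram of each neuron for that stimulus class.
#'
#' @param responses neurons x time rate matrix.
#' @param labels integer label per time sample.
#' @param class the label value to align on.
#' @param skip samples to drop at each epoch onset, e.g. to exclude the
#'   synaptic-trace carryover from the preceding stimulus when stimuli
#'   follow each other back to back.
#' @return Matrix (neurons x epoch samples).
#' @export
label_psth <- function(responses, labels, class, skip = 0) {
  r <- rle(labels == class)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  if (!length(on)) stop("label class absent")
  # alignment length: the shortest *interior* run (runs touching the trace
  # boundaries may be truncated mid-epoch; runs can also be multiples of
  # the epoch when the same stimulus repeats back to back)
  interior <- on[starts[on] > 1 & ends[on] < length(labels)]
  if (length(interior)) on <- interior
  len <- min(r$lengths[on]) - skip
  if (len < 1) stop("'skip' leaves no samples in the epoch")
  acc <- matrix(0, nrow(responses), len)
  for (k in on)
    acc <- acc + responses[, starts[k] + skip + seq_len(len) - 1, drop = FALSE]
  acc / length(on)
}

#' Binary reference response tracks
#'
#' One track per class, taking 1 while that class's stimulus is presented
#' and 0 otherwise.
#'
#' @param labels integer label per time sample.
#' @return Matrix (classes x time) of 0/1 tracks, rownames `ref<k>`.
#' @export
reference_tracks <- function(labels) {
  classes <- sort(unique(labels[labels > 0]))
  refs <- vapply(classes, function(cl) as.numeric(labels == cl),
                 numeric(length(labels)))
  t(matrix(refs, length(labels), length(classes),
           dimnames = list(NULL, paste0("ref", classes))))
}

#' Correlation between assembly responses and reference tracks
#'
#' Computes the mean response of each assembly (group of neurons with the
#' same assignment), correlates it with every class's binary reference
#' track, and reports, per class, the maximally correlated assembly — the
#' matching used to score how faithfully the assemblies track the stimulus.
#'
#' @param responses neurons x time rate matrix.
#' @param labels integer label per time sample.
#' @param assignment factor from [selectivity_assignment()] (or any
#'   grouping); `"others"` neurons are ignored.  `NULL` treats every neuron
#'   as its own assembly.
#' @return A list with the full correlation `matrix` (assemblies x classes)
#'   and `best`, the per-class maximum correlation.
#' @export
reference_correlation <- function(responses, labels, assignment = NULL) {
  refs <- reference_tracks(labels)
  if (is.null(assignment)) {
    amr <- responses
    rownames(amr) <- paste0("neuron", seq_len(nrow(responses)))
  } else {
    keep <- levels(assignment)[levels(assignment) != "others"]
    keep <- keep[keep %in% assignment]
    if (!length(keep)) stop("no non-'others' assemblies to evaluate")
    amr <- t(vapply(keep, function(g)
      colMeans(responses[assignment == g, , drop = FALSE]), numeric(ncol(responses))))
    rownames(amr) <- keep
  }
  cm <- matrix(NA_real_, nrow(amr), nrow(refs),
               dimnames = list(rownames(amr), rownames(refs)))
  for (a in seq_len(nrow(amr))) for (r in seq_len(nrow(refs))) {
    if (stats::sd(amr[a, ]) > 0 && stats::sd(refs[r, ]) > 0)
      cm[a, r] <- stats::cor(amr[a, ], refs[r, ])
  }
  list(matrix = cm, best = apply(cm, 2, max, na.rm = TRUE))
}

#' Cumulative variance captured by leading principal components
#'
#' Eigendecomposition of the covariance of the response traces (samples =
#' time points, variables = neurons).  Returns the sorted fractions of
#' total variance; zero-variance directions contribute zero.
#'
#' @param responses neurons x time rate matrix (>= 3 time samples).
#' @return Vector of variance fractions (non-increasing, summing to 1).
#' @export
pc_variance <- function(responses) {
  if (ncol(responses) < 3) stop("need at least 3 time samples")
  X <- t(responses)
  X <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot <= 0) stop("responses have zero total variance")
  sort(ev / tot, decreasing = TRUE)
}

#' Assign output neurons to sources by response correlation
#'
#' For continuous-source tasks (blind source separation) where discrete
#' labels do not exist: each neuron joins the source whose envelope its
#' response correlates with most; neurons whose best correlation is below
#' `min_cor` are left unassigned (`"others"`).
#'
#' @param responses neurons x time rate matrix.
#' @param sources sources x time matrix of true source envelopes, resampled
#'   to the response time base.
#' @param min_cor minimum correlation for membership.
#' @return A factor with levels `source1..K, others`.
#' @export
source_assignment <- function(responses, sources, min_cor = 0) {
  stopifnot(ncol(responses) == ncol(sources))
  K <- nrow(sources)
  lv <- paste0("source", seq_len(K))
  cm <- matrix(-Inf, nrow(responses), K)
  for (i in seq_len(nrow(responses))) for (k in seq_len(K)) {
    if (stats::sd(responses[i, ]) > 0 && stats::sd(sources[k, ]) > 0)
      cm[i, k] <- stats::cor(responses[i, ], sources[k, ])
  }
  best <- apply(cm, 1, which.max)
  val <- cm[cbind(seq_len(nrow(cm)), best)]
  factor(ifelse(is.finite(val) & val >= min_cor, lv[best], "others"),
         levels = c(lv, "others"))
}

#' Decode source waveforms from assembly activity
#'
#' Averages the firing rates within each assembly, low-pass filters the
#' result (boxcar) and normalizes it to unit peak: the network's estimate
#' of each source envelope.
#'
#' @param responses neurons x time rate matrix.
#' @param assignment factor grouping neurons into assemblies (`"others"`
#'   ignored); at least two non-empty assemblies are required — fewer means
#'   the separation failed.
#' @param smooth_bins boxcar length in samples.
#' @return Matrix (assemblies x time) of decoded, peak-normalized
#'   envelopes.
#' @export
decode_sources <- function(responses, assignment, smooth_bins = 5) {
  keep <- levels(assignment)[levels(assignment) != "others"]
  keep <- keep[keep %in% assignment]
  if (length(keep) < 2)
    stop("separation failed: fewer than 2 assemblies found")
  dec <- t(vapply(keep, function(g) {
    m <- colMeans(responses[assignment == g, , drop = FALSE])
    m <- smooth_trace(m, smooth_bins)
    if (max(m) > 0) m / max(m) else m
  }, numeric(ncol(responses))))
  rownames(dec) <- keep
  dec
}

#' Cross-correlation between decoded and true sources
#'
#' Pearson correlation per source under the best assignment of decoded
#' signals to sources (exhaustive over the two pairings for two sources,
#' all permutations generally), so a label swap does not penalize the
#' score.
#'
#' @param decoded matrix (assemblies/estimates x time).
#' @param true_sources matrix (sources x time), same time base.
#' @param allow_sign_flip if `TRUE`, correlations are taken in absolute
#'   value — appropriate for methods (such as ICA) whose component signs
#'   are unidentifiable.  Decoded firing rates have a definite sign, so the
#'   default is `FALSE`.
#' @return A list with `cor` (per-source correlations under the best
#'   pairing, named by source), `pairing` (decoded row chosen per source)
#'   and `mean` (their mean).
#' @export
separation_score <- function(decoded, true_sources, allow_sign_flip = FALSE) {
  stopifnot(ncol(decoded) == ncol(true_sources))
  K <- nrow(true_sources)
  D <- nrow(decoded)
  cm <- matrix(NA_real_, D, K)
  for (d in seq_len(D)) for (k in seq_len(K)) {
    if (stats::sd(decoded[d, ]) > 0 && stats::sd(true_sources[k, ]) > 0)
      cm[d, k] <- stats::cor(decoded[d, ], true_sources[k, ])
  }
  if (allow_sign_flip) cm <- abs(cm)
  perms <- all_injections(K, D)
  score <- vapply(perms, function(p) sum(cm[cbind(p, seq_len(K))]), numeric(1))
  best <- perms[[which.max(score)]]
  out <- cm[cbind(best, seq_len(K))]
  names(out) <- rownames(true_sources) %||% paste0("source", seq_len(K))
  list(cor = out, pairing = best, mean = mean(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all injective maps sources(1..K) -> decoded rows(1..D), K <= D
all_injections <- function(K, D) {
  if (K > D) stop("need at least as many decoded signals as sources")
  perms <- list(integer(0))
  for (k in seq_len(K)) {
    perms <- unlist(lapply(perms, function(p) {
      lapply(setdiff(seq_len(D), p), function(d) c(p, d))
    }), recursive = FALSE)
  }
  perms
}

#' Log-cosh negentropy approximation
#'
#' `J(Y) = (E[Q(Y)] - E[Q(rho)])^2` with `Q(u) = log(cosh(a*u))/a` and
#' `rho` standard normal; `E[Q(rho)]` is computed once per `a` by adaptive
#' quadrature (0.374567 for `a = 1`).  Zero for Gaussian data, positive
#' otherwise; a proxy for the deviation from Gaussianity used to quantify
#' how (in)dependent signals are.  Samples are standardized to zero mean
#' and unit variance before evaluation.
#'
#' @param samples numeric vector (>= 100 values recommended; fewer warns).
#' @param a contrast parameter in `[1, 2]`.
#' @return Nonnegative scalar.
#' @export
negentropy <- function(samples, a = 1) {
  stopifnot(a >= 1, a <= 2)
  if (length(samples) < 100)
    warning("negentropy estimated from fewer than 100 samples is noisy")
  y <- (samples - mean(samples)) / stats::sd(samples)
  (mean(log_cosh(a * y) / a) - gauss_logcosh_moment(a))^2
}

# numerically stable log(cosh(x))
log_cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

gauss_moment_cache <- new.env(parent = emptyenv())

gauss_logcosh_moment <- function(a) {
  key <- format(a, digits = 15)
  if (!is.null(gauss_moment_cache[[key]])) return(gauss_moment_cache[[key]])
  val <- stats::integrate(function(x) log_cosh(a * x) / a * stats::dnorm(x),
                          -Inf, Inf, rel.tol = 1e-10)$value
  gauss_moment_cache[[key]] <- val
  val
}
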