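#' FastICA baseline separation of two mixtures
#'
#' Comparison baseline for the network model: classical independent
#' component analysis of a two-channel mixture, delegated to
#' scikit-learn's FastICA through the `python` interpreter on the PATH
#' (no R implementation is bundled; ICA is a reference method here, not a
#' contribution).  Signals are exchanged through temporary CSV files.
#'
#' @param m1,m2 equal-length mixture signals.
#' @param seed integer seed passed to FastICA's random state.
#' @return A matrix (2 x length) of estimated source signals, or an error
#'   if no suitable `python` is available.
#' @export
fastica_separate <- function(m1, m2, seed = 0) {
  if (length(m1) != length(m2)) stop("mixtures must have equal length")
  py <- Sys.which("python")
  if (py == "") stop("no 'python' interpreter on the PATH")
  dir <- tempfile("fastica")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fin <- file.path(dir, "in.csv"); fout <- file.path(dir, "out.csv")
  utils::write.table(cbind(m1, m2), fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.decomposition import FastICA\n",
    "X = np.loadtxt(%s, delimiter=',')\n",
    "ica = FastICA(n_components=2, random_state=%d, max_iter=2000)\n",
    "S = ica.fit_transform(X)\n",
    "np.savetxt(%s, S, delimiter=',')\n"),
    deparse(fin), as.integer(seed), deparse(fout))
  status <- system2(py, c("-c", shQuote(script)), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout))
    stop("FastICA subprocess failed (scikit-learn not importable?)")
  S <- as.matrix(utils::read.csv(fout, header = FALSE))
  t(S)
}
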