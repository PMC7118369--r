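# Shared fixture builders. All randomness is seeded by the caller's config.

# a single bright Gaussian blob on a dark-but-positive background
blobImage <- function(n = 48, rowC = NULL, colC = NULL, sigma = 4,
                      amp = 2000, bg = 50) {
  if (is.null(rowC)) rowC <- (n + 1) / 2
  if (is.null(colC)) colC <- (n + 1) / 2
  g <- outer((seq_len(n) - rowC)^2, (seq_len(n) - colC)^2, "+")
  round(bg + amp * exp(-g / (2 * sigma^2)))
}

# seeded strictly-positive texture with spatial autocorrelation (smoothed
# noise), so its correlation-vs-shift surface is unimodal and climbable
textureImage <- function(n = 48, seed = 1, window = 9) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  k <- rep(1 / window, window)
  sm <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, circular = TRUE)))
  round(500 + 3000 * (sm - min(sm)) / diff(range(sm))) + 50
}

# a noiseless static-cells-only config (used by registration tests)
staticConfig <- function(nCells = 6L, drift = list(model = "none"), seed = 1L,
                         noiseSd = 0, ...) {
  simConfig(nStaticCells = nCells, nMigratoryCells = 0L, nClusterEvents = 0L,
            drift = drift, noiseSd = noiseSd, staticJitterFrac = 0,
            seed = seed, ...)
}

# build a straight-line track table: one cell, stepUm per 1-h frame
lineTrack <- function(stepUm, nFrames = 5, diameter = 20, trackId = 1L) {
  data.frame(track_id = trackId, frame = seq_len(nFrames),
             x_um = 50 + stepUm * (seq_len(nFrames) - 1), y_um = 50,
             diameter_um = diameter, lgr5 = FALSE)
}
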