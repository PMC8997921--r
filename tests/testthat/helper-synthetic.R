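# shared fixture builders and independent oracles, all generated in code

# small deterministic spectra set: smooth signals + per-row offsets
toy_spectra <- function(n = 6, p = 40, modality = "raman", seed = 1,
                        replicates = 1) {
  set.seed(seed)
  axis <- seq(500, 500 + p - 1)
  base <- exp(-(axis - 520)^2 / 50)
  X <- t(vapply(seq_len(n * replicates), function(i) {
    (1 + 0.1 * i) * base + 0.01 * i + rnorm(p, 0, 0.001)
  }, numeric(p)))
  if (modality == "nir_reflectance") X <- 10^(-abs(X))
  spectra_set(X, axis, modality,
              sample_ids = rep(sprintf("S%02d", seq_len(n)), each = replicates))
}

# independently coded fold-loop cross-validation oracle: plain loop over
# held-out folds, no shared code path with cross_validate()'s bookkeeping
cv_oracle <- function(X, y, A_max, folds) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, A_max)
  for (f in unique(folds)) {
    tr <- folds != f
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], A_max = A_max)
    preds[!tr, ] <- as.matrix(predict(fit, X[!tr, , drop = FALSE],
                                      ncomp = seq_len(A_max)))
  }
  preds
}

# data with signal confined to a known block of channels
planted_block_data <- function(n = 120, p = 800, block = 3, block_size = 100,
                               seed = 5, noise = 0.05) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, 0, 1), n, p)
  idx <- ((block - 1) * block_size + 1):(block * block_size)
  latent <- rnorm(n)
  shape <- sin(seq(0, pi, length.out = block_size))
  X[, idx] <- X[, idx] * 0.05 + latent %o% shape
  y <- latent + rnorm(n, 0, noise)
  list(X = X, y = y, informative = idx, latent = latent)
}

# small Raman-like study shared by several test files (cached per session)
study_cache <- new.env(parent = emptyenv())
small_raman_study <- function(n = 150, seed = 11) {
  key <- sprintf("raman_%d_%d", n, seed)
  if (is.null(study_cache[[key]])) {
    comps <- draw_compositions(composition_spec(n_samples = n, seed = seed))
    raw <- synthesize_spectra(comps, modality = "raman", baseline_order = 4,
                              seed = seed + 100)
    study_cache[[key]] <- list(comps = comps,
                               spectra = preprocess_raman(raw)$spectra)
  }
  study_cache[[key]]
}
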