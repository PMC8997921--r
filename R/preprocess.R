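#' Transform diffuse reflectance to absorbance
#'
#' Linearizes NIR reflectance spectra elementwise via `A = log10(1/R)`. The
#' modality tag changes from `nir_reflectance` to `nir_absorbance`.
#'
#' @param spectra a `spectra_set` with modality `nir_reflectance` and all
#'   intensities > 0.
#' @return the transformed `spectra_set`.
#' @export
reflectance_to_absorbance <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (spectra$modality != "nir_reflectance")
    stop("reflectance_to_absorbance requires modality 'nir_reflectance', got '",
         spectra$modality, "'")
  bad <- which(apply(spectra$intensities <= 0, 2, any))
  if (length(bad))
    stop("nonpositive reflectance in channels: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ...")
  update_spectra(spectra, intensities = log10(1 / spectra$intensities),
                 modality = "nir_absorbance", step = "log10(1/R)")
}

#' Standard normal variate correction
#'
#' Centers every spectrum to mean zero and scales it to unit standard
#' deviation (the n-1 sample SD), removing additive offsets and
#' multiplicative scatter per spectrum. Idempotent.
#'
#' @param spectra a `spectra_set` with >= 2 channels per spectrum and no
#'   constant spectrum.
#' @return the corrected `spectra_set`.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  X <- spectra$intensities
  if (ncol(X) < 2) stop("SNV requires >= 2 channels")
  s <- apply(X, 1, stats::sd)
  if (any(s == 0))
    stop("constant spectrum (zero SD): sample ",
         paste(spectra$sample_ids[s == 0], collapse = ", "))
  update_spectra(spectra, intensities = (X - rowMeans(X)) / s, step = "snv")
}

#' Trim a spectra set to an axis window
#'
#' Keeps the channels with `low <= axis <= high`, preserving order.
#'
#' @param spectra a `spectra_set`.
#' @param low,high window bounds in axis units, `low <= high`.
#' @return the trimmed `spectra_set`.
#' @export
trim_spectra <- function(spectra, low, high) {
  stopifnot(inherits(spectra, "spectra_set"), low <= high)
  keep <- spectra$axis >= low & spectra$axis <= high
  if (!any(keep))
    stop("trim window [", low, ", ", high, "] does not overlap the axis")
  update_spectra(spectra,
                 intensities = spectra$intensities[, keep, drop = FALSE],
                 axis = spectra$axis[keep],
                 step = sprintf("trim(%g, %g)", low, high))
}

# orthonormal-ish polynomial design on the axis mapped affinely to [-1, 1];
# plain powers are used so the fitted subspace is the textbook one
poly_basis <- function(axis, order) {
  u <- if (length(axis) > 1 && diff(range(axis)) > 0) {
    2 * (axis - min(axis)) / diff(range(axis)) - 1
  } else {
    rep(0, length(axis))
  }
  outer(u, 0:order, `^`)
}

#' Polynomial baseline correction
#'
#' Fits a least-squares polynomial of the given order to the spectrum (on
#' the axis mapped to [-1, 1] for conditioning) and returns the residual.
#'
#' @param spectrum numeric vector.
#' @param axis axis vector, same length.
#' @param order polynomial order >= 0; the spectrum must have more than
#'   `order + 1` channels.
#' @return baseline-corrected vector.
#' @export
polynomial_baseline_correct <- function(spectrum, axis, order = 4) {
  stopifnot(order >= 0, length(spectrum) == length(axis))
  if (length(spectrum) <= order + 1)
    stop("need more than order + 1 channels")
  B <- poly_basis(axis, order)
  drop(spectrum - B %*% qr.coef(qr(B), spectrum))
}

#' Build the EMSC reference spectrum
#'
#' The reference is the grand mean over all replicate spectra in the set,
#' baseline-corrected with a polynomial of the stated order. Using one
#' global reference corrects every spectrum to a common frame.
#'
#' @param spectra a `spectra_set` with >= 2 spectra.
#' @param baseline_order polynomial order of the baseline correction
#'   (default 4).
#' @return numeric reference vector.
#' @export
emsc_fit_reference <- function(spectra, baseline_order = 4) {
  stopifnot(inherits(spectra, "spectra_set"), nrow(spectra$intensities) >= 2)
  polynomial_baseline_correct(colMeans(spectra$intensities), spectra$axis,
                              baseline_order)
}

#' Extended multiplicative signal correction
#'
#' Decomposes every spectrum `z` by least squares as
#' `z = a + b * reference + sum_j d_j p_j + e`, where `p_j` are polynomial
#' terms (orders 1..`polynomial_order`) on the axis mapped to [-1, 1], and
#' returns the corrected spectrum `(z - a - sum_j d_j p_j) / b`. Additive
#' offsets, polynomial baselines up to the stated order, and multiplicative
#' scaling are thereby removed relative to the reference frame.
#'
#' @param spectra a `spectra_set`.
#' @param reference reference vector, e.g. from [emsc_fit_reference()]; must
#'   not be collinear with the polynomial basis.
#' @param polynomial_order order of the polynomial extension (default 6).
#' @return a list with `spectra` (the corrected `spectra_set`) and `model`
#'   (class `emsc_model`: the reference, basis and per-spectrum parameters
#'   `a`, `b`, `d`).
#' @export
emsc_correct <- function(spectra, reference, polynomial_order = 6) {
  stopifnot(inherits(spectra, "spectra_set"),
            length(reference) == length(spectra$axis))
  P <- poly_basis(spectra$axis, polynomial_order)  # column 1 is the constant
  M <- cbind(P[, 1], reference, P[, -1, drop = FALSE])
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop("reference is collinear with the polynomial basis; EMSC is ",
         "unidentifiable (degenerate reference)")
  cf <- unname(qr.coef(qrM, t(spectra$intensities)))  # (order + 2) x n
  b <- cf[2, ]
  if (any(abs(b) < 1e-8))
    stop("EMSC multiplicative coefficient ~ 0 for sample ",
         paste(spectra$sample_ids[abs(b) < 1e-8], collapse = ", "))
  additive <- t(M[, -2, drop = FALSE] %*% cf[-2, , drop = FALSE])
  corrected <- (spectra$intensities - additive) / b
  model <- structure(
    list(reference = reference, polynomial_order = polynomial_order,
         basis = P, a = cf[1, ], b = b,
         d = t(cf[-(1:2), , drop = FALSE])),
    class = "emsc_model")
  list(spectra = update_spectra(spectra, intensities = corrected,
                                step = sprintf("emsc(order=%d)",
                                               polynomial_order)),
       model = model)
}

#' Average replicate spectra per sample
#'
#' Returns one spectrum per `sample_id`, the arithmetic mean of its
#' replicates, in the samples' order of first appearance.
#'
#' @param spectra a `spectra_set`.
#' @return a `spectra_set` with one row per sample.
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  ids <- unique(spectra$sample_ids)
  X <- t(vapply(ids, function(s) {
    colMeans(spectra$intensities[spectra$sample_ids == s, , drop = FALSE])
  }, numeric(ncol(spectra$intensities))))
  update_spectra(spectra, intensities = X, sample_ids = ids,
                 replicate_ids = rep("mean", length(ids)),
                 step = "average_replicates")
}

#' NIR preprocessing chain
#'
#' Reflectance to absorbance (if needed), replicate averaging, SNV, then
#' trim to the analysis window (default 1150-2500 nm). The chain order is
#' fixed and recorded in the provenance.
#'
#' @param spectra a `spectra_set` (modality `nir_reflectance` or
#'   `nir_absorbance`).
#' @param range analysis window in nm.
#' @return preprocessed `spectra_set`, one spectrum per sample.
#' @export
preprocess_nir <- function(spectra, range = c(1150, 2500)) {
  stopifnot(startsWith(spectra$modality, "nir"))
  if (spectra$modality == "nir_reflectance")
    spectra <- reflectance_to_absorbance(spectra)
  spectra <- average_replicates(spectra)
  spectra <- snv(spectra)
  trim_spectra(spectra, range[1], range[2])
}

#' Raman preprocessing chain
#'
#' Trim to the analysis window (default 500-1800 cm^-1), EMSC-correct all
#' replicate spectra against a common reference (the baseline-corrected
#' grand mean spectrum), then average replicates per sample. The chain order
#' is fixed and recorded in the provenance.
#'
#' @param spectra a `spectra_set` with modality `raman`.
#' @param range analysis window in cm^-1.
#' @param emsc_order polynomial order of the EMSC extension (default 6).
#' @param baseline_order baseline order used for the reference spectrum
#'   (default 4).
#' @return a list with `spectra` (preprocessed, one spectrum per sample),
#'   `reference` (the EMSC reference) and `emsc` (the `emsc_model`).
#' @export
preprocess_raman <- function(spectra, range = c(500, 1800), emsc_order = 6,
                             baseline_order = 4) {
  stopifnot(spectra$modality == "raman")
  spectra <- trim_spectra(spectra, range[1], range[2])
  ref <- emsc_fit_reference(spectra, baseline_order)
  fit <- emsc_correct(spectra, ref, emsc_order)
  list(spectra = average_replicates(fit$spectra), reference = ref,
       emsc = fit$model)
}
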