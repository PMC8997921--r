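#' Construct a spectra set
#'
#' A `spectra_set` holds a samples-by-channels intensity matrix together with
#' the spectral axis (Raman shift in cm^-1 or wavelength in nm), a modality
#' tag, and sample/replicate identifiers. It is the common currency of the
#' preprocessing and calibration functions.
#'
#' @param intensities numeric matrix, one row per measured spectrum.
#' @param axis numeric vector of channel positions, strictly increasing, of
#'   length `ncol(intensities)`.
#' @param modality one of `"raman"`, `"nir_reflectance"`, `"nir_absorbance"`.
#' @param sample_ids character or factor, one entry per row; replicate spectra
#'   of the same physical sample share a `sample_id`.
#' @param replicate_ids identifier of the replicate within each sample; by
#'   default replicates are numbered in order of appearance.
#' @param provenance character vector of processing steps already applied;
#'   updated by the preprocessing functions.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(intensities, axis,
                        modality = c("raman", "nir_reflectance", "nir_absorbance"),
                        sample_ids = NULL, replicate_ids = NULL,
                        provenance = character()) {
  modality <- match.arg(modality)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  axis <- as.numeric(axis)
  if (length(axis) != ncol(intensities))
    stop("axis length (", length(axis), ") must equal channel count (",
         ncol(intensities), ")")
  if (length(axis) > 1 && any(diff(axis) <= 0))
    stop("axis must be strictly increasing")
  n <- nrow(intensities)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("sample_ids must have one entry per spectrum")
  if (is.null(replicate_ids)) {
    replicate_ids <- stats::ave(seq_len(n), sample_ids, FUN = seq_along)
  }
  replicate_ids <- as.character(replicate_ids)
  if (length(replicate_ids) != n)
    stop("replicate_ids must have one entry per spectrum")
  structure(
    list(intensities = intensities, axis = axis, modality = modality,
         sample_ids = sample_ids, replicate_ids = replicate_ids,
         provenance = as.character(provenance)),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d channels [%s]\n",
              nrow(x$intensities), length(x$axis), x$modality))
  cat(sprintf("  axis: %g .. %g (%d channels)\n",
              min(x$axis), max(x$axis), length(x$axis)))
  cat(sprintf("  samples: %d unique, replicates per sample: %s\n",
              length(unique(x$sample_ids)),
              paste(range(table(x$sample_ids)), collapse = "-")))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$intensities)

#' Number of spectra in a spectra set
#' @param x a `spectra_set`.
#' @return integer count of rows (replicate spectra).
#' @export
n_spectra <- function(x) nrow(x$intensities)

# internal: clone with new intensity matrix and an appended provenance step
update_spectra <- function(x, intensities = x$intensities, axis = x$axis,
                           modality = x$modality, sample_ids = x$sample_ids,
                           replicate_ids = x$replicate_ids, step = NULL) {
  prov <- x$provenance
  if (!is.null(step)) prov <- c(prov, step)
  spectra_set(intensities, axis, modality, sample_ids, replicate_ids, prov)
}

#' Write a spectra set to CSV
#'
#' The layout is one row per spectrum: `sample_id`, `replicate_id`, then one
#' column per channel named by its axis value. The modality and provenance are
#' stored in a YAML sidecar when `sidecar = TRUE`.
#'
#' @param x a `spectra_set`.
#' @param path output CSV path.
#' @param sidecar write `<path>.yaml` with modality, axis units and provenance.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path, sidecar = TRUE) {
  df <- data.frame(sample_id = x$sample_ids, replicate_id = x$replicate_ids,
                   x$intensities, check.names = FALSE)
  names(df)[-(1:2)] <- format(x$axis, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    yaml::write_yaml(list(modality = x$modality,
                          provenance = as.list(x$provenance)),
                     paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read a spectra set from CSV
#'
#' Inverse of [write_spectra_csv()]. The modality is taken from the YAML
#' sidecar when present, otherwise from the `modality` argument.
#'
#' @param path CSV path written by [write_spectra_csv()].
#' @param modality fallback modality if no sidecar exists.
#' @return a `spectra_set`.
#' @export
read_spectra_csv <- function(path, modality = "raman") {
  df <- utils::read.csv(path, check.names = FALSE)
  prov <- character()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    modality <- meta$modality
    prov <- unlist(meta$provenance)
    if (is.null(prov)) prov <- character()
  }
  axis <- as.numeric(names(df)[-(1:2)])
  spectra_set(as.matrix(df[, -(1:2), drop = FALSE]), axis, modality,
              df$sample_id, df$replicate_id, provenance = prov)
}
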