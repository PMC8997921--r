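#' Reference statistics for salmon-muscle fatty acids
#'
#' Means and standard deviations (percent of total FA) of the 13 fatty acids
#' that each exceed 2% of total FA in homogenized Atlantic salmon muscle, as
#' reported by GC reference analysis of a large single-year-class cohort fed
#' a high fish-oil feed. These are the default marginals of the composition
#' simulator.
#'
#' @return data.frame with columns `name`, `mean`, `sd`.
#' @export
salmon_reference_stats <- function() {
  data.frame(
    name = c("C14-0", "C16-0", "C18-0", "C16-1 (n-7)", "C18-1 (n-9)",
             "C18-1 (n-7)", "C20-1 (n-9)", "C22-1 (n-11)", "C18-2 (n-6)",
             "C18-3 (n-3)", "C20-5 (n-3)", "C22-5 (n-3)", "C22-6 (n-3)"),
    mean = c(3.4, 11.7, 2.7, 4.0, 30.5, 3.0, 3.7, 3.1, 9.6, 3.4, 5.1, 2.3, 6.8),
    sd   = c(0.3, 0.6, 0.2, 0.3, 1.8, 0.3, 0.3, 0.5, 0.7, 0.2, 0.5, 0.2, 0.5),
    stringsAsFactors = FALSE)
}

#' Default correlation matrix for the 13 salmon fatty acids
#'
#' Only a handful of pairwise correlations among salmon-muscle FAs are
#' published (0.95 between C18-1(n-9) and C18-2(n-6), 0.88 between
#' C18-2(n-6) and C18-3(n-3), 0.51 between EPA and DHA, and a strong
#' negative correlation between the long-chain n-3 PUFAs and C18-1(n-9)).
#' This synthetic default embeds those values in a full matrix built from a
#' four-factor latent model (marine-vs-vegetable oil axis, saturates,
#' long-chain monoenes, and an EPA/DHA-specific contrast) with small
#' uniquenesses, so that 5-6 principal components explain most of the
#' reference variance. The cited pairs are then imposed exactly and the
#' matrix repaired to positive semi-definiteness.
#'
#' @return 13 x 13 correlation matrix with FA names as dimnames.
#' @export
salmon_fa_correlation <- function() {
  fa <- salmon_reference_stats()$name
  # loadings: marine-vs-vegetable, saturates, long monoenes, EPA/DHA contrast
  L <- rbind(
    "C14-0"        = c(-0.55, 0.70, 0.00,  0.00),
    "C16-0"        = c(-0.45, 0.75, 0.00,  0.00),
    "C18-0"        = c( 0.05, 0.60, 0.00,  0.00),
    "C16-1 (n-7)"  = c(-0.50, 0.55, 0.20,  0.00),
    "C18-1 (n-9)"  = c( 0.93, 0.00, 0.20,  0.00),
    "C18-1 (n-7)"  = c( 0.40, 0.30, 0.40,  0.00),
    "C20-1 (n-9)"  = c( 0.30, 0.00, 0.80,  0.00),
    "C22-1 (n-11)" = c(-0.10, 0.00, 0.85,  0.00),
    "C18-2 (n-6)"  = c( 0.95, 0.00, 0.10,  0.00),
    "C18-3 (n-3)"  = c( 0.90, 0.00, 0.10,  0.00),
    "C20-5 (n-3)"  = c(-0.75, 0.00, 0.00,  0.45),
    "C22-5 (n-3)"  = c(-0.60, 0.10, 0.10,  0.30),
    "C22-6 (n-3)"  = c(-0.72, 0.00, 0.00, -0.35))
  # rescale every row to communality 0.92 so uniquenesses are uniformly small
  L <- L * sqrt(0.92) / sqrt(rowSums(L^2))
  C <- L %*% t(L)
  diag(C) <- 1
  dimnames(C) <- list(fa, fa)
  # impose the published pairs exactly
  set_pair <- function(C, a, b, r) { C[a, b] <- C[b, a] <- r; C }
  C <- set_pair(C, "C18-1 (n-9)", "C18-2 (n-6)", 0.95)
  C <- set_pair(C, "C18-2 (n-6)", "C18-3 (n-3)", 0.88)
  C <- set_pair(C, "C20-5 (n-3)", "C22-6 (n-3)", 0.51)
  repair_correlation(C)
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Eigenvalues in `[-1e-8, 0)` are treated as numerical noise and clipped to
#' zero; the matrix is rebuilt and its diagonal rescaled to one. An
#' eigenvalue below `-1e-8` indicates a genuinely inconsistent requested
#' structure and raises an error naming it.
#'
#' @param C square symmetric matrix with unit diagonal.
#' @param tol most-negative eigenvalue accepted as numerical noise.
#' @return repaired correlation matrix.
#' @export
repair_correlation <- function(C, tol = 1e-8) {
  if (!isSymmetric(unname(C), tol = 1e-10))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-10))
    stop("correlation matrix must have unit diagonal")
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -tol)
    stop(sprintf(
      "correlation matrix is not repairable to PSD: eigenvalue %.3g < -%g",
      min(e$values), tol))
  if (min(e$values) >= 0) return(C)
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  dimnames(R) <- dimnames(C)
  R
}

#' Specify a composition simulation
#'
#' Bundles the marginal statistics, correlation structure, fat-content
#' distribution and sample size for [draw_compositions()]. Defaults
#' reproduce the salmon-muscle reference statistics
#' ([salmon_reference_stats()], [salmon_fa_correlation()]). Fat content
#' defaults to N(18, 3^2) percent of sample, truncated below at 5% — a
#' typical range for farmed Atlantic salmon NQC muscle.
#'
#' @param fa_names FA labels.
#' @param means,sds marginal mean and SD per FA (% of total FA).
#' @param correlation correlation matrix (symmetric, unit diagonal; repaired
#'   to PSD via [repair_correlation()]).
#' @param fat_mean,fat_sd,fat_min fat-content distribution (% of sample).
#' @param fat_correlation optional named vector of correlations between fat
#'   and individual FAs; default none (fat independent of composition).
#' @param n_samples number of samples to draw.
#' @param seed integer seed recorded with the draw.
#' @return object of class `composition_spec`.
#' @export
composition_spec <- function(fa_names = salmon_reference_stats()$name,
                             means = salmon_reference_stats()$mean,
                             sds = salmon_reference_stats()$sd,
                             correlation = NULL,
                             fat_mean = 18, fat_sd = 3, fat_min = 5,
                             fat_correlation = NULL,
                             n_samples = 100, seed = 1) {
  p <- length(fa_names)
  stopifnot(length(means) == p, length(sds) == p)
  if (any(means <= 0)) stop("means must be > 0")
  if (any(sds < 0)) stop("sds must be >= 0")
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (is.null(correlation)) {
    if (identical(fa_names, salmon_reference_stats()$name)) {
      correlation <- salmon_fa_correlation()
    } else {
      correlation <- diag(p)
      dimnames(correlation) <- list(fa_names, fa_names)
    }
  }
  if (!all(dim(correlation) == c(p, p)))
    stop("correlation must be ", p, " x ", p)
  correlation <- repair_correlation(correlation)
  if (!is.null(fat_correlation)) {
    if (is.null(names(fat_correlation)) ||
        !all(names(fat_correlation) %in% fa_names))
      stop("fat_correlation must be named by FA")
  }
  structure(list(fa_names = fa_names, means = means, sds = sds,
                 correlation = correlation, fat_mean = fat_mean,
                 fat_sd = fat_sd, fat_min = fat_min,
                 fat_correlation = fat_correlation,
                 n_samples = n_samples, seed = seed),
            class = "composition_spec")
}

#' Draw fatty-acid compositions with known ground truth
#'
#' Samples per-sample FA vectors from a truncated multivariate normal
#' (truncation at zero, by rejection) with the requested means, SDs and
#' correlations, and fat contents from a truncated normal. Fat is drawn
#' independently of the FAs unless `fat_correlation` was supplied in the
#' spec, in which case fat is appended to the joint Gaussian.
#'
#' By default the drawn FA vectors are returned as-is, so that the requested
#' correlation structure is recovered empirically (a hard sum constraint
#' would distort it — two FAs forced to a constant sum are perfectly
#' anti-correlated regardless of the request). Supplying `total` rescales
#' every sample so its modeled FAs sum to that constant, for workflows that
#' need compositional closure.
#'
#' @param spec a [composition_spec()].
#' @param total optional constant to which each sample's FA vector is
#'   rescaled (e.g. 100 when the modeled FAs are the complete set); `NULL`
#'   (default) applies no closure.
#' @return a list of class `composition_table` with elements `V` (n x p
#'   matrix, % of total FA), `fat` (% of sample), `sample_ids`, `fa_names`,
#'   `seed`, `spec`.
#' @examples
#' comps <- draw_compositions(composition_spec(n_samples = 20, seed = 7))
#' colMeans(comps$V)
#' @export
draw_compositions <- function(spec, total = NULL) {
  stopifnot(inherits(spec, "composition_spec"))
  set.seed(spec$seed)
  p <- length(spec$fa_names)
  n <- spec$n_samples
  # joint covariance, optionally including fat as an extra coordinate
  if (is.null(spec$fat_correlation)) {
    R <- spec$correlation
    sds <- spec$sds
    mus <- spec$means
    fat_joint <- FALSE
  } else {
    R <- rbind(cbind(spec$correlation, 0), 0)
    R[p + 1, p + 1] <- 1
    r <- rep(0, p)
    r[match(names(spec$fat_correlation), spec$fa_names)] <- spec$fat_correlation
    R[p + 1, 1:p] <- R[1:p, p + 1] <- r
    R <- repair_correlation(R)
    sds <- c(spec$sds, spec$fat_sd)
    mus <- c(spec$means, spec$fat_mean)
    fat_joint <- TRUE
  }
  Sigma <- (sds %o% sds) * R
  draw <- function(m) {
    X <- MASS::mvrnorm(m, mu = mus, Sigma = Sigma)
    if (m == 1) X <- matrix(X, nrow = 1)
    X
  }
  X <- draw(n)
  # rejection step enforces nonnegative FA contents (and fat above fat_min)
  lower <- c(rep(0, p), if (fat_joint) spec$fat_min)
  bad <- which(apply(X, 1, function(z) any(z < lower)))
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    X[bad, ] <- draw(length(bad))
    bad <- bad[apply(X[bad, , drop = FALSE], 1, function(z) any(z < lower))]
    tries <- tries + 1
  }
  if (length(bad) > 0)
    stop("could not draw nonnegative compositions; check means/sds")
  V <- X[, 1:p, drop = FALSE]
  colnames(V) <- spec$fa_names
  if (fat_joint) {
    fat <- X[, p + 1]
  } else {
    fat <- stats::rnorm(n, spec$fat_mean, spec$fat_sd)
    while (any(fat < spec$fat_min))
      fat[fat < spec$fat_min] <- stats::rnorm(sum(fat < spec$fat_min),
                                              spec$fat_mean, spec$fat_sd)
  }
  if (!is.null(total)) {
    stopifnot(is.numeric(total), total > 0)
    V <- V * (total / rowSums(V))
  }
  structure(list(V = V, fat = fat,
                 sample_ids = sprintf("S%03d", seq_len(n)),
                 fa_names = spec$fa_names, seed = spec$seed, spec = spec),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d samples x %d FAs (seed %d)\n",
              nrow(x$V), ncol(x$V), x$seed))
  cat(sprintf("  fat: mean %.1f%% of sample (sd %.1f)\n",
              mean(x$fat), stats::sd(x$fat)))
  print(round(rbind(mean = colMeans(x$V), sd = apply(x$V, 2, stats::sd)), 2))
  invisible(x)
}

#' Define a set of spectral bands
#'
#' @param positions band centers (cm^-1 or nm).
#' @param widths full widths at half maximum, same units; all > 0.
#' @param amplitudes peak intensities (arbitrary units).
#' @param shape band profile, `"gaussian"` or `"lorentzian"`.
#' @return object of class `band_model`.
#' @export
band_model <- function(positions, widths, amplitudes,
                       shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(length(positions) == length(widths),
            length(positions) == length(amplitudes))
  if (any(widths <= 0)) stop("all band widths must be > 0")
  structure(list(positions = positions, widths = widths,
                 amplitudes = amplitudes, shape = shape),
            class = "band_model")
}

#' Evaluate a band model on a spectral axis
#'
#' Sums the band profiles over the axis. Gaussian bands use
#' `a * exp(-4 log(2) (x - pos)^2 / w^2)`, Lorentzian bands
#' `a * (w/2)^2 / ((x - pos)^2 + (w/2)^2)`; both peak at `a`.
#'
#' @param bands a [band_model()].
#' @param axis numeric axis vector.
#' @return nonnegative numeric vector of length `length(axis)`.
#' @export
build_component_spectrum <- function(bands, axis) {
  stopifnot(inherits(bands, "band_model"))
  if (length(bands$positions) == 0) {
    warning("empty band list; returning zero spectrum")
    return(numeric(length(axis)))
  }
  s <- numeric(length(axis))
  for (i in seq_along(bands$positions)) {
    d <- axis - bands$positions[i]
    w <- bands$widths[i]
    s <- s + if (bands$shape == "gaussian") {
      bands$amplitudes[i] * exp(-4 * log(2) * d^2 / w^2)
    } else {
      bands$amplitudes[i] * (w / 2)^2 / (d^2 + (w / 2)^2)
    }
  }
  s
}

#' Default spectral axis per modality
#'
#' Raman: 500-1800 cm^-1 in 1 cm^-1 steps (the analysis range). NIR:
#' 1150-2500 nm in 2 nm steps. Both are coarser than typical instrument
#' steps; band widths are much larger than either step.
#'
#' @param modality `"raman"` or `"nir"` (any `nir_*` tag accepted).
#' @return numeric axis vector.
#' @export
default_axis <- function(modality) {
  if (startsWith(modality, "nir")) seq(1150, 2500, by = 2)
  else seq(500, 1800, by = 1)
}

# C=C stretch position shifts downward with decreasing unsaturation
cc_stretch_position <- function(db) {
  c(`1` = 1655, `2` = 1657, `3` = 1659, `4` = 1662, `5` = 1664,
    `6` = 1667)[as.character(db)]
}

#' Default fatty-acid band library
#'
#' Maps each FA to a [band_model()] tied to its chemistry. Raman-like
#' components use narrow bands (FWHM <= 25 cm^-1): unsaturation bands at
#' 1665 cm^-1 (C=C stretch, position shifting from ~1655 cm^-1 for monoenes
#' up to 1666 cm^-1 for DHA), 1266 cm^-1 (symmetric =C-H rock) and
#' 935 cm^-1 (alkene C-H deformation, relatively stronger for DHA), with
#' amplitudes proportional to the double-bond count; saturation bands at
#' 1440 (CH2 scissoring), 1300 (CH2 twist), 1122 (C-C stretch) and 1066
#' cm^-1 (C-O stretch) with amplitudes proportional to the CH2 proxy
#' (chain length minus twice the double-bond count). NIR-like components
#' use broad bands (FWHM >= 80 nm) at CH overtone/combination positions,
#' with the same chemistry-driven amplitudes.
#'
#' @param defs FA definitions table ([fatty_acid_definitions()]).
#' @param modality `"raman"` or `"nir"`.
#' @return named list of `band_model` objects, one per FA.
#' @export
default_band_library <- function(defs = fatty_acid_definitions(),
                                 modality = "raman") {
  lib <- lapply(seq_len(nrow(defs)), function(i) {
    db <- defs$n_double_bonds[i]
    m <- max(defs$chain_length[i] - 2 * db, 0)  # CH2-group proxy
    if (startsWith(modality, "nir")) {
      # combination/overtone positions drift with chain length and
      # unsaturation, which is what lends NIR its (limited) FA selectivity
      dc <- defs$chain_length[i] - 18
      pos <- c(1210, 1725, 1760, 2310, 2350, 2140) + 0.8 * dc +
        c(0, 0, 0, 1.5, 1.5, 2.5) * db
      wid <- c(110, 90, 90, 80, 85, 95)
      amp <- c(0.010 * m, 0.030 * m, 0.020 * m, 0.050 * m, 0.040 * m,
               0.060 * db)
    } else {
      pos <- c(1440, 1300, 1122, 1066)
      wid <- c(22, 20, 16, 16)
      amp <- c(0.100 * m, 0.060 * m, 0.035 * m, 0.025 * m)
      if (db > 0) {
        boost <- if (db == 6) 1.8 else 1  # DHA's 935 band is relatively stronger
        pos <- c(pos, cc_stretch_position(db), 1266, 935)
        wid <- c(wid, 16, 18, 20)
        amp <- c(amp, 0.50 * db, 0.25 * db, 0.30 * db * boost)
      }
    }
    keep <- amp > 0
    band_model(pos[keep], wid[keep], amp[keep])
  })
  names(lib) <- defs$name
  lib
}

# weak Raman backgrounds; strong broad NIR water/protein terms
default_backgrounds <- function(modality, axis) {
  if (startsWith(modality, "nir")) {
    protein <- build_component_spectrum(
      band_model(c(1510, 2055, 2180), c(100, 100, 90), c(0.20, 0.25, 0.30)),
      axis)
    water <- build_component_spectrum(
      band_model(c(1450, 1940), c(120, 140), c(0.80, 1.20)), axis)
  } else {
    protein <- build_component_spectrum(
      band_model(c(1003, 1250, 1450, 1660), c(10, 50, 30, 40),
                 c(0.020, 0.010, 0.012, 0.016)), axis)
    water <- build_component_spectrum(
      band_model(1640, 100, 0.01), axis)
  }
  list(protein = protein, water = water)
}

#' Synthesize replicate spectra from compositions
#'
#' Builds each replicate spectrum as the fat-weighted mixture of FA
#' component spectra plus matrix backgrounds,
#' `signal = fat/100 * sum_i V_i/100 * component_i +
#'  (protein + water) * (1 - fat/100)`
#' (the lean fraction of muscle — water plus protein — displaces fat, so
#' both background terms scale with it),
#' then applies a random multiplicative scatter factor `1 + N(0, scatter_sd)`,
#' adds a random polynomial baseline of order `baseline_order` (coefficient
#' scale `baseline_amp`), and adds iid Gaussian noise. For
#' `modality = "nir_reflectance"` the signal is treated as absorbance and the
#' returned intensities are `R = 10^(-signal)`, so the log10(1/R) transform
#' is exercised downstream.
#'
#' @param comps a `composition_table` from [draw_compositions()].
#' @param library named list of [band_model()]s, one per FA in `comps`;
#'   default [default_band_library()] for the modality.
#' @param modality `"raman"`, `"nir_absorbance"` or `"nir_reflectance"`.
#' @param axis spectral axis; default [default_axis()].
#' @param noise_sd additive noise SD (intensity units). Defaults are
#'   calibrated so that calibration models on the salmon defaults are good
#'   but imperfect: 0.001 (Raman), 0.0012 (NIR).
#' @param baseline_order order of the random polynomial baseline; `NULL`
#'   (default) disables it. The salmon study conditions
#'   ([salmon_study_config()]) use 4 (Raman) and 2 (NIR).
#' @param baseline_amp coefficient scale of the random baseline.
#' @param scatter_sd SD of the multiplicative scatter factor. Defaults:
#'   0.05 (Raman), 0.10 (NIR; scatter dominates diffuse reflectance).
#' @param backgrounds `"default"` for the modality's protein/water terms,
#'   `"none"` to disable them, or a list with numeric vectors `protein` and
#'   `water` on the axis.
#' @param n_replicates replicate spectra per sample (default 3).
#' @param seed integer seed.
#' @return a [spectra_set()].
#' @export
synthesize_spectra <- function(comps, library = NULL,
                               modality = c("raman", "nir_absorbance",
                                            "nir_reflectance"),
                               axis = NULL, noise_sd = NULL,
                               baseline_order = NULL, baseline_amp = NULL,
                               scatter_sd = NULL, backgrounds = "default",
                               n_replicates = 3, seed = 1) {
  modality <- match.arg(modality)
  stopifnot(inherits(comps, "composition_table"))
  if (any(comps$fat < 0) || any(comps$V < 0))
    stop("negative fat or FA contents")
  nir <- startsWith(modality, "nir")
  if (is.null(axis)) axis <- default_axis(modality)
  if (is.null(library))
    library <- default_band_library(fatty_acid_definitions(comps$fa_names),
                                    modality)
  missing_fa <- setdiff(comps$fa_names, names(library))
  if (length(missing_fa))
    stop("no band model for FA: ", paste(missing_fa, collapse = ", "))
  if (is.null(noise_sd)) noise_sd <- if (nir) 0.0012 else 0.001
  if (is.null(scatter_sd)) scatter_sd <- if (nir) 0.10 else 0.05
  if (is.null(baseline_amp)) baseline_amp <- if (nir) 0.03 else 0.01

  set.seed(seed)
  p <- length(axis)
  comp_mat <- vapply(comps$fa_names,
                     function(f) build_component_spectrum(library[[f]], axis),
                     numeric(p))                       # p x nFA
  bg <- if (identical(backgrounds, "default")) {
    default_backgrounds(modality, axis)
  } else if (is.null(backgrounds) || identical(backgrounds, "none")) {
    list(protein = numeric(p), water = numeric(p))
  } else {
    stopifnot(is.list(backgrounds),
              length(backgrounds$protein) == p, length(backgrounds$water) == p)
    backgrounds
  }
  n <- nrow(comps$V)
  # noiseless per-sample signal: exact linear map of fat x composition
  S <- (comps$V / 100 * comps$fat / 100) %*% t(comp_mat) +
    ((100 - comps$fat) / 100) %o% (bg$protein + bg$water)
  u <- seq(-1, 1, length.out = p)                      # baseline basis axis
  nr <- n_replicates
  X <- matrix(0, n * nr, p)
  for (i in seq_len(n)) {
    for (r in seq_len(nr)) {
      z <- S[i, ] * (1 + stats::rnorm(1, 0, scatter_sd))
      if (!is.null(baseline_order)) {
        cf <- stats::rnorm(baseline_order + 1, 0, baseline_amp)
        z <- z + drop(outer(u, 0:baseline_order, `^`) %*% cf)
      }
      z <- z + stats::rnorm(p, 0, noise_sd)
      X[(i - 1) * nr + r, ] <- z
    }
  }
  if (modality == "nir_reflectance") X <- 10^(-X)
  spectra_set(X, axis, modality,
              sample_ids = rep(comps$sample_ids, each = nr),
              replicate_ids = rep(seq_len(nr), times = n),
              provenance = sprintf("synthesized(%s, seed=%d)", modality, seed))
}
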