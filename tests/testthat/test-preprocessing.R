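test_that("log10(1/R) matches its closed forms and flags bad input", {
  s <- spectra_set(rbind(c(1, 0.1, 0.01)), axis = 1:3,
                   modality = "nir_reflectance")
  a <- reflectance_to_absorbance(s)
  expect_equal(a$intensities[1, ], c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(a$modality, "nir_absorbance")
  bad <- spectra_set(rbind(c(0.5, -0.1, 0.2)), axis = 1:3,
                     modality = "nir_reflectance")
  expect_error(reflectance_to_absorbance(bad), "channels")
  expect_error(reflectance_to_absorbance(toy_spectra()), "modality")
})

test_that("SNV centers, scales, and is idempotent", {
  s <- spectra_set(rbind(c(1, 2, 3), c(10, 20, 60)), axis = 1:3)
  z <- snv(s)
  expect_equal(z$intensities[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(rowMeans(z$intensities), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z$intensities, 1, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(snv(z)$intensities, z$intensities, tolerance = 1e-12)
  const <- spectra_set(rbind(c(2, 2, 2)), axis = 1:3, sample_ids = "flat")
  expect_error(snv(const), "flat")
})

test_that("SNV is invariant to positive scaling of any spectrum", {
  s <- toy_spectra(n = 3, p = 30, seed = 2)
  scaled <- s
  scaled$intensities[2, ] <- 7.3 * scaled$intensities[2, ]
  expect_equal(snv(scaled)$intensities, snv(s)$intensities, tolerance = 1e-8)
})

test_that("trim keeps the requested window and errors when empty", {
  s <- spectra_set(matrix(rnorm(2 * 1591), 2), axis = seq(300, 1890))
  t1 <- trim_spectra(s, 500, 1800)
  expect_equal(range(t1$axis), c(500, 1800))
  expect_equal(trim_spectra(s, 0, 1e5)$intensities, s$intensities)
  expect_equal(length(trim_spectra(s, 1000, 1000)$axis), 1L)
  expect_error(trim_spectra(s, 2000, 3000), "overlap")
  expect_error(trim_spectra(s, 1800, 500))
})

test_that("baseline correction annihilates polynomials and is linear", {
  axis <- seq(500, 1800, by = 2)
  u <- seq(-1, 1, length.out = length(axis))
  poly4 <- 2 - u + 3 * u^2 - 0.5 * u^3 + 4 * u^4
  expect_equal(polynomial_baseline_correct(poly4, axis, 4),
               numeric(length(axis)), tolerance = 1e-8)
  signal <- exp(-(axis - 1000)^2 / 200)
  expect_equal(polynomial_baseline_correct(signal + poly4, axis, 4),
               polynomial_baseline_correct(signal, axis, 4),
               tolerance = 1e-8)
  # order 0 is mean centering
  expect_equal(polynomial_baseline_correct(signal, axis, 0),
               signal - mean(signal), tolerance = 1e-12)
})

test_that("EMSC reference is the baseline-corrected grand mean", {
  s <- toy_spectra(n = 4, p = 50, seed = 3)
  ref <- emsc_fit_reference(s, baseline_order = 4)
  expect_equal(ref, polynomial_baseline_correct(colMeans(s$intensities),
                                                s$axis, 4))
  # invariant to replicate ordering
  perm <- s
  idx <- c(3, 1, 4, 2)
  perm$intensities <- perm$intensities[idx, ]
  perm$sample_ids <- perm$sample_ids[idx]
  expect_equal(emsc_fit_reference(perm), ref)
})

test_that("EMSC is the identity on its own reference and removes
           affine + polynomial distortions", {
  axis <- seq(500, 1800, by = 5)
  ref <- exp(-(axis - 1200)^2 / 5000) + 0.5 * exp(-(axis - 800)^2 / 2000)
  u <- 2 * (axis - min(axis)) / diff(range(axis)) - 1
  distorted <- rbind(ref,
                     3 * ref + 5,
                     ref + 0.8 * u^2 - 0.3 * u,
                     1.7 * ref - 2 + u - 0.5 * u^3 + 0.2 * u^5)
  s <- spectra_set(distorted, axis)
  out <- emsc_correct(s, ref, polynomial_order = 6)
  for (i in 1:4)
    expect_equal(out$spectra$intensities[i, ], ref, tolerance = 1e-8,
                 ignore_attr = TRUE)
  expect_equal(out$model$a[1], 0, tolerance = 1e-8)
  expect_equal(out$model$b[1], 1, tolerance = 1e-8)
  expect_equal(unname(out$model$b[2]), 3, tolerance = 1e-8)
  expect_equal(max(abs(out$model$d[1, ])), 0, tolerance = 1e-8)
})

test_that("EMSC rejects degenerate references and vanishing b", {
  axis <- seq(1, 100)
  u <- 2 * (axis - min(axis)) / diff(range(axis)) - 1
  s <- spectra_set(matrix(rnorm(300), 3), axis)
  expect_error(emsc_correct(s, 1 + u + u^2, polynomial_order = 6),
               "collinear")
  # a spectrum orthogonal to the reference and the polynomial basis has b ~ 0
  ref <- sin(axis / 5)
  M <- cbind(1, ref, poly(u, 6, raw = TRUE))
  set.seed(1)
  z <- rnorm(100)
  z <- z - M %*% qr.coef(qr(M), z)
  orth <- spectra_set(rbind(drop(z)), axis, sample_ids = "odd")
  expect_error(emsc_correct(orth, ref), "odd")
})

test_that("replicate averaging reduces to the mean and commutes with trim", {
  axis <- 1:20
  x <- sin(axis / 3); y <- cos(axis / 4)
  s <- spectra_set(rbind(x, x, x, x, y), axis,
                   sample_ids = c("a", "a", "a", "b", "b"))
  avg <- average_replicates(s)
  expect_equal(n_spectra(avg), 2L)
  expect_equal(avg$intensities[1, ], x, ignore_attr = TRUE)
  expect_equal(avg$intensities[2, ], (x + y) / 2, ignore_attr = TRUE)
  expect_equal(average_replicates(trim_spectra(s, 5, 15))$intensities,
               trim_spectra(avg, 5, 15)$intensities)
})

test_that("preprocessing chains run in the declared order and record it", {
  cc <- draw_compositions(composition_spec(n_samples = 10, seed = 6))
  nir_raw <- synthesize_spectra(cc, modality = "nir_reflectance", seed = 7)
  nir <- preprocess_nir(nir_raw)
  expect_match(paste(nir$provenance, collapse = ";"),
               "log10\\(1/R\\).*average_replicates.*snv.*trim\\(1150, 2500\\)")
  expect_equal(range(nir$axis), c(1150, 2500))
  ram_raw <- synthesize_spectra(cc, modality = "raman", seed = 8)
  ram <- preprocess_raman(ram_raw)
  expect_match(paste(ram$spectra$provenance, collapse = ";"),
               "trim\\(500, 1800\\).*emsc\\(order=6\\).*average_replicates")
  expect_equal(n_spectra(ram$spectra), 10L)
})
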