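test_that("degenerate draw with zero SDs returns the mean vector", {
  spec <- composition_spec(fa_names = c("A", "B"), means = c(30, 10),
                           sds = c(0, 0), correlation = diag(2),
                           n_samples = 5, seed = 3)
  cc <- draw_compositions(spec)
  expect_equal(unname(cc$V), matrix(rep(c(30, 10), each = 5), 5, 2))
})

test_that("salmon-default draw recovers the reference means within 3 SE", {
  stats <- salmon_reference_stats()
  cc <- draw_compositions(composition_spec(n_samples = 618, seed = 123))
  se <- stats$sd / sqrt(618)
  dev <- abs(colMeans(cc$V) - stats$mean)
  expect_true(all(dev <= 3 * se),
              info = paste("worst FA:", stats$name[which.max(dev / se)]))
  # C18-1 (n-9) sits at its reference mean of 30.5
  expect_equal(unname(colMeans(cc$V)["C18-1 (n-9)"]), 30.5,
               tolerance = 3 * se[5] / 30.5)
})

test_that("requested correlations are recovered empirically", {
  # two FAs at correlation 0.95, large n
  R <- matrix(c(1, 0.95, 0.95, 1), 2)
  spec <- composition_spec(fa_names = c("x", "y"), means = c(20, 20),
                           sds = c(2, 2), correlation = R,
                           n_samples = 1e4, seed = 9)
  cc <- draw_compositions(spec)
  expect_equal(cor(cc$V)[1, 2], 0.95, tolerance = 0.02)
  # full salmon structure within +/- 0.03 elementwise
  cc13 <- draw_compositions(composition_spec(n_samples = 1e4, seed = 17))
  expect_lt(max(abs(cor(cc13$V) - salmon_fa_correlation())), 0.03)
})

test_that("closure rescales modeled FAs to a constant sum", {
  cc <- draw_compositions(composition_spec(n_samples = 20, seed = 2),
                          total = 100)
  expect_equal(rowSums(cc$V), rep(100, 20), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical compositions and spectra", {
  spec <- composition_spec(n_samples = 8, seed = 21)
  a <- draw_compositions(spec); b <- draw_compositions(spec)
  expect_identical(a$V, b$V)
  expect_identical(a$fat, b$fat)
  sa <- synthesize_spectra(a, modality = "raman", seed = 5)
  sb <- synthesize_spectra(b, modality = "raman", seed = 5)
  expect_identical(sa$intensities, sb$intensities)
})

test_that("unrepairable correlation matrices error with the eigenvalue", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(repair_correlation(R), "eigenvalue")
  # a singular (perfectly collinear) matrix passes through as valid PSD
  fixed <- repair_correlation(matrix(1, 3, 3))
  expect_equal(diag(fixed), rep(1, 3), ignore_attr = TRUE)
  expect_gte(min(eigen(fixed)$values), -1e-12)
})

test_that("band profiles peak at their position and superpose linearly", {
  axis <- seq(1000, 1200, by = 1)
  one <- band_model(1100, 20, 1)
  expect_equal(max(build_component_spectrum(one, axis)), 1)
  expect_equal(build_component_spectrum(one, axis)[axis == 1100], 1)
  two <- band_model(c(1030, 1170), c(10, 10), c(1, 2))
  s2 <- build_component_spectrum(two, axis)
  s_each <- build_component_spectrum(band_model(1030, 10, 1), axis) +
    build_component_spectrum(band_model(1170, 10, 2), axis)
  expect_equal(s2, s_each)
  # integrals add for non-overlapping bands
  expect_equal(sum(s2), sum(s_each))
  expect_warning(z <- build_component_spectrum(
    band_model(numeric(), numeric(), numeric()), axis), "empty")
  expect_equal(z, numeric(length(axis)))
})

test_that("unsaturation dominates the C=C stretch region", {
  axis <- default_axis("raman")
  lib <- default_band_library()
  epa <- build_component_spectrum(lib[["C20-5 (n-3)"]], axis)
  stearate <- build_component_spectrum(lib[["C18-0"]], axis)
  at1665 <- which(axis == 1665)
  expect_gt(epa[at1665] / max(stearate[at1665], 1e-12), 10)
})

test_that("noiseless spectra are the exact fat-scaled component mixture", {
  spec <- composition_spec(fa_names = "C18-1 (n-9)", means = 100, sds = 0,
                           correlation = diag(1), n_samples = 3, seed = 1,
                           fat_sd = 0)
  cc <- draw_compositions(spec)
  s <- synthesize_spectra(cc, modality = "raman", noise_sd = 0,
                          scatter_sd = 0, backgrounds = "none",
                          n_replicates = 1, seed = 2)
  comp <- build_component_spectrum(
    default_band_library(fatty_acid_definitions("C18-1 (n-9)"))[[1]], s$axis)
  expect_equal(s$intensities[1, ], cc$fat[1] / 100 * comp,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("noiseless signal matrix has rank at most #FAs + #backgrounds", {
  cc <- draw_compositions(composition_spec(n_samples = 40, seed = 4))
  s <- synthesize_spectra(cc, modality = "raman", noise_sd = 0,
                          scatter_sd = 0, n_replicates = 1, seed = 2)
  sv <- svd(s$intensities, nu = 0, nv = 0)$d
  expect_lte(sum(sv > 1e-10 * sv[1]), ncol(cc$V) + 2)
})

test_that("composition CSV round trip is faithful", {
  cc <- draw_compositions(composition_spec(n_samples = 6, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_composition_csv(cc, path)
  r <- read_composition_csv(path)
  expect_equal(r$V, cc$V, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$fat, cc$fat, tolerance = 1e-12)
  expect_equal(r$fa_names, cc$fa_names)
})
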