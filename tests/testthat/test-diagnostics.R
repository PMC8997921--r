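test_that("explained variance saturates at the matrix rank", {
  set.seed(2)
  M <- matrix(rnorm(60 * 3), 60, 3) %*% matrix(rnorm(3 * 20), 3, 20)
  ev <- explained_variance_curves(list(m = M), n_components = 8)
  expect_equal(ev[3, 1], 100, tolerance = 1e-8)
  expect_equal(ev[8, 1], 100)
  expect_true(all(diff(ev[, 1]) >= -1e-10))
})

test_that("isotropic noise spreads variance almost uniformly", {
  set.seed(7)
  M <- matrix(rnorm(80 * 500), 80, 500)
  ev <- explained_variance_curves(list(m = M), n_components = 40)
  # each of the first components carries roughly 1/min(n,p) of the variance
  increments <- diff(c(0, ev[, 1])) / 100
  expect_lt(max(increments), 3 / 79)
})

test_that("NIR-like blocks concentrate variance in fewer components than
           Raman-like blocks", {
  cc <- draw_compositions(composition_spec(n_samples = 120, seed = 19))
  nir <- preprocess_nir(synthesize_spectra(cc, modality = "nir_reflectance",
                                           baseline_order = 2, seed = 20))
  ram <- preprocess_raman(
    synthesize_spectra(cc, modality = "raman", baseline_order = 4,
                       seed = 21))$spectra
  ev <- explained_variance_curves(
    list(nir = nir$intensities, raman = ram$intensities), 13)
  first90 <- apply(ev, 2, function(v) which(v >= 90)[1])
  expect_lt(first90["nir"], ifelse(is.na(first90["raman"]), 14,
                                   first90["raman"]))
})

test_that("correlation matrices handle self, anti and degenerate columns", {
  x <- rnorm(20)
  M <- cbind(a = x, b = -x, c = rnorm(20))
  C <- correlation_matrix(M)
  expect_equal(diag(C), c(a = 1, b = 1, c = 1))
  expect_equal(C["a", "b"], -1)
  Mdeg <- cbind(M, flat = rep(1, 20))
  expect_warning(Cd <- correlation_matrix(Mdeg), "flat")
  expect_true(all(is.na(Cd["flat", c("a", "b", "c")])))
})

test_that("the simulator reproduces the configured EPA-DHA correlation", {
  cc <- draw_compositions(composition_spec(n_samples = 1e4, seed = 43))
  C <- correlation_matrix(cc$V)
  expect_equal(C["C20-5 (n-3)", "C22-6 (n-3)"], 0.51, tolerance = 0.02)
})

test_that("covariance inflation is 1 on identity and reacts as expected", {
  set.seed(3)
  R <- MASS::mvrnorm(60, rep(0, 3),
                     matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3))
  colnames(R) <- c("a", "b", "c")
  expect_equal(as.numeric(covariance_inflation(R, R)), 1.0)
  # predictions collapsed onto one direction: ratio = 1 / mean |ref corr|
  P <- R[, 1] %o% c(1, 2, 3)
  off <- function(M) M[lower.tri(M)]
  expect_equal(as.numeric(covariance_inflation(P, R)),
               1 / mean(abs(off(cor(R)))), tolerance = 1e-10)
  expect_gt(as.numeric(covariance_inflation(P, R)), 1)
  # attenuation: adding independent noise to perfect predictions lowers it
  Pn <- R + matrix(rnorm(180, 0, 1.5), 60, 3)
  expect_lt(as.numeric(covariance_inflation(Pn, R)), 1)
  expect_error(covariance_inflation(R[, 1:2], R), "shape")
})

test_that("coefficient profiles are unit norm and scale-equivariant", {
  s <- small_raman_study()
  y <- s$comps$V[, "C20-5 (n-3)"]
  m1 <- pls_fit(s$spectra$intensities, y, A_max = 5)
  m2 <- pls_fit(s$spectra$intensities, 100 * y, A_max = 5)
  p1 <- coefficient_profile(m1, s$spectra$axis)
  p2 <- coefficient_profile(m2, s$spectra$axis)
  expect_equal(sqrt(sum(p1$coefficient^2)), 1, tolerance = 1e-12)
  expect_equal(p1$coefficient, p2$coefficient, tolerance = 1e-10)
})

test_that("EPA models lean on the C=C stretch region", {
  s <- small_raman_study()
  m <- pls_fit(s$spectra$intensities, s$comps$V[, "C20-5 (n-3)"], A_max = 5)
  pr <- coefficient_profile(m, s$spectra$axis, ncomp = 5)
  c1665 <- pr$coefficient[pr$axis == 1665]
  c1440 <- pr$coefficient[pr$axis == 1440]
  expect_gt(c1665, 0)
  expect_gt(abs(c1665), 3 * abs(c1440))
})

test_that("cage analysis exposes fat-driven absolute models", {
  s <- small_raman_study()
  fa <- c("C18-1 (n-9)", "C20-5 (n-3)")
  cage <- cage_analysis(s$spectra$intensities, s$comps$V[, fa], s$comps$fat,
                        A_max = 12)
  expect_true(all(cage$cor_fat_absolute > 0.5))
  expect_true(all(abs(cage$cor_fat_proportional) < 0.15))
  expect_true(all(cage$r2_prop_times_fat > cage$r2_abs_over_fat))
})

test_that("constant fat makes absolute and proportional routes coincide", {
  set.seed(4)
  cc <- draw_compositions(composition_spec(n_samples = 70, seed = 44,
                                           fat_sd = 0))
  s <- preprocess_raman(synthesize_spectra(cc, modality = "raman",
                                           seed = 45))$spectra
  fa <- "C18-1 (n-9)"
  cage <- cage_analysis(s$intensities, cc$V[, fa, drop = FALSE], cc$fat,
                        A_max = 8)
  # absolute = proportional x constant: identical scores on both routes
  expect_equal(cage$r2_absolute, cage$r2_proportional, tolerance = 1e-8)
  expect_equal(cage$r2_prop_times_fat, cage$r2_absolute, tolerance = 1e-8)
})

test_that("diagnostics reports assemble and serialize", {
  set.seed(6)
  R <- matrix(rnorm(40 * 4), 40, 4)
  colnames(R) <- letters[1:4]
  P <- R + matrix(rnorm(160, 0, 0.1), 40, 4)
  rep <- diagnostics_report(list(refs = R), R, P, n_components = 4)
  expect_s3_class(rep, "diagnostics_report")
  expect_true(is.numeric(rep$covariance_inflation))
  dir <- withr::local_tempdir()
  write_diagnostics(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("explained_variance.csv", "reference_correlation.csv",
      "predicted_correlation.csv", "diagnostics.yaml")))))
})
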