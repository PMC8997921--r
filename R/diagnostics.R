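#' Cumulative explained-variance curves
#'
#' For each data block (e.g. the reference composition table, the NIR
#' spectra, the Raman spectra) the block is column-mean-centered, decomposed
#' by SVD, and the cumulative percentage of variance carried by the leading
#' components is returned. Components beyond the block's rank are padded at
#' 100%. Comparing the curves shows how concentrated each block's variation
#' is: a few strong bulk signals (water, protein, scatter) give a steep
#' curve, well-resolved chemical variation a shallow one.
#'
#' @param blocks named list of numeric matrices (samples x variables).
#' @param n_components number of components to report (default 13).
#' @return matrix `n_components` x `length(blocks)` of cumulative percent
#'   variance, one column per block.
#' @export
explained_variance_curves <- function(blocks, n_components = 13) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop("blocks must be named")
  out <- vapply(blocks, function(M) {
    M <- as.matrix(M)
    M <- sweep(M, 2, colMeans(M))
    d2 <- svd(M, nu = 0, nv = 0)$d^2
    d2 <- d2[d2 > max(d2) * 1e-14]
    cum <- cumsum(d2) / sum(d2) * 100
    if (length(cum) >= n_components) cum[seq_len(n_components)]
    else c(cum, rep(100, n_components - length(cum)))
  }, numeric(n_components))
  rownames(out) <- paste0("PC", seq_len(n_components))
  out
}

#' Pairwise Pearson correlation matrix
#'
#' Correlations are computed pairwise over complete values. Zero-variance
#' columns yield `NA` entries and a warning naming them, rather than a
#' silent zero.
#'
#' @param table numeric matrix or data.frame, samples x variables, >= 3
#'   samples.
#' @return correlation matrix.
#' @export
correlation_matrix <- function(table) {
  M <- as.matrix(table)
  if (nrow(M) < 3) stop("need >= 3 samples")
  sds <- apply(M, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance columns give undefined correlations: ",
            paste(colnames(M)[which(sds == 0)], collapse = ", "))
  suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
}

#' Covariance inflation of predictions relative to references
#'
#' Calibration models inherit the covariance structure of their training
#' references (the "cage of covariance"), and truncated models can
#' exaggerate it. The inflation ratio compares the mean absolute
#' off-diagonal correlation among the predicted analyte columns with the
#' same quantity among the reference columns; 1.08 means the predictions'
#' pairwise couplings are on average 8% stronger than the references'.
#' Correlations (not raw covariances) are used so the ratio is free of scale
#' effects; the raw-covariance variant is returned alongside.
#'
#' @param pred_table predictions, samples x analytes.
#' @param ref_table references, same samples and analytes.
#' @return scalar ratio (correlation-based), with the covariance-based
#'   variant attached as attribute `"covariance_ratio"`.
#' @export
covariance_inflation <- function(pred_table, ref_table) {
  P <- as.matrix(pred_table); R <- as.matrix(ref_table)
  if (!all(dim(P) == dim(R)))
    stop("prediction and reference tables must have identical shape")
  off <- function(M) M[lower.tri(M)]
  ref_cor <- off(stats::cor(R))
  if (any(!is.finite(ref_cor)) || mean(abs(ref_cor)) == 0)
    stop("degenerate reference correlation matrix")
  ratio <- mean(abs(off(stats::cor(P)))) / mean(abs(ref_cor))
  cov_ratio <- mean(abs(off(stats::cov(P)))) / mean(abs(off(stats::cov(R))))
  structure(ratio, covariance_ratio = cov_ratio)
}

#' Normalized regression-coefficient profile
#'
#' The coefficient vector at the chosen component count, divided by its
#' Euclidean norm so profiles from different models are comparable, paired
#' with the axis for plotting and band lookup.
#'
#' @param model a `pls_model`.
#' @param axis channel positions matching the model.
#' @param ncomp component count (default: the model's `A_max`).
#' @return data.frame with columns `axis` and `coefficient` (unit norm).
#' @export
coefficient_profile <- function(model, axis, ncomp = model$A_max) {
  stopifnot(inherits(model, "pls_model"),
            length(axis) == nrow(model$coefficients))
  b <- model$coefficients[, ncomp]
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("zero coefficient vector")
  data.frame(axis = axis, coefficient = b / nb)
}

# R^2 about the reference's own mean, the convention used throughout
r_squared <- function(pred, ref) {
  1 - sum((pred - ref)^2) / sum((ref - mean(ref))^2)
}

#' Absolute-vs-proportional calibration analysis ("cage" table)
#'
#' For every fatty acid, four cross-validated prediction routes are
#' compared: (i) a model trained on absolute contents (% of sample),
#' scored against the absolute reference; (ii) a model trained on
#' proportional contents (% of total FA), scored against the proportional
#' reference; (iii) the absolute model's predictions divided by fat, scored
#' against the proportional reference; (iv) the proportional model's
#' predictions multiplied by fat, scored against the absolute reference.
#' The correlation of each model's predictions with fat content is also
#' reported: an absolute model that mostly tracks fat has a high
#' prediction-fat correlation and collapses on route (iii).
#'
#' @param X preprocessed spectra matrix, samples x channels.
#' @param composition proportional contents matrix (% of total FA), samples
#'   x FAs, with FA column names.
#' @param fat fat content (% of sample), one value per sample.
#' @param k CV folds (default 7).
#' @param A_max maximum PLS components.
#' @param rule component-selection rule for scoring ([select_components()]).
#' @param folds optional explicit fold assignment.
#' @return data.frame, one row per FA: `r2_absolute`, `r2_proportional`,
#'   `r2_abs_over_fat`, `r2_prop_times_fat`, `cor_fat_absolute`,
#'   `cor_fat_proportional`, `ncomp_absolute`, `ncomp_proportional`.
#' @export
cage_analysis <- function(X, composition, fat, k = 7, A_max = 20,
                          rule = "min", folds = NULL) {
  X <- as.matrix(X)
  V <- as.matrix(composition)
  stopifnot(nrow(X) == nrow(V), length(fat) == nrow(X))
  if (is.null(colnames(V))) stop("composition must carry FA names")
  absolute <- to_absolute(V, fat)
  if (is.null(folds)) folds <- venetian_blinds(nrow(X), k)
  rows <- lapply(colnames(V), function(fa) {
    cv_abs <- cross_validate(X, absolute[, fa], A_max = A_max, folds = folds)
    cv_prp <- cross_validate(X, V[, fa], A_max = A_max, folds = folds)
    Aa <- select_components(cv_abs, rule)
    Ap <- select_components(cv_prp, rule)
    pa <- cv_abs$predictions[, Aa]
    pp <- cv_prp$predictions[, Ap]
    data.frame(
      fa = fa,
      r2_absolute = r_squared(pa, absolute[, fa]),
      r2_proportional = r_squared(pp, V[, fa]),
      r2_abs_over_fat = r_squared(pa / fat * 100, V[, fa]),
      r2_prop_times_fat = r_squared(pp * fat / 100, absolute[, fa]),
      cor_fat_absolute = if (stats::sd(fat) == 0) NA_real_ else
        stats::cor(pa, fat),
      cor_fat_proportional = if (stats::sd(fat) == 0) NA_real_ else
        stats::cor(pp, fat),
      ncomp_absolute = Aa, ncomp_proportional = Ap)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a diagnostics report
#'
#' Bundles the interpretive analyses of a calibration study: explained
#' variance per data block, reference and predicted FA correlation matrices,
#' the covariance-inflation ratio, and (optionally) the cage table from
#' [cage_analysis()].
#'
#' @param blocks named list of matrices for [explained_variance_curves()].
#' @param ref_table reference FA table (samples x FAs).
#' @param pred_table matching predicted FA table, or `NULL`.
#' @param cage optional cage table.
#' @param n_components components for the explained-variance curves.
#' @return object of class `diagnostics_report`.
#' @export
diagnostics_report <- function(blocks, ref_table, pred_table = NULL,
                               cage = NULL, n_components = 13) {
  rep <- list(
    explained_variance = explained_variance_curves(blocks, n_components),
    reference_correlation = correlation_matrix(ref_table))
  if (!is.null(pred_table)) {
    rep$predicted_correlation <- correlation_matrix(pred_table)
    infl <- covariance_inflation(pred_table, ref_table)
    rep$covariance_inflation <- as.numeric(infl)
    rep$covariance_inflation_cov <- attr(infl, "covariance_ratio")
  }
  rep$cage <- cage
  structure(rep, class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat("  explained variance (cumulative %):\n")
  print(round(x$explained_variance[seq_len(min(6, nrow(x$explained_variance))), ,
                                   drop = FALSE], 1))
  if (!is.null(x$covariance_inflation))
    cat(sprintf("  covariance inflation: %.3f (correlation-based)\n",
                x$covariance_inflation))
  if (!is.null(x$cage)) {
    cat("  cage table:\n")
    print(cbind(x$cage[1], round(x$cage[-1], 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Write a diagnostics report to disk
#'
#' JSON for the scalar summaries plus CSV matrices alongside.
#'
#' @param report a `diagnostics_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_diagnostics <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$explained_variance,
                   file.path(dir, "explained_variance.csv"))
  utils::write.csv(report$reference_correlation,
                   file.path(dir, "reference_correlation.csv"))
  if (!is.null(report$predicted_correlation))
    utils::write.csv(report$predicted_correlation,
                     file.path(dir, "predicted_correlation.csv"))
  if (!is.null(report$cage))
    utils::write.csv(report$cage, file.path(dir, "cage_table.csv"),
                     row.names = FALSE)
  scalars <- list(covariance_inflation = report$covariance_inflation,
                  covariance_inflation_cov = report$covariance_inflation_cov)
  yaml::write_yaml(scalars[!vapply(scalars, is.null, logical(1))],
                   file.path(dir, "diagnostics.yaml"))
  invisible(dir)
}
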