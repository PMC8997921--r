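#' Fit a single-response PLS regression model
#'
#' NIPALS partial least squares for one response: X is column-centered and y
#' centered, then for each component the weight vector `w = X'y / |X'y|`,
#' scores `t = Xw`, loading `p = X't / t't`, y-loading `q = y't / t't` are
#' extracted and X is deflated by `t p'`. Regression coefficient vectors are
#' accumulated for every component count `1..A_max`, so a single fit serves
#' all model sizes. No scaling of X is applied (spectral channels share
#' units).
#'
#' @param X numeric matrix, samples x channels (n >= 3).
#' @param y numeric response vector with nonzero variance.
#' @param A_max maximum number of components, at most `min(n - 1, ncol(X))`.
#' @return object of class `pls_model` with elements `x_mean`, `y_mean`,
#'   `weights` (p x A), `loadings`, `scores`, `y_loadings`, `coefficients`
#'   (p x A matrix, column a = coefficient vector using a components),
#'   `fitted` (n x A), `A_max`, `selected_channels`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- X %*% c(1, -1, 0.5) + rnorm(20, 0, 0.1)
#' m <- pls_fit(X, y, A_max = 3)
#' @export
pls_fit <- function(X, y, A_max = 10) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need n >= 3 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::var(y) == 0) stop("zero-variance response")
  A_max <- min(A_max, n - 1, p)
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  W <- P <- matrix(0, p, A_max)
  Tm <- matrix(0, n, A_max)
  q <- numeric(A_max)
  Xd <- Xc
  A <- A_max
  for (a in seq_len(A_max)) {
    w <- crossprod(Xd, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      warning("component ", a, " has negligible weight norm; truncating A_max to ",
              a - 1)
      A <- a - 1
      break
    }
    w <- w / wn
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    pp <- crossprod(Xd, tt) / tt2
    q[a] <- sum(yc * tt) / tt2
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt
    Xd <- Xd - tcrossprod(tt, pp)
  }
  if (A == 0) stop("no usable PLS component (X'y is zero)")
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; q <- q[seq_len(A)]
  # R = W (P'W)^-1 maps centered X directly to scores; built recursively
  R <- matrix(0, p, A)
  B <- matrix(0, p, A)
  bcur <- numeric(p)
  for (a in seq_len(A)) {
    r <- W[, a]
    if (a > 1)
      r <- r - R[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(P[, seq_len(a - 1), drop = FALSE], W[, a])
    R[, a] <- r
    bcur <- bcur + r * q[a]
    B[, a] <- bcur
  }
  fitted <- Xc %*% B + y_mean
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
                 scores = Tm, y_loadings = q, rotations = R,
                 coefficients = B, fitted = fitted, A_max = A,
                 selected_channels = seq_len(p)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d channels, %d components\n",
              nrow(x$coefficients), x$A_max))
  invisible(x)
}

#' Predict from a PLS model
#'
#' Applies the coefficient vector at the requested component count to
#' centered new data: `yhat = y_mean + (X - x_mean) B_a`.
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix (or vector) with the model's channels.
#' @param ncomp component count(s); default all `1..A_max`.
#' @param ... unused.
#' @return matrix of predictions, rows = samples, one column per entry of
#'   `ncomp` (dropped to a vector for a single count).
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (is.null(ncomp)) ncomp <- seq_len(object$A_max)
  stopifnot(all(ncomp >= 1), all(ncomp <= object$A_max))
  Xc <- sweep(as.matrix(newdata), 2, object$x_mean)
  out <- Xc %*% object$coefficients[, ncomp, drop = FALSE] + object$y_mean
  colnames(out) <- paste0("A", ncomp)
  if (length(ncomp) == 1) drop(out) else out
}

#' Venetian-blind fold assignment
#'
#' Assigns sample `i` (in dataset order) to fold `((i - 1) mod k) + 1`:
#' every k-th sample lands in the same fold, the interleaved pattern used
#' when sample order is already randomized. An optional seeded shuffle
#' permutes the order first.
#'
#' @param n number of samples (>= k).
#' @param k number of folds (default 7).
#' @param shuffle_seed optional integer; if given, samples are permuted
#'   reproducibly before the interleaved assignment.
#' @return integer vector of fold labels in `1..k`.
#' @export
venetian_blinds <- function(n, k = 7, shuffle_seed = NULL) {
  if (n < k) stop("need n >= k samples for ", k, " folds")
  folds <- ((seq_len(n) - 1) %% k) + 1
  if (!is.null(shuffle_seed)) {
    set.seed(shuffle_seed)
    folds <- folds[order(sample.int(n))]
  }
  folds
}

#' Cross-validate a PLS model
#'
#' Seven-fold venetian-blind cross-validation by default: for each fold the
#' model is fitted on the remaining samples and the held-out samples are
#' predicted at every component count. Reports RMSECV and cross-validated
#' R-squared per component count; the R-squared denominator is the total sum
#' of squares about the global mean of `y`.
#'
#' @param X samples x channels matrix.
#' @param y response vector.
#' @param A_max maximum component count (capped per training split).
#' @param k number of folds (default 7).
#' @param folds optional explicit fold assignment (overrides `k`).
#' @return object of class `cv_result`: `rmsecv` and `r2cv` (length A
#'   vectors), `predictions` (n x A matrix of held-out predictions), `folds`,
#'   `A_max`.
#' @export
cross_validate <- function(X, y, A_max = 10, k = 7, folds = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(folds)) folds <- venetian_blinds(n, k)
  stopifnot(length(folds) == n)
  A_eff <- min(A_max, n - max(table(factor(folds))) - 1, ncol(X))
  if (A_eff < 1) stop("too few samples per fold for any component")
  preds <- matrix(NA_real_, n, A_eff)
  for (j in sort(unique(folds))) {
    hold <- folds == j
    ytr <- y[!hold]
    if (stats::var(ytr) == 0)
      stop("zero-variance response in training split for fold ", j)
    fit <- pls_fit(X[!hold, , drop = FALSE], ytr, A_max = A_eff)
    A_eff <- min(A_eff, fit$A_max)
    ph <- predict(fit, X[hold, , drop = FALSE], ncomp = seq_len(A_eff))
    preds[hold, seq_len(A_eff)] <- as.matrix(ph)
  }
  preds <- preds[, seq_len(A_eff), drop = FALSE]
  res <- preds - y
  rmsecv <- sqrt(colMeans(res^2))
  sstot <- sum((y - mean(y))^2)
  r2cv <- 1 - colSums(res^2) / sstot
  names(rmsecv) <- names(r2cv) <- paste0("A", seq_len(A_eff))
  structure(list(rmsecv = rmsecv, r2cv = r2cv, predictions = preds,
                 folds = folds, A_max = A_eff),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  best <- which.min(x$rmsecv)
  cat(sprintf("<cv_result> %d folds, %d components; best RMSECV %.4g at A=%d (R2cv %.3f)\n",
              length(unique(x$folds)), x$A_max, x$rmsecv[best], best,
              x$r2cv[best]))
  invisible(x)
}

#' Choose the number of PLS components from cross-validation
#'
#' `"min"` picks the global minimum of RMSECV. `"parsimonious"` picks the
#' smallest component count whose RMSECV is within a factor `1 + tol` of the
#' minimum (default tol 0.01), trading a marginal loss of accuracy for a
#' simpler model. Ties go to the smaller count.
#'
#' @param cv a `cv_result`.
#' @param rule `"min"` or `"parsimonious"`.
#' @param tol relative tolerance for the parsimonious rule.
#' @return integer component count.
#' @export
select_components <- function(cv, rule = c("min", "parsimonious"), tol = 0.01) {
  rule <- match.arg(rule)
  stopifnot(inherits(cv, "cv_result"), length(cv$rmsecv) >= 1)
  if (rule == "min") return(unname(which.min(cv$rmsecv)))
  m <- min(cv$rmsecv)
  unname(which(cv$rmsecv <= (1 + tol) * m)[1])
}
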