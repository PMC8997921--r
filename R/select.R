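#' Retrain a model on regions of interest
#'
#' Restricts the predictors to the union of the given axis windows, fits and
#' cross-validates, and keeps the restricted model only if its best RMSECV
#' is strictly lower than the baseline's (ties keep the baseline,
#' full-spectrum model). Typical use: NIR windows known to carry CH
#' overtone/combination signal from fatty acids.
#'
#' @param X samples x channels matrix.
#' @param y response vector.
#' @param axis channel positions (length `ncol(X)`).
#' @param regions list of `c(low, high)` windows in axis units; their union
#'   must be nonempty.
#' @param baseline_cv `cv_result` of the full-spectrum model; computed here
#'   if omitted.
#' @param A_max,k,folds passed to [cross_validate()].
#' @return object of class `selection_result` with the decision
#'   (`"restricted"` or `"baseline"`), the selected channel indices, and both
#'   CV results.
#' @export
region_retrain <- function(X, y, axis, regions, baseline_cv = NULL,
                           A_max = 20, k = 7, folds = NULL) {
  X <- as.matrix(X)
  stopifnot(length(axis) == ncol(X), is.list(regions))
  sel <- sort(unique(unlist(lapply(regions, function(w) {
    which(axis >= w[1] & axis <= w[2])
  }))))
  if (length(sel) == 0) stop("union of regions contains no channels")
  if (is.null(baseline_cv))
    baseline_cv <- cross_validate(X, y, A_max = A_max, k = k, folds = folds)
  restricted_cv <- cross_validate(X[, sel, drop = FALSE], y, A_max = A_max,
                                  k = k, folds = folds)
  keep_restricted <- min(restricted_cv$rmsecv) < min(baseline_cv$rmsecv)
  structure(list(
    method = "region_retrain",
    decision = if (keep_restricted) "restricted" else "baseline",
    selected_channels = if (keep_restricted) sel else seq_len(ncol(X)),
    regions = regions,
    baseline_cv = baseline_cv, restricted_cv = restricted_cv,
    trace = data.frame(
      step = c("baseline", "restricted"),
      rmsecv = c(min(baseline_cv$rmsecv), min(restricted_cv$rmsecv)),
      r2cv = c(max(baseline_cv$r2cv), max(restricted_cv$r2cv)))),
    class = "selection_result")
}

#' Bottom-up forward selection over channel blocks
#'
#' Partitions the channels into consecutive blocks of `block_size` (the last
#' block may be smaller). Round one cross-validates each block alone and
#' keeps the best (lowest minimum RMSECV over component counts). Every later
#' round cross-validates the current selection joined with each remaining
#' block and accepts the best candidate only if it lowers the minimum RMSECV
#' by more than `tol`; otherwise the procedure stops. Component count is
#' re-optimized for every candidate. Ties between candidate blocks go to the
#' lower block index.
#'
#' @param X samples x channels matrix with `ncol(X) >= block_size`.
#' @param y response vector.
#' @param block_size channels per block (default 100).
#' @param k CV folds (default 7).
#' @param A_max maximum PLS components per candidate model.
#' @param tol minimum RMSECV improvement required to accept another block
#'   (default 0 = strict improvement).
#' @param folds optional explicit fold assignment.
#' @return object of class `selection_result`: `blocks` (list of channel
#'   index ranges), `accepted_blocks` (in acceptance order),
#'   `selected_channels`, `trace` (per-round RMSECV/R2cv), `stop_reason`,
#'   and the final `cv` on the selected channels.
#' @export
bottom_up_select <- function(X, y, block_size = 100, k = 7, A_max = 20,
                             tol = 0, folds = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < block_size) stop("need at least block_size channels")
  starts <- seq(1, p, by = block_size)
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1, p))
  nb <- length(blocks)
  if (is.null(folds)) folds <- venetian_blinds(nrow(X), k)

  score <- function(channels) {
    cv <- cross_validate(X[, channels, drop = FALSE], y, A_max = A_max,
                         k = k, folds = folds)
    list(cv = cv, rmsecv = min(cv$rmsecv), r2cv = max(cv$r2cv),
         A = select_components(cv))
  }

  accepted <- integer()
  remaining <- seq_len(nb)
  best_rmsecv <- Inf
  cur_channels <- integer()
  trace <- list()
  cur_cv <- NULL
  stop_reason <- "no remaining blocks"
  round_no <- 0
  while (length(remaining) > 0) {
    round_no <- round_no + 1
    cand <- lapply(remaining, function(b) {
      score(sort(c(cur_channels, blocks[[b]])))
    })
    rms <- vapply(cand, `[[`, numeric(1), "rmsecv")
    best <- which.min(rms)  # which.min takes the first => lower block index
    improves <- if (round_no == 1) TRUE else (best_rmsecv - rms[best]) > tol
    trace[[round_no]] <- data.frame(
      round = round_no, block = remaining[best],
      rmsecv = rms[best], r2cv = cand[[best]]$r2cv,
      n_components = cand[[best]]$A, accepted = improves)
    if (!improves) {
      stop_reason <- sprintf(
        "round %d: best candidate improved RMSECV by %.3g <= tol %.3g",
        round_no, best_rmsecv - rms[best], tol)
      break
    }
    accepted <- c(accepted, remaining[best])
    cur_channels <- sort(c(cur_channels, blocks[[remaining[best]]]))
    best_rmsecv <- rms[best]
    cur_cv <- cand[[best]]$cv
    remaining <- remaining[-best]
  }
  structure(list(
    method = "bottom_up", blocks = blocks, accepted_blocks = accepted,
    selected_channels = cur_channels, trace = do.call(rbind, trace),
    stop_reason = stop_reason, cv = cur_cv, block_size = block_size),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method %s\n", x$method))
  if (x$method == "bottom_up") {
    cat(sprintf("  accepted %d/%d blocks (%d channels); %s\n",
                length(x$accepted_blocks), length(x$blocks),
                length(x$selected_channels), x$stop_reason))
  } else {
    cat(sprintf("  decision: keep %s model\n", x$decision))
  }
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Serialize a selection result to YAML (+ CSV trace)
#'
#' Writes block/region definitions in channel indices and, when an axis is
#' supplied, in axis units; the per-round trace goes to `<path>.trace.csv`.
#'
#' @param x a `selection_result`.
#' @param path YAML output path.
#' @param axis optional axis vector for unit-annotated ranges.
#' @export
write_selection_yaml <- function(x, path, axis = NULL) {
  rng <- range(x$selected_channels)
  out <- list(method = x$method,
              selected_channels = as.list(as.integer(x$selected_channels)))
  if (x$method == "bottom_up") {
    out$accepted_blocks <- lapply(x$accepted_blocks, function(b) {
      ch <- x$blocks[[b]]
      r <- list(block = as.integer(b), first_channel = as.integer(min(ch)),
                last_channel = as.integer(max(ch)))
      if (!is.null(axis)) {
        r$axis_low <- axis[min(ch)]; r$axis_high <- axis[max(ch)]
      }
      r
    })
    out$stop_reason <- x$stop_reason
  } else {
    out$decision <- x$decision
    out$regions <- lapply(x$regions, function(w) list(low = w[1], high = w[2]))
  }
  yaml::write_yaml(out, path)
  if (!is.null(x$trace))
    utils::write.csv(x$trace, paste0(path, ".trace.csv"), row.names = FALSE)
  invisible(path)
}
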