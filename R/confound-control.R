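# OLS of y on [intercept, x]; returns residual (orthogonal to x and the
# intercept) and R^2.
ols_residual <- function(y, x) {
  vx <- stats::var(x)
  if (vx == 0) {
    res <- y - mean(y)
    return(list(residual = res, r2 = 0, coef = 0))
  }
  b <- stats::cov(y, x) / vx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(residual = res, r2 = r2, coef = b)
}

#' Remove the block design from one response series at its best lag
#'
#' Regresses an electrode's HFB series on the block-design indicator shifted
#' over a grid of lags (zero-padded shifts; positive lag = response delayed
#' relative to the stimulus) and keeps the lag with the highest OLS
#' R-squared, ties broken toward the smallest absolute lag. The residual is
#' the OLS residual at that lag and is exactly orthogonal to the lagged
#' regressor.
#'
#' @param hfb_row numeric response series (one electrode).
#' @param block block-design indicator series (same length).
#' @param lag_grid candidate lags in seconds, integer multiples of the frame
#'   period; default -5..5 s at the frame period.
#' @param frame_rate frames per second (default 25).
#' @return list with `lag` (seconds), `lag_frames`, `residual`, `r2`.
#' @export
best_block_lag <- function(hfb_row, block, lag_grid = NULL, frame_rate = 25) {
  stopifnot(length(hfb_row) == length(block))
  if (stats::var(hfb_row) == 0) {
    return(list(lag = 0, lag_frames = 0L, residual = hfb_row - mean(hfb_row), r2 = 0))
  }
  if (is.null(lag_grid)) lag_grid <- seq(-5, 5, by = 1 / frame_rate)
  lag_frames <- vapply(lag_grid, seconds_to_frames, integer(1),
                       frame_rate = frame_rate, what = "lag")
  fits <- lapply(lag_frames, function(k) ols_residual(hfb_row, shift_frames(block, k)))
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  # max R^2; ties toward smallest |lag|
  best <- order(-r2, abs(lag_frames))[1]
  list(lag = lag_frames[best] / frame_rate, lag_frames = lag_frames[best],
       residual = fits[[best]]$residual, r2 = r2[best])
}

#' Remove the audio envelope from one response series at its best lag
#'
#' Finds the lag (within `±max_lag` seconds) maximizing the absolute
#' normalized cross-correlation between the response and the envelope, then
#' regresses the envelope out at that lag by OLS.
#'
#' @param hfb_row numeric response series.
#' @param envelope non-negative envelope series (same length).
#' @param max_lag maximum absolute lag in seconds.
#' @param frame_rate frames per second (default 25).
#' @return list with `lag` (seconds), `lag_frames`, `residual`, `r` (signed
#'   correlation at the selected lag).
#' @export
best_envelope_lag <- function(hfb_row, envelope, max_lag = 5, frame_rate = 25) {
  stopifnot(length(hfb_row) == length(envelope))
  if (stats::var(envelope) == 0) stop("zero-variance envelope", call. = FALSE)
  if (max_lag >= length(hfb_row) / frame_rate / 4) {
    stop("`max_lag` must be below a quarter of the recording duration", call. = FALSE)
  }
  if (stats::var(hfb_row) == 0) {
    return(list(lag = 0, lag_frames = 0L, residual = hfb_row - mean(hfb_row), r = 0))
  }
  kmax <- as.integer(round(max_lag * frame_rate))
  lags <- seq.int(-kmax, kmax)
  r <- vapply(lags, function(k) {
    stats::cor(hfb_row, shift_frames(envelope, k))
  }, numeric(1))
  best <- order(-abs(r), abs(lags))[1]
  fit <- ols_residual(hfb_row, shift_frames(envelope, lags[best]))
  list(lag = lags[best] / frame_rate, lag_frames = lags[best],
       residual = fit$residual, r = r[best])
}

#' Residualize stimulus features on the confounds at lag zero
#'
#' Replaces each feature column by its OLS residual on
#' `[intercept, block, envelope]` (no lag: the confounds are stimulus-locked
#' on the stimulus side). Residual columns are orthogonal to both confounds.
#'
#' @param features frames x K numeric matrix (e.g. component scores).
#' @param confounds a `stimulus_confounds` tibble aligned on frames.
#' @return matrix of the same shape.
#' @export
residualize_features <- function(features, confounds) {
  features <- as.matrix(features)
  if (nrow(features) != nrow(confounds)) {
    stop("features and confounds have different lengths", call. = FALSE)
  }
  X <- cbind(1, confounds$block, confounds$envelope)
  qr.resid(qr(X), features)
}

#' Remove block and envelope confounds from every electrode
#'
#' Applies [best_block_lag()] then [best_envelope_lag()] sequentially to each
#' electrode of a recording (per-electrode optimal lags, determined
#' independently for the two confounds).
#'
#' @param recording a `neural_recording`.
#' @param confounds a `stimulus_confounds` aligned on frames.
#' @param lag_grid,max_lag passed to the per-electrode steps.
#' @return list with `recording` (residualized copy) and `lags` (tibble
#'   `electrode`, `block_lag`, `block_r2`, `envelope_lag`, `envelope_r`).
#' @export
residualize_recording <- function(recording, confounds, lag_grid = NULL,
                                  max_lag = 5) {
  stopifnot(inherits(recording, "neural_recording"))
  fr <- recording$frame_rate
  E <- nrow(recording$hfb)
  n <- ncol(recording$hfb)
  if (is.null(lag_grid)) lag_grid <- seq(-5, 5, by = 1 / fr)
  blk_lags <- vapply(lag_grid, seconds_to_frames, integer(1),
                     frame_rate = fr, what = "lag")
  env_lags <- seq.int(-round(max_lag * fr), round(max_lag * fr))

  # all-lags correlation of every electrode with the lagged confound,
  # computed in one crossproduct per stage
  lag_cor <- function(Ymat, x, lags) {
    L <- vapply(lags, function(k) shift_frames(x, k), numeric(n))
    Lc <- sweep(L, 2, colMeans(L))
    nl <- sqrt(colSums(Lc^2))
    Yc <- sweep(Ymat, 2, colMeans(Ymat))
    ny <- sqrt(colSums(Yc^2))
    r <- crossprod(Lc, Yc) / outer(nl, ny)
    r[, ny == 0] <- 0
    r[nl == 0, ] <- 0
    r
  }

  Y <- t(recording$hfb)
  rb <- lag_cor(Y, confounds$block, blk_lags)       # lags x E
  best_b <- apply(rb^2, 2, function(z) order(-z, abs(blk_lags))[1])
  out <- recording
  rows <- vector("list", E)
  for (e in seq_len(E)) {
    if (stats::var(Y[, e]) == 0) {
      fitb <- list(residual = Y[, e] - mean(Y[, e]), r2 = 0)
      blag <- 0L
    } else {
      blag <- blk_lags[best_b[e]]
      fitb <- ols_residual(Y[, e], shift_frames(confounds$block, blag))
    }
    Y[, e] <- fitb$residual
    rows[[e]] <- tibble::tibble(electrode = e, block_lag = blag / fr,
                                block_r2 = fitb$r2)
  }
  re <- lag_cor(Y, confounds$envelope, env_lags)
  best_e <- apply(abs(re), 2, function(z) order(-z, abs(env_lags))[1])
  for (e in seq_len(E)) {
    if (stats::var(Y[, e]) == 0) {
      elag <- 0L
      r_e <- 0
    } else {
      elag <- env_lags[best_e[e]]
      r_e <- re[best_e[e], e]
      Y[, e] <- ols_residual(Y[, e], shift_frames(confounds$envelope, elag))$residual
    }
    rows[[e]]$envelope_lag <- elag / fr
    rows[[e]]$envelope_r <- r_e
  }
  out$hfb <- t(Y)
  list(recording = out, lags = dplyr::bind_rows(rows))
}
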