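#' Build a block-stratified cross-validation fold plan
#'
#' Tiles every stimulus block into `fragment_seconds` fragments and assigns
#' fragments to folds round-robin within block (random starting offset per
#' block), so each fold's test set is a concatenation of short fragments
#' drawn from multiple speech and music blocks. The assignment is exhaustive
#' and disjoint; leftover frames at the end of a block are absorbed by its
#' last fragment.
#'
#' @param n_frames total number of frames.
#' @param frame_rate frames per second.
#' @param block_design per-frame block indicator (+1/-1), constant within a
#'   block and alternating between blocks.
#' @param n_folds number of folds (>= 2, default 5).
#' @param fragment_seconds fragment duration in seconds (default 6).
#' @param seed integer seed for the per-block starting offsets.
#' @return a `fold_plan`: list with `fragments` (tibble `block`, `block_type`,
#'   `fragment`, `start`, `end`, `fold`), `n_folds`, `n_frames`, `frame_rate`.
#' @export
make_fold_plan <- function(n_frames, frame_rate, block_design, n_folds = 5,
                           fragment_seconds = 6, seed = 1) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  frag_len <- round(fragment_seconds * frame_rate)
  if (frag_len < 1) stop("`fragment_seconds` below one frame", call. = FALSE)
  stopifnot(length(block_design) == n_frames)
  runs <- rle(as.numeric(block_design))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  if (any(runs$lengths < frag_len)) {
    stop("every block must be at least one fragment long", call. = FALSE)
  }
  offs <- with_seed(seed, sample.int(n_folds, length(starts), replace = TRUE))
  rows <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    n_frag <- floor(runs$lengths[b] / frag_len)
    fs <- starts[b] + (seq_len(n_frag) - 1L) * frag_len
    fe <- fs + frag_len - 1L
    fe[n_frag] <- ends[b]                 # last fragment absorbs the remainder
    rows[[b]] <- tibble::tibble(
      block = b, block_type = runs$values[b], fragment = seq_len(n_frag),
      start = fs, end = fe,
      fold = ((seq_len(n_frag) - 1L + offs[b]) %% n_folds) + 1L)
  }
  structure(list(fragments = dplyr::bind_rows(rows), n_folds = n_folds,
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 seed = seed),
            class = "fold_plan")
}

#' Frame indices of one fold's test set
#' @param plan a `fold_plan`.
#' @param fold fold number.
#' @return sorted integer frame indices.
#' @export
fold_test_indices <- function(plan, fold) {
  fr <- plan$fragments[plan$fragments$fold == fold, ]
  sort(unlist(purrr::map2(fr$start, fr$end, seq.int)))
}

# Inner fold plan: reassign the training fragments of `outer_fold`
# round-robin to `n_inner` inner folds.
inner_fold_frames <- function(plan, outer_fold, n_inner = plan$n_folds) {
  fr <- plan$fragments[plan$fragments$fold != outer_fold, ]
  fr <- fr[order(fr$block, fr$fragment), ]
  inner <- ((seq_len(nrow(fr)) - 1L) %% n_inner) + 1L
  lapply(seq_len(n_inner), function(g) {
    sub <- fr[inner == g, ]
    sort(unlist(purrr::map2(sub$start, sub$end, seq.int)))
  })
}

# Ridge solver on standardized features via an eigendecomposition of the
# Gram matrix: one factorization per training set serves the whole lambda
# grid and every electrode at once. Centering and scaling are folded into
# the Gram matrices so no standardized data copies are materialized.
ridge_context <- function(X, Y, idx) {
  Xt <- X[idx, , drop = FALSE]
  Yt <- Y[idx, , drop = FALSE]
  n <- length(idx)
  xm <- colMeans(Xt)
  ym <- colMeans(Yt)
  xv <- (colSums(Xt^2) - n * xm^2) / (n - 1)
  xs <- sqrt(pmax(xv, 0))
  xs[xs == 0] <- 1
  XtX <- (crossprod(Xt) - n * tcrossprod(xm)) / outer(xs, xs)
  XtY <- (crossprod(Xt, Yt) - n * outer(xm, ym)) / xs
  eig <- eigen(XtX, symmetric = TRUE)
  list(xm = xm, xs = xs, ym = ym, Q = eig$vectors,
       d = pmax(eig$values, 0), XtY = XtY)
}

ridge_betas <- function(ctx, lambda) {
  ctx$Q %*% ((1 / (ctx$d + lambda)) * crossprod(ctx$Q, ctx$XtY))
}

# Pyper-Peterman effective sample size for the correlation of two
# autocorrelated series: n / (1 + 2 sum_k acf_x(k) acf_y(k)).
effective_n <- function(x, y, max_lag = NULL) {
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(100L, floor(n / 5))
  ax <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  ay <- stats::acf(y, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  denom <- 1 + 2 * sum(ax * ay)
  max(8, min(n, n / max(1, denom)))
}

#' Convert cross-validated correlations to t-based significance
#'
#' Transforms per-electrode correlations to t values,
#' `t = r sqrt((n_eff - 2) / (1 - r^2))`, takes two-sided p values from the t
#' distribution with `n_eff - 2` degrees of freedom and Bonferroni-corrects
#' by the number of tests (electrodes).
#'
#' @param r_cv per-electrode correlation values in `[-1, 1]`.
#' @param n_eff effective sample size(s), scalar or per electrode (> 2).
#' @param n_tests Bonferroni correction factor (default `length(r_cv)`).
#' @param alpha significance level after correction (default 0.001).
#' @return tibble `r_cv`, `t`, `p_value` (corrected, capped at 1),
#'   `significant`.
#' @export
significance <- function(r_cv, n_eff, n_tests = length(r_cv), alpha = 0.001) {
  if (any(n_eff <= 2)) stop("`n_eff` must exceed 2", call. = FALSE)
  r <- pmin(pmax(r_cv, -1), 1)
  t <- ifelse(abs(r) == 1, Inf, r * sqrt((n_eff - 2) / (1 - r^2)))
  p <- ifelse(abs(r) == 1, 0, 2 * stats::pt(-abs(t), df = n_eff - 2))
  p_corr <- pmin(1, p * n_tests)
  tibble::tibble(r_cv = r_cv, t = t, p_value = p_corr,
                 significant = p_corr < alpha)
}

#' Fit the cross-validated ridge encoding model
#'
#' Predicts every electrode's (residualized) HFB series from the time-shifted
#' stimulus features by ridge regression with nested cross-validation: for
#' each outer fold, inner folds over the training fragments select the
#' regularization strength per electrode from `lambda_grid` by mean
#' validation correlation; the model is refit on the outer training set and
#' scored by Pearson correlation on the held-out test set. Features are
#' standardized with training-set statistics; the intercept is handled by
#' centering. Reported weights are averaged over the outer folds and
#' back-transformed to the original feature scale.
#'
#' @param features frames x K numeric matrix (e.g. residualized component
#'   scores).
#' @param hfb electrodes x frames response matrix.
#' @param plan a `fold_plan`.
#' @param time_shift stimulus-to-response shift in seconds (integer number of
#'   frames; positive = response delayed).
#' @param lambda_grid candidate ridge penalties (default log-spaced
#'   `10^-3 .. 10^6`, 10 points).
#' @param alpha significance level (Bonferroni-corrected), default 0.001.
#' @param n_tests Bonferroni factor, default the number of electrodes.
#' @param df_method `"bartlett"` (default) estimates an effective sample size
#'   per electrode from the autocorrelation of predicted and observed test
#'   series; `"frames"` uses the raw per-fold test length.
#' @return an `encoding_fit`: list with `betas` (electrodes x K, original
#'   feature scale), `betas_std` (electrodes x K on the standardized-feature
#'   scale the model works in; the scale used for weight-profile analyses),
#'   `lambda` (per electrode), `r_cv`, `t`, `p_value`,
#'   `significant`, `n_eff`, `time_shift`, `alpha`, `flagged` (degenerate
#'   electrodes), `fold_r` (electrodes x folds).
#' @export
fit_ridge_cv <- function(features, hfb, plan, time_shift = 0,
                         lambda_grid = 10^seq(-3, 6, length.out = 10),
                         alpha = 0.001, n_tests = NULL,
                         df_method = c("bartlett", "frames")) {
  df_method <- match.arg(df_method)
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  lambda_grid <- sort(lambda_grid)
  X0 <- as.matrix(features)
  Y <- t(hfb)                              # frames x electrodes
  stopifnot(nrow(X0) == plan$n_frames, nrow(Y) == plan$n_frames)
  k_shift <- seconds_to_frames(time_shift, plan$frame_rate, "time_shift")
  X <- shift_frames(X0, k_shift)
  E <- ncol(Y)
  K <- ncol(X)
  nl <- length(lambda_grid)

  betas_sum <- matrix(0, K, E)
  betas_std_sum <- matrix(0, K, E)
  fold_r <- matrix(NA_real_, E, plan$n_folds)
  lambda_sel <- matrix(NA_real_, E, plan$n_folds)
  neff_mat <- matrix(NA_real_, E, plan$n_folds)
  flagged <- rep(FALSE, E)
  test_len <- numeric(plan$n_folds)

  for (f in seq_len(plan$n_folds)) {
    test_idx <- fold_test_indices(plan, f)
    train_idx <- setdiff(seq_len(plan$n_frames), test_idx)
    test_len[f] <- length(test_idx)

    inner <- inner_fold_frames(plan, f)
    val_r <- matrix(0, E, nl)
    for (g in seq_along(inner)) {
      val_idx <- inner[[g]]
      fit_idx <- setdiff(train_idx, val_idx)
      ctx <- ridge_context(X, Y, fit_idx)
      Xv <- X[val_idx, , drop = FALSE]
      Yv <- Y[val_idx, , drop = FALSE]
      for (l in seq_len(nl)) {
        # correlation is invariant to the affine part, so predictions are
        # formed on the raw feature scale without centering
        rr <- col_cor(Xv %*% (ridge_betas(ctx, lambda_grid[l]) / ctx$xs), Yv)
        val_r[, l] <- val_r[, l] + ifelse(is.na(rr), 0, rr)
      }
    }
    sel <- max.col(val_r, ties.method = "last")
    lambda_sel[, f] <- lambda_grid[sel]

    ctx <- ridge_context(X, Y, train_idx)
    Xtst <- X[test_idx, , drop = FALSE]
    Ytest <- Y[test_idx, , drop = FALSE]
    for (l in unique(sel)) {
      cols <- which(sel == l)
      B <- ridge_betas(ctx, lambda_grid[l])[, cols, drop = FALSE]
      pred <- Xtst %*% (B / ctx$xs)
      rr <- col_cor(pred, Ytest[, cols, drop = FALSE])
      deg <- is.na(rr)
      rr[deg] <- 0
      flagged[cols[deg]] <- TRUE
      fold_r[cols, f] <- rr
      betas_sum[, cols] <- betas_sum[, cols] + B / ctx$xs
      betas_std_sum[, cols] <- betas_std_sum[, cols] + B
      if (df_method == "bartlett") {
        for (j in seq_along(cols)) {
          neff_mat[cols[j], f] <- effective_n(pred[, j], Ytest[, cols[j]])
        }
      }
    }
  }

  r_cv <- rowMeans(fold_r)
  betas <- t(betas_sum) / plan$n_folds
  betas_std <- t(betas_std_sum) / plan$n_folds
  rownames(betas) <- rownames(betas_std) <- rownames(hfb)
  colnames(betas) <- colnames(betas_std) <- colnames(features)
  n_eff <- if (df_method == "bartlett") rowMeans(neff_mat) else rep(mean(test_len), E)
  if (is.null(n_tests)) n_tests <- E
  sig <- significance(r_cv, n_eff, n_tests, alpha)

  structure(list(betas = betas, betas_std = betas_std,
                 lambda = apply(lambda_sel, 1, function(z) exp(mean(log(z)))),
                 r_cv = r_cv, t = sig$t, p_value = sig$p_value,
                 significant = sig$significant, n_eff = n_eff,
                 time_shift = time_shift, alpha = alpha, n_tests = n_tests,
                 df_method = df_method, flagged = flagged, fold_r = fold_r),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> %d electrodes, shift %g s: %d significant, max r_cv %.3f\n",
              length(x$r_cv), x$time_shift, sum(x$significant), max(x$r_cv)))
  invisible(x)
}

#' @rdname fit_ridge_cv
#' @param x an `encoding_fit`.
#' @param ... unused.
#' @export
tidy.encoding_fit <- function(x, ...) {
  tibble::tibble(electrode = seq_along(x$r_cv), r_cv = x$r_cv, t = x$t,
                 p_value = x$p_value, significant = x$significant,
                 lambda = x$lambda, n_eff = x$n_eff, flagged = x$flagged)
}

#' @rdname fit_ridge_cv
#' @export
glance.encoding_fit <- function(x, ...) {
  tibble::tibble(n_electrodes = length(x$r_cv),
                 n_significant = sum(x$significant),
                 mean_r_significant = ifelse(any(x$significant),
                                             mean(x$r_cv[x$significant]), NA_real_),
                 max_r_cv = max(x$r_cv), time_shift = x$time_shift,
                 alpha = x$alpha)
}

#' Sweep the encoding model over stimulus-response time shifts
#'
#' Refits the full nested-CV ridge model at every shift on a grid and records
#' the number of significantly predicted electrodes and the mean correlation
#' over the significant set. The best shift maximizes the significant count;
#' ties are broken by mean correlation, then by the smaller absolute shift.
#'
#' @param features,hfb,plan,lambda_grid,alpha,df_method as in
#'   [fit_ridge_cv()].
#' @param shift_range two-element range in seconds (default `c(-10, 10)`).
#' @param step grid step in seconds; must be an integer multiple of the frame
#'   period (default one frame period).
#' @return a `shift_sweep`: list with `curve` (tibble `shift`,
#'   `n_significant`, `mean_r_significant`, `mean_r_all`), `best_shift`
#'   (seconds) and `frame_rate`.
#' @export
sweep_time_shifts <- function(features, hfb, plan, shift_range = c(-10, 10),
                              step = NULL,
                              lambda_grid = 10^seq(-3, 6, length.out = 10),
                              alpha = 0.001, df_method = "bartlett") {
  fr <- plan$frame_rate
  if (is.null(step)) step <- 1 / fr
  step_frames <- seconds_to_frames(step, fr, "step")
  if (step_frames < 1) stop("`step` must be at least one frame period", call. = FALSE)
  k0 <- seconds_to_frames(shift_range[1], fr, "shift_range")
  k1 <- seconds_to_frames(shift_range[2], fr, "shift_range")
  shifts_frames <- seq.int(k0, k1, by = step_frames)
  if (max(abs(shifts_frames)) >= plan$n_frames) {
    stop("`shift_range` exceeds the data duration", call. = FALSE)
  }
  rows <- purrr::map(shifts_frames, function(k) {
    fit <- fit_ridge_cv(features, hfb, plan, time_shift = k / fr,
                        lambda_grid = lambda_grid, alpha = alpha,
                        df_method = df_method)
    tibble::tibble(shift = k / fr, n_significant = sum(fit$significant),
                   mean_r_significant = ifelse(any(fit$significant),
                                               mean(fit$r_cv[fit$significant]),
                                               NA_real_),
                   mean_r_all = mean(fit$r_cv))
  })
  curve <- dplyr::bind_rows(rows)
  score <- ifelse(is.na(curve$mean_r_significant), curve$mean_r_all,
                  curve$mean_r_significant)
  best <- order(-curve$n_significant, -score, abs(curve$shift))[1]
  structure(list(curve = curve, best_shift = curve$shift[best],
                 frame_rate = fr),
            class = "shift_sweep")
}

#' @export
print.shift_sweep <- function(x, ...) {
  cat(sprintf("<shift_sweep> %d shifts, best at %g s\n",
              nrow(x$curve), x$best_shift))
  invisible(x)
}

#' @rdname sweep_time_shifts
#' @param x a `shift_sweep`.
#' @param ... unused.
#' @export
tidy.shift_sweep <- function(x, ...) x$curve
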