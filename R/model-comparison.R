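#' Flatten frame images into raw pixel features
#'
#' One row per frame: the RGB values flattened row-major, channels last
#' (`M = height * width * 3` columns).
#'
#' @param images a `frame_image_stack` (frames x H x W x 3 array).
#' @return a `feature_set`: list with `name = "pixel"`, `values` (frames x M)
#'   and `reduced = NULL`.
#' @export
pixel_features <- function(images) {
  d <- dim(images)
  # per frame: row-major over (row, col), channel fastest
  values <- matrix(0, d[1], d[2] * d[3] * d[4])
  for (f in seq_len(d[1])) {
    values[f, ] <- as.vector(aperm(array(images[f, , , ], d[2:4]), c(3, 2, 1)))
  }
  structure(list(name = "pixel", values = values, reduced = NULL),
            class = "feature_set")
}

# Quadrature Gabor pair (even/odd) at one scale, orientation and position,
# returned as flattened filters over an H x W luminance image.
gabor_pair <- function(height, width, freq, theta, cx, cy, sigma) {
  yy <- (matrix(rep(seq_len(height), width), height, width) / height) - cy
  xx <- (matrix(rep(seq_len(width), each = height), height, width) / width) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  env <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * freq * u)
  even <- even - mean(even)            # zero-DC: no response to constants
  list(even = as.vector(even),
       odd = as.vector(env * sin(2 * pi * freq * u)))
}

#' Gabor-pyramid complex-cell energy features
#'
#' Converts frames to luminance (mean of RGB), then computes, for each
#' (scale, orientation, position), the quadrature-pair energy
#' `sqrt(even^2 + odd^2)` of a Gabor filter pair — a model of retinotopic
#' complex-cell responses. Scale `j` uses spatial frequency `2^j`
#' cycles/image on a `2^j x 2^j` position grid with an envelope sigma of half
#' a wavelength.
#'
#' @param images a `frame_image_stack`.
#' @param scales number of dyadic scales (default 4).
#' @param orientations number of evenly spaced orientations in `[0, pi)`
#'   (default 8).
#' @return a `feature_set` with `name = "gabor"`, `values` (frames x M
#'   energies, `M = orientations * sum_j 4^j`) and a `filters` attribute
#'   recording the (scale, orientation, x, y) of every column.
#' @export
gabor_features <- function(images, scales = 4, orientations = 8) {
  d <- dim(images)
  height <- d[2]; width <- d[3]
  lum <- matrix(0, d[1], height * width)
  for (f in seq_len(d[1])) {
    lum[f, ] <- as.vector((images[f, , , 1] + images[f, , , 2] + images[f, , , 3]) / 3)
  }
  ev_list <- list(); od_list <- list(); meta <- list()
  for (j in seq_len(scales)) {
    freq <- 2^j
    wavelength_px <- min(height, width) / freq
    if (wavelength_px < 2) {
      warning(sprintf("scale %d finer than the pixel grid; skipped", j))
      next
    }
    grid <- (seq_len(2^j) - 0.5) / 2^j
    sigma <- 1 / (2 * freq)
    for (th in (seq_len(orientations) - 1) / orientations * pi) {
      for (cx in grid) for (cy in grid) {
        gp <- gabor_pair(height, width, freq, th, cx, cy, sigma)
        ev_list[[length(ev_list) + 1]] <- gp$even
        od_list[[length(od_list) + 1]] <- gp$odd
        meta[[length(meta) + 1]] <- c(scale = j, theta = th, x = cx, y = cy)
      }
    }
  }
  Fe <- do.call(cbind, ev_list)
  Fo <- do.call(cbind, od_list)
  energy <- sqrt((lum %*% Fe)^2 + (lum %*% Fo)^2)
  out <- structure(list(name = "gabor", values = energy, reduced = NULL),
                   class = "feature_set")
  attr(out, "filters") <- do.call(rbind, meta)
  out
}

#' Reduce a feature set to its leading principal components
#'
#' Projects a (typically very wide) feature set onto its top `n_components`
#' principal components with the same PCA contract as the semantic
#' components (mean centering, no scaling, deterministic sign), so control
#' models match the semantic model's dimensionality.
#'
#' @param features a `feature_set`.
#' @param n_components target dimensionality (default 50).
#' @return the `feature_set` with `reduced` filled in (frames x
#'   `n_components`).
#' @export
reduce_features <- function(features, n_components = 50) {
  stopifnot(inherits(features, "feature_set"))
  fem <- structure(list(values = features$values,
                        n_labels_used = rep(1L, nrow(features$values)),
                        frame_rate = NA_real_),
                   class = "frame_embedding_matrix")
  comps <- fit_components(fem, min(n_components,
                                   nrow(features$values) - 1,
                                   ncol(features$values)))
  features$reduced <- comps$scores
  features
}

# One-sided (a > b) Wilcoxon signed-rank z statistic with the normal
# approximation, zero-difference dropping and tie correction.
signed_rank_z <- function(a, b, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(z = 0, p = if (alternative == "greater") 0.5 else 1,
                statistic = 0, n = 0))
  }
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  if (n < 50 && !any(duplicated(rk))) {
    # exact null distribution (small untied samples, as wilcox.test uses)
    p_ge <- stats::psignrank(w_pos - 1, n, lower.tail = FALSE)
    p <- if (alternative == "greater") p_ge
         else min(1, 2 * min(stats::psignrank(w_pos, n), p_ge))
  } else {
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = p, statistic = w_pos, n = n)
}

#' Compare two encoding models by a one-sided signed-rank test
#'
#' Tests whether model A predicts better than model B over the union of
#' electrodes with a significant fit in either model, using a one-sided
#' Wilcoxon signed-rank test on the paired cross-validated correlations
#' (alternative: A > B).
#'
#' @param fit_a,fit_b `encoding_fit` objects on the same electrodes and time
#'   shift.
#' @param alpha unused for the test itself; retained for reporting.
#' @return tibble with `z`, `p`, `n_electrodes`, `median_a`, `median_b` and a
#'   `electrode_set` attribute holding the compared indices.
#' @export
compare_models <- function(fit_a, fit_b, alpha = 0.001) {
  stopifnot(inherits(fit_a, "encoding_fit"), inherits(fit_b, "encoding_fit"))
  if (length(fit_a$r_cv) != length(fit_b$r_cv)) {
    stop("fits cover different electrode sets", call. = FALSE)
  }
  if (!isTRUE(all.equal(fit_a$time_shift, fit_b$time_shift))) {
    stop("fits were computed at different time shifts", call. = FALSE)
  }
  idx <- which(fit_a$significant | fit_b$significant)
  if (length(idx) == 0) stop("no electrode significant in either model", call. = FALSE)
  ww <- signed_rank_z(fit_a$r_cv[idx], fit_b$r_cv[idx], "greater")
  out <- tibble::tibble(z = ww$z, p = ww$p, n_electrodes = length(idx),
                        median_a = stats::median(fit_a$r_cv[idx]),
                        median_b = stats::median(fit_b$r_cv[idx]))
  attr(out, "electrode_set") <- idx
  out
}

# Upper-triangle (diagonal excluded) of the frames x frames Pearson
# similarity matrix of a frames x M representation. Zero-variance frames
# yield NA entries which the caller drops pairwise.
similarity_upper <- function(values) {
  cm <- suppressWarnings(stats::cor(t(values)))
  cm[upper.tri(cm)]
}

#' Representational similarity of feature layers with the semantic components
#'
#' For each candidate layer, computes the frames x frames Pearson similarity
#' matrix and correlates its upper triangle (diagonal excluded) with the
#' upper triangle of the target's similarity matrix — a simplified
#' representational similarity analysis with the semantic components as the
#' target representation. Uncertainty comes from a bootstrap over frames
#' (resampled with replacement), recomputing the whole score per replicate.
#'
#' @param layers named list of `feature_set`s (or plain frames x M matrices).
#' @param target a `semantic_components` (its scores are the target
#'   representation).
#' @param k_subset optional: restrict the target to its top `k_subset`
#'   components.
#' @param n_boot bootstrap replicates (default 1000).
#' @param boot_frames frames per bootstrap sample (default
#'   `min(1000, n_frames)`).
#' @param seed integer seed for the bootstrap.
#' @return an `rsa_result`: tibble with `layer`, `similarity`, `ci_lower`,
#'   `ci_upper` plus `n_boot`/`n_frames_sampled` attributes.
#' @export
representational_similarity <- function(layers, target, k_subset = NULL,
                                        n_boot = 1000, boot_frames = NULL,
                                        seed = 1) {
  stopifnot(inherits(target, "semantic_components"))
  mats <- lapply(layers, function(l) {
    if (inherits(l, "feature_set")) {
      if (!is.null(l$reduced)) l$reduced else l$values
    } else as.matrix(l)
  })
  if (is.null(names(mats)) || any(names(mats) == "")) {
    names(mats) <- sprintf("layer%d", seq_along(mats))
  }
  tscores <- target$scores
  if (!is.null(k_subset)) tscores <- tscores[, seq_len(k_subset), drop = FALSE]
  n_frames <- nrow(tscores)
  if (n_frames < 3) stop("need at least 3 frames", call. = FALSE)
  if (any(vapply(mats, nrow, 1L) != n_frames)) {
    stop("layers and target disagree on the number of frames", call. = FALSE)
  }
  if (is.null(boot_frames)) boot_frames <- min(1000L, n_frames)
  if (boot_frames > n_frames) stop("`boot_frames` exceeds n_frames", call. = FALSE)

  # drop frames that are constant in any representation (undefined rows)
  const_in <- function(m) apply(m, 1, stats::sd) == 0
  bad <- Reduce(`|`, lapply(c(mats, list(tscores)), const_in))
  if (any(bad)) {
    warning(sprintf("%d constant frame(s) dropped from the similarity analysis",
                    sum(bad)))
    mats <- lapply(mats, function(m) m[!bad, , drop = FALSE])
    tscores <- tscores[!bad, , drop = FALSE]
    n_frames <- nrow(tscores)
    boot_frames <- min(boot_frames, n_frames)
  }

  score_for <- function(idx) {
    ts <- similarity_upper(tscores[idx, , drop = FALSE])
    vapply(mats, function(m) {
      ls <- similarity_upper(m[idx, , drop = FALSE])
      ok <- stats::complete.cases(ls, ts)
      stats::cor(ls[ok], ts[ok])
    }, numeric(1))
  }

  point <- score_for(seq_len(n_frames))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      score_for(sample.int(n_frames, boot_frames, replace = TRUE))
    }, numeric(length(mats)))
  })
  boot <- matrix(boot, nrow = length(mats))
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)

  out <- tibble::tibble(layer = names(mats), similarity = unname(point),
                        ci_lower = unname(pmin(ci[1, ], point)),
                        ci_upper = unname(pmax(ci[2, ], point)))
  attr(out, "n_boot") <- n_boot
  attr(out, "n_frames_sampled") <- boot_frames
  class(out) <- c("rsa_result", class(out))
  out
}

#' Synthetic hierarchical feature layers
#'
#' Builds a stack of synthetic "layers" interpolating between pixel-like
#' noise and the target representation: layer `l` mixes a random projection
#' of the target scores (weight `weights[l]`) with independent noise
#' (weight `1 - weights[l]`). With increasing weights the layers emulate the
#' gradual emergence of semantic structure along a deep network's hierarchy;
#' no pretrained network is involved.
#'
#' @param target a `semantic_components`.
#' @param weights increasing mixing weights in `[0, 1]`, one per layer.
#' @param n_features feature count per layer (default 100).
#' @param seed integer seed.
#' @return named list of frames x `n_features` matrices.
#' @export
synthetic_hierarchy <- function(target, weights = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                n_features = 100, seed = 1) {
  stopifnot(inherits(target, "semantic_components"))
  S <- scale(target$scores)
  n <- nrow(S); K <- ncol(S)
  with_seed(seed, {
    # one shared projection: layers differ only in their semantic content
    P <- matrix(stats::rnorm(K * n_features), K, n_features) / sqrt(K)
    sig <- S %*% P
    out <- lapply(seq_along(weights), function(l) {
      noise <- matrix(stats::rnorm(n * n_features), n, n_features)
      weights[l] * sig + (1 - weights[l]) * noise
    })
    names(out) <- sprintf("layer%d", seq_along(weights))
    out
  })
}
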