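#' Filter a frame label table by probability and vocabulary
#'
#' Retains entries whose probability is strictly greater than
#' `min_probability` and whose label is in the curated `keep_list`; duplicate
#' labels within a frame are collapsed (keeping the highest probability).
#' Mirrors the curation step of an automatic concept recognizer: labels below
#' 90% probability and outside the corrected vocabulary are dropped.
#'
#' @param table a `frame_label_table`.
#' @param min_probability threshold in `[0, 1]`; retention is strict (`>`).
#' @param keep_list character vector of admissible labels (non-empty).
#' @return a filtered `frame_label_table` with the same frame-count and
#'   frame-rate attributes; frames may end up with zero labels.
#' @export
filter_labels <- function(table, min_probability = 0.9, keep_list) {
  stopifnot(inherits(table, "frame_label_table"))
  check_prob(min_probability, "min_probability")
  if (missing(keep_list) || length(keep_list) == 0) {
    stop("`keep_list` must be a non-empty label set", call. = FALSE)
  }
  at <- attributes(table)
  out <- table[table$probability > min_probability & table$label %in% keep_list, ]
  # collapse per-frame duplicates, keeping the highest probability
  out <- out[order(out$frame, out$label, -out$probability), ]
  out <- out[!duplicated(out[c("frame", "label")]), ]
  out <- out[order(out$frame), ]
  attr(out, "n_frames") <- at$n_frames
  attr(out, "frame_rate") <- at$frame_rate
  attr(out, "scene_topic") <- at$scene_topic
  class(out) <- unique(c("frame_label_table", class(out)))
  out
}

#' Average embedding vectors over the labels of each frame
#'
#' Looks up each label's vector in the lexicon and averages (unweighted) over
#' all labels of a frame, yielding one semantic vector per frame. Frames with
#' no surviving labels get an all-zero row and are flagged so the PCA stage
#' can exclude them.
#'
#' @param table a (typically filtered) `frame_label_table`.
#' @param lexicon an `embedding_lexicon` covering every label in `table`.
#' @return a `frame_embedding_matrix`: list with `values` (frames x D matrix),
#'   `n_labels_used` (integer per frame) and `frame_rate`.
#' @export
embed_frames <- function(table, lexicon) {
  stopifnot(inherits(table, "frame_label_table"),
            inherits(lexicon, "embedding_lexicon"))
  n_frames <- attr(table, "n_frames")
  idx <- match(table$label, lexicon$labels)
  if (anyNA(idx)) {
    missing_lab <- unique(table$label[is.na(idx)])
    stop(sprintf("labels not found in lexicon: %s",
                 paste(utils::head(missing_lab, 5), collapse = ", ")), call. = FALSE)
  }
  D <- ncol(lexicon$vectors)
  sums <- rowsum(lexicon$vectors[idx, , drop = FALSE], group = table$frame)
  counts <- as.integer(table(factor(table$frame, levels = seq_len(n_frames))))
  values <- matrix(0, n_frames, D)
  present <- as.integer(rownames(sums))
  values[present, ] <- sums / counts[present]
  structure(list(values = values, n_labels_used = counts,
                 frame_rate = attr(table, "frame_rate")),
            class = "frame_embedding_matrix")
}

#' Extract semantic components by principal component analysis
#'
#' Fits a PCA (column-mean centering, no variance scaling) to the
#' frame-averaged embedding vectors and keeps the leading `n_components`
#' axes, ordered by explained variance. Zero-label frames are excluded from
#' the fit; their scores are the projection of the global mean, i.e. zero.
#' Component signs follow a fixed convention: the largest-magnitude loading
#' coefficient of each component is positive.
#'
#' @param embeddings a `frame_embedding_matrix`.
#' @param n_components number of components K (<= min(frames, D)).
#' @return a `semantic_components`: list with `scores` (frames x K),
#'   `loadings` (D x K, orthonormal columns), `mean` (length-D centering
#'   vector), `explained_variance_ratio` (length K, non-increasing),
#'   `excluded_frames` and `frame_rate`.
#' @export
fit_components <- function(embeddings, n_components = 50) {
  stopifnot(inherits(embeddings, "frame_embedding_matrix"))
  n_components <- check_count(n_components, "n_components")
  keep <- embeddings$n_labels_used > 0
  X <- embeddings$values[keep, , drop = FALSE]
  if (n_components > min(nrow(X), ncol(X))) {
    stop("`n_components` exceeds min(n_frames, D) after excluding empty frames",
         call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  loadings <- pc$rotation
  # deterministic sign: largest |loading| entry positive
  flip <- vapply(seq_len(ncol(loadings)), function(k) {
    v <- loadings[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, `*`)

  total_var <- sum(apply(X, 2, stats::var))
  evr <- pc$sdev[seq_len(n_components)]^2 / total_var

  scores <- matrix(0, length(keep), n_components)
  scores[keep, ] <- sweep(X, 2, pc$center) %*% loadings
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", seq_len(n_components))

  structure(list(scores = scores, loadings = loadings, mean = pc$center,
                 explained_variance_ratio = evr,
                 excluded_frames = which(!keep),
                 frame_rate = embeddings$frame_rate),
            class = "semantic_components")
}

#' @export
print.semantic_components <- function(x, ...) {
  cat(sprintf("<semantic_components> %d frames x %d components (%.2f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' @rdname fit_components
#' @param x a `semantic_components` object.
#' @param ... unused.
#' @export
glance.semantic_components <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$scores), n_components = ncol(x$scores),
                 variance_retained = sum(x$explained_variance_ratio),
                 variance_top5 = sum(utils::head(x$explained_variance_ratio, 5)))
}

#' @rdname fit_components
#' @export
tidy.semantic_components <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_variance_ratio),
                 explained_variance_ratio = x$explained_variance_ratio)
}

#' Rank frames along one semantic component
#'
#' Selects the frames with the bottom and top `fraction` of scores along a
#' component (the frames that most strongly express its negative and positive
#' poles) and tallies the concept labels occurring in each set.
#'
#' @param components a `semantic_components`.
#' @param component_idx component to rank along (1-based).
#' @param fraction fraction per tail, in `(0, 0.5]` (default 0.10).
#' @param table optional `frame_label_table` used for the label histograms;
#'   omit to skip them.
#' @return list with `bottom_frames`, `top_frames` (integer frame indices,
#'   each of size `ceiling(fraction * n_frames)`, ties broken by ascending
#'   frame index) and `label_histograms` (tibble `set`, `label`, `n`, or NULL).
#' @export
rank_frames <- function(components, component_idx = 1, fraction = 0.10,
                        table = NULL) {
  stopifnot(inherits(components, "semantic_components"))
  if (component_idx < 1 || component_idx > ncol(components$scores)) {
    stop("`component_idx` out of range", call. = FALSE)
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("`fraction` must lie in (0, 0.5]", call. = FALSE)
  }
  s <- components$scores[, component_idx]
  n <- length(s)
  m <- ceiling(fraction * n)
  # ties broken by ascending frame index in both tails
  bottom <- sort(order(s, seq_len(n))[seq_len(m)])
  top <- sort(order(-s, seq_len(n))[seq_len(m)])

  hist <- NULL
  if (!is.null(table)) {
    counts <- function(frames, set) {
      sub <- table[table$frame %in% frames, ]
      if (nrow(sub) == 0) return(tibble::tibble(set = character(), label = character(), n = integer()))
      out <- dplyr::count(sub, .data$label, sort = TRUE)
      tibble::add_column(out, set = set, .before = 1)
    }
    hist <- dplyr::bind_rows(counts(bottom, "bottom"), counts(top, "top"))
  }
  list(bottom_frames = bottom, top_frames = top, label_histograms = hist)
}

#' Build a binary frame-by-label indicator matrix
#'
#' Represents the (filtered) concept labels as 0/1 categorical vectors: entry
#' `(f, l)` is 1 when label `l` is assigned to frame `f`. Used both for the
#' post-hoc interpretation regression and as the feature set of the
#' binary-label encoding model.
#'
#' @param table a `frame_label_table`.
#' @param label_ids optional fixed column order; defaults to the sorted unique
#'   labels present.
#' @return a `binary_label_matrix`: list with `values` (frames x L 0/1
#'   matrix) and `label_ids`.
#' @export
binary_label_matrix <- function(table, label_ids = NULL) {
  stopifnot(inherits(table, "frame_label_table"))
  n_frames <- attr(table, "n_frames")
  if (is.null(label_ids)) label_ids <- sort(unique(table$label))
  values <- matrix(0L, n_frames, length(label_ids),
                   dimnames = list(NULL, label_ids))
  j <- match(table$label, label_ids)
  ok <- !is.na(j)
  values[cbind(table$frame[ok], j[ok])] <- 1L
  structure(list(values = values, label_ids = label_ids),
            class = "binary_label_matrix")
}

#' Post-hoc interpretation of components by label regression
#'
#' Fits an ordinary least squares model (with intercept) predicting each of
#' the top `k_top` component score series from the binary concept-label
#' matrix. The per-label weights rank the labels from the most negative to
#' the most positive pole of each component; the overall fit quality is
#' summarized by R-squared and an F statistic pooled over the modelled
#' components.
#'
#' @param components a `semantic_components`.
#' @param labels a `binary_label_matrix` aligned on frames.
#' @param k_top number of leading components to model (default 5).
#' @return list with `weights` (L x k_top matrix), `intercepts`,
#'   `r_squared` (pooled over components), `f_statistic`, `df1`, `df2` and
#'   `per_component` (tibble of per-component R-squared).
#' @export
posthoc_label_regression <- function(components, labels, k_top = 5) {
  stopifnot(inherits(components, "semantic_components"),
            inherits(labels, "binary_label_matrix"))
  k_top <- check_count(k_top, "k_top")
  if (k_top > ncol(components$scores)) stop("`k_top` exceeds K", call. = FALSE)
  Y <- components$scores[, seq_len(k_top), drop = FALSE]
  X <- labels$values
  if (nrow(X) != nrow(Y)) stop("frames do not align between inputs", call. = FALSE)
  n <- nrow(X)
  L <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) {
    warning("rank-deficient label matrix; using the minimum-norm solution")
    coefs <- pseudo_inverse(Xd) %*% Y
  } else {
    coefs <- qr.coef(qrx, Y)
  }
  fitted <- Xd %*% coefs
  res <- Y - fitted
  ss_res <- colSums(res^2)
  ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  r2_comp <- 1 - ss_res / ss_tot
  r2 <- 1 - sum(ss_res) / sum(ss_tot)
  df1 <- qrx$rank - 1
  df2 <- n - qrx$rank
  f_stat <- (r2 / df1) / ((1 - r2) / df2)
  list(weights = coefs[-1, , drop = FALSE],
       intercepts = coefs[1, ],
       r_squared = r2, f_statistic = f_stat, df1 = df1, df2 = df2,
       per_component = tibble::tibble(component = seq_len(k_top),
                                      r_squared = r2_comp))
}

# Moore-Penrose pseudoinverse via SVD (kept local; only needed on the
# rank-deficient path).
pseudo_inverse <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}
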