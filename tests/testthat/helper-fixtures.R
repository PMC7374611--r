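# shared fixtures and small independent oracles, built in code at test time

# adjusted Rand index (independent of any clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# build a frame_label_table by hand
make_label_table <- function(frame, label, probability, n_frames = max(frame),
                             frame_rate = 25) {
  out <- tibble::tibble(frame = as.integer(frame), label = label,
                        probability = probability)
  attr(out, "n_frames") <- as.integer(n_frames)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("frame_label_table", class(out))
  out
}

# build a semantic_components object directly from a score matrix
make_components <- function(scores, evr = NULL, frame_rate = 25) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  if (is.null(evr)) {
    v <- apply(scores, 2, stats::var)
    evr <- v / sum(v)
  }
  structure(list(scores = scores, loadings = diag(K), mean = rep(0, K),
                 explained_variance_ratio = evr, excluded_frames = integer(0),
                 frame_rate = frame_rate),
            class = "semantic_components")
}

# minimal encoding_fit stand-in for comparison tests
make_fit <- function(r_cv, significant, time_shift = 0.32) {
  structure(list(r_cv = r_cv, significant = significant,
                 time_shift = time_shift),
            class = "encoding_fit")
}

# a small film study shared across tests (memoised per test run)
.fixture_env <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_study(
      seed = 42, n_labels = 40, n_topics = 5, dim = 24, n_blocks = 4,
      block_seconds = 12, labels_per_frame = 6, n_components = 12,
      n_subjects = 5, electrodes_per_subject = 4)
  }
  .fixture_env$small
}
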