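test_that("probability filter is strict and vocabulary-aware (hand enumeration)", {
  tbl <- make_label_table(rep(1:5, each = 3), rep(c("a", "b", "c"), 5),
                          rep(c(0.95, 0.91, 0.80), 5))
  out <- filter_labels(tbl, 0.9, c("a", "b", "c"))
  expect_true(all(table(out$frame) == 2))          # 0.95 and 0.91 survive
  expect_setequal(unique(out$label), c("a", "b"))

  # boundary: p = 0.89 dropped by a strict 0.9 threshold
  edge <- make_label_table(1, "a", 0.89)
  expect_equal(nrow(filter_labels(edge, 0.9, "a")), 0)

  # no-op filter is the identity
  idt <- filter_labels(tbl, 0, c("a", "b", "c"))
  expect_equal(dplyr::arrange(tibble::as_tibble(idt), frame, label),
               dplyr::arrange(tibble::as_tibble(tbl), frame, label))

  # duplicates collapse to the highest probability
  dup <- make_label_table(c(1, 1), c("a", "a"), c(0.92, 0.97))
  fd <- filter_labels(dup, 0.9, "a")
  expect_equal(nrow(fd), 1)
  expect_equal(fd$probability, 0.97)

  expect_error(filter_labels(tbl, 0.9, character(0)), "keep_list")
})

test_that("frame embedding equals the label-vector mean (loop oracle)", {
  lex <- generate_lexicon(8, 8, 16, seed = 4)
  # 10 frames with 1..4 labels each
  set.seed(11)
  frames <- rep(1:10, times = sample(1:4, 10, replace = TRUE))
  tbl <- make_label_table(frames, sample(lex$labels, length(frames), TRUE),
                          rep(1, length(frames)), n_frames = 10)
  emb <- embed_frames(tbl, lex)
  oracle <- matrix(0, 10, 16)
  for (f in 1:10) {
    labs <- tbl$label[tbl$frame == f]
    for (l in labs) oracle[f, ] <- oracle[f, ] + lex$vectors[l, ] / length(labs)
  }
  expect_equal(emb$values, oracle, tolerance = 1e-12)

  # mean of one label is that label's vector
  one <- make_label_table(1, lex$labels[3], 1)
  expect_equal(embed_frames(one, lex)$values[1, ], unname(lex$vectors[3, ]))

  # two-label average lies nearer (in cosine) to both parents than a third label
  two <- make_label_table(c(1, 1), lex$labels[c(1, 2)], c(1, 1))
  v <- embed_frames(two, lex)$values[1, ]
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  third <- lex$vectors[7, ]   # different topic than labels 1, 2
  expect_gt(cosim(v, lex$vectors[1, ]), cosim(third, lex$vectors[1, ]))
  expect_gt(cosim(v, lex$vectors[2, ]), cosim(third, lex$vectors[2, ]))

  # averaging is label-order invariant
  rev2 <- make_label_table(c(1, 1), lex$labels[c(2, 1)], c(1, 1))
  expect_equal(embed_frames(rev2, lex)$values, embed_frames(two, lex)$values)

  bad <- make_label_table(1, "nosuch", 1)
  expect_error(embed_frames(bad, lex), "nosuch")
})

test_that("PCA matches an eigendecomposition oracle and keeps its invariants", {
  set.seed(21)
  X <- matrix(rnorm(120 * 6), 120, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  emb <- structure(list(values = X, n_labels_used = rep(1L, 120),
                        frame_rate = 25), class = "frame_embedding_matrix")

  # complete basis recovers all variance
  full <- fit_components(emb, 6)
  expect_equal(sum(full$explained_variance_ratio), 1, tolerance = 1e-10)

  # rank-2 data: ratios equal covariance eigenvalues (dense eigen oracle)
  X2 <- matrix(rnorm(80 * 2), 80, 2) %*% matrix(rnorm(2 * 5), 2, 5)
  emb2 <- structure(list(values = X2, n_labels_used = rep(1L, 80),
                         frame_rate = 25), class = "frame_embedding_matrix")
  pc2 <- fit_components(emb2, 2)
  ev <- eigen(stats::cov(X2), symmetric = TRUE)$values
  expect_equal(pc2$explained_variance_ratio, (ev / sum(ev))[1:2], tolerance = 1e-8)

  # orthonormal loadings, non-increasing ratios, sign convention
  expect_equal(crossprod(full$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(full$explained_variance_ratio) <= 1e-12))
  for (k in 1:6) {
    v <- full$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }

  # reconstruction: residual norm equals the discarded eigenvalue mass
  part <- fit_components(emb, 3)
  Xc <- sweep(X, 2, part$mean)
  resid <- Xc - part$scores %*% t(part$loadings)
  total_var <- sum(apply(X, 2, var))
  discarded <- (1 - sum(part$explained_variance_ratio)) * total_var * (120 - 1)
  expect_equal(sum(resid^2), discarded, tolerance = 1e-8)

  # permuting frames permutes scores identically; loadings unchanged
  perm <- sample(120)
  embp <- structure(list(values = X[perm, ], n_labels_used = rep(1L, 120),
                         frame_rate = 25), class = "frame_embedding_matrix")
  fullp <- fit_components(embp, 6)
  expect_equal(fullp$loadings, full$loadings, tolerance = 1e-8)
  expect_equal(fullp$scores, full$scores[perm, ], tolerance = 1e-8)

  # zero-label frames excluded from the fit and scored as zero
  emb0 <- structure(list(values = rbind(X, 0),
                         n_labels_used = c(rep(1L, 120), 0L),
                         frame_rate = 25), class = "frame_embedding_matrix")
  pc0 <- fit_components(emb0, 3)
  expect_equal(pc0$excluded_frames, 121L)
  expect_equal(pc0$scores[121, ], rep(0, 3), ignore_attr = TRUE)
  expect_equal(pc0$loadings, part$loadings, tolerance = 1e-10)

  expect_error(fit_components(emb, 7), "exceeds")
})

test_that("frame ranking selects exact tail fractions with index tie-breaks", {
  comps <- make_components(cbind(c(-(50:1), 1:50), rnorm(100)))
  rk <- rank_frames(comps, 1, 0.10)
  expect_length(rk$top_frames, 10)
  expect_length(rk$bottom_frames, 10)
  expect_equal(rk$top_frames, 91:100)
  expect_equal(rk$bottom_frames, 1:10)

  half <- rank_frames(comps, 1, 0.5)
  expect_setequal(c(half$top_frames, half$bottom_frames), 1:100)

  # planted contrast: top set dominated by the planted pole's labels
  tbl <- make_label_table(1:100, rep(c("B", "A"), each = 50), rep(1, 100))
  rk2 <- rank_frames(comps, 1, 0.10, table = tbl)
  top_hist <- rk2$label_histograms[rk2$label_histograms$set == "top", ]
  expect_equal(top_hist$label[which.max(top_hist$n)], "A")

  # ties broken by ascending frame index
  tie <- make_components(cbind(rep(c(0, 1), each = 5)))
  rt <- rank_frames(tie, 1, 0.2)
  expect_equal(rt$bottom_frames, 1:2)
  expect_equal(rt$top_frames, 6:7)       # tied scores resolve to earliest frames

  expect_error(rank_frames(comps, 5, 0.1), "out of range")
  expect_error(rank_frames(comps, 1, 0.6), "fraction")
})

test_that("post-hoc label regression matches a pseudo-inverse oracle", {
  set.seed(31)
  B <- matrix(rbinom(20 * 4, 1, 0.4), 20, 4,
              dimnames = list(NULL, letters[1:4]))
  labs <- structure(list(values = B, label_ids = letters[1:4]),
                    class = "binary_label_matrix")
  W <- matrix(rnorm(4 * 2), 4, 2)
  scores <- B %*% W + 0.3
  comps <- make_components(cbind(scores, rnorm(20)))
  fit <- posthoc_label_regression(comps, labs, 2)

  # noiseless linear case
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # pseudo-inverse oracle on the design with intercept
  Xd <- cbind(1, B)
  sv <- svd(Xd)
  coef_or <- sv$v %*% diag(1 / sv$d) %*% t(sv$u) %*% comps$scores[, 1:2]
  expect_equal(unname(fit$weights), unname(coef_or[-1, ]), tolerance = 1e-8)

  # vocabulary-scale shape: a 129-label design gives 129 weight rows
  set.seed(32)
  B2 <- matrix(rbinom(300 * 129, 1, 0.15), 300, 129)
  labs2 <- structure(list(values = B2, label_ids = sprintf("l%03d", 1:129)),
                     class = "binary_label_matrix")
  comps2 <- make_components(matrix(rnorm(300 * 5), 300, 5))
  expect_equal(nrow(posthoc_label_regression(comps2, labs2, 5)$weights), 129)

  # rank deficiency falls back to the minimum-norm solution with a warning
  Bdef <- cbind(B, B[, 1])
  labsd <- structure(list(values = Bdef, label_ids = c(letters[1:4], "e")),
                     class = "binary_label_matrix")
  expect_warning(posthoc_label_regression(comps, labsd, 2), "rank")
})

test_that("binary label matrix is an exact 0/1 indicator", {
  tbl <- make_label_table(c(1, 1, 2, 3), c("a", "b", "b", "a"), rep(1, 4))
  bm <- binary_label_matrix(tbl)
  expect_equal(bm$label_ids, c("a", "b"))
  expect_equal(unname(bm$values),
               matrix(c(1, 0, 1, 1, 1, 0), 3, 2), ignore_attr = TRUE)
})
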