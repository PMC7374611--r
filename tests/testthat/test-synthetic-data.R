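test_that("lexicon generation is deterministic and respects its contracts", {
  lex <- generate_lexicon(129, 8, 300, seed = 5)
  expect_equal(dim(lex$vectors), c(129, 300))
  expect_equal(anyDuplicated(lex$labels), 0L)
  expect_identical(lex, generate_lexicon(129, 8, 300, seed = 5))

  single <- generate_lexicon(1, 1, 5, seed = 1)
  expect_equal(nrow(single$vectors), 1)

  expect_error(generate_lexicon(0, 1, 10), "integer")
  expect_error(generate_lexicon(10, 20, 10), "n_topics")
  expect_error(generate_lexicon(10, 2, 10, spread = 0), "spread")
})

test_that("within-topic cosine similarity exceeds between-topic (brute force)", {
  lex <- generate_lexicon(40, 4, spread = 0.1, seed = 7)
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- c(); between <- c()
  for (i in 1:39) for (j in (i + 1):40) {
    cs <- cosim(lex$vectors[i, ], lex$vectors[j, ])
    if (lex$topic_of[i] == lex$topic_of[j]) within <- c(within, cs)
    else between <- c(between, cs)
  }
  expect_gt(mean(within), mean(between))
})

test_that("stimulus frame count, label count and block alternation are exact", {
  lex <- generate_lexicon(30, 4, 10, seed = 1)
  st <- generate_stimulus(lex, n_blocks = 13, block_seconds = 30,
                          frame_rate = 25, seed = 2)
  expect_equal(attr(st$labels, "n_frames"), 9750)       # 13 x 30 x 25
  expect_equal(nrow(st$confounds), 9750)
  expect_true(all(table(st$labels$frame) == 20))
  runs <- rle(st$confounds$block)
  expect_true(all(runs$lengths == 750))
  expect_true(all(abs(diff(runs$values)) == 2))          # strict alternation
  expect_true(all(st$confounds$envelope >= 0))
  expect_error(generate_stimulus(lex, labels_per_frame = 31), "exceeds")
})

test_that("scene persistence controls embedding autocorrelation monotonically", {
  lex <- generate_lexicon(30, 5, 12, seed = 3)
  lag1 <- function(p, seed) {
    st <- generate_stimulus(lex, n_blocks = 2, block_seconds = 20,
                            frame_rate = 25, labels_per_frame = 5,
                            scene_persistence = p, seed = seed)
    v <- embed_frames(st$labels, lex)$values
    n <- nrow(v)
    mean(vapply(seq_len(ncol(v)), function(d) {
      stats::cor(v[-1, d], v[-n, d])
    }, numeric(1)))
  }
  grid <- vapply(c(0, 0.5, 0.9), function(p) {
    mean(vapply(1:10, function(s) lag1(p, s), numeric(1)))
  }, numeric(1))
  expect_lt(abs(grid[1]), 0.1)                  # no persistence: ~iid scenes
  expect_true(all(diff(grid) > 0))
})

test_that("rendered frames are deterministic, bounded and topic-structured", {
  lex <- generate_lexicon(12, 4, 8, seed = 2)
  st <- generate_stimulus(lex, n_blocks = 2, block_seconds = 2, frame_rate = 25,
                          labels_per_frame = 3, scene_persistence = 0.9, seed = 4)
  img <- render_frames(st$labels, lex, 16, 16, seed = 1)
  expect_equal(dim(img), c(100, 16, 16, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(unclass(img), unclass(render_frames(st$labels, lex, 16, 16, seed = 1)))

  # two frames with identical label sets render identically
  tbl <- make_label_table(c(1, 1, 2, 2), lex$labels[c(1, 5, 1, 5)], rep(1, 4))
  pair <- render_frames(tbl, lex, 16, 16, seed = 9)
  expect_identical(pair[1, , , ], pair[2, , , ])

  # within-scene-topic pixel correlation exceeds between-topic (brute force)
  topic <- attr(st$labels, "scene_topic")
  flat <- matrix(img, 100)
  cm <- suppressWarnings(stats::cor(t(flat)))
  same <- outer(topic, topic, `==`) & upper.tri(cm)
  diff_t <- (!outer(topic, topic, `==`)) & upper.tri(cm)
  expect_gt(mean(cm[same], na.rm = TRUE), mean(cm[diff_t], na.rm = TRUE))

  expect_error(render_frames(tbl, lex, 8, 16), ">= 16")
})

test_that("neural generator reduces to the exact lagged readout without noise", {
  comps <- make_components(matrix(rnorm(500 * 6), 500, 6))
  conf <- small_study()$stimulus$confounds[1:500, ]
  attr(conf, "frame_rate") <- 25
  class(conf) <- c("stimulus_confounds", class(conf))
  geom <- generate_geometry(2, 5, seed = 3)
  out <- generate_neural(comps, conf, geom, lag_true = 0.32, snr = Inf,
                         frac_null = 0.2, ar1 = 0, confound_gain = 0, seed = 6)
  # brute-force index-shift oracle: hfb[e, t] = sum_k beta[e, k] s[t - 8, k]
  beta <- out$truth$beta_true
  expect_equal(out$truth$lag_frames, 8L)     # 0.32 s at 25 Hz
  oracle <- matrix(0, 10, 500)
  for (e in 1:10) for (t in 1:500) {
    if (t > 8) oracle[e, t] <- sum(beta[e, ] * comps$scores[t - 8, ])
  }
  expect_equal(unname(out$recording$hfb), oracle, tolerance = 1e-12)

  # all-null limit
  allnull <- generate_neural(comps, conf, geom, frac_null = 1, seed = 2)
  expect_equal(length(allnull$truth$null_electrodes), 10)
  expect_true(all(allnull$truth$beta_true == 0))

  expect_error(generate_neural(comps, conf, geom, lag_true = 30), "duration")
  expect_error(generate_neural(comps, conf, geom, lag_true = 0.3001), "multiple")
})

test_that("generated signal-to-noise ratio matches the request within 20%", {
  s <- small_study()
  big <- generate_stimulus(s$lexicon, n_blocks = 6, block_seconds = 40,
                           frame_rate = 25, labels_per_frame = 6, seed = 8)
  comps <- fit_components(embed_frames(big$labels, s$lexicon), 12)
  geom <- generate_geometry(4, 5, seed = 1)
  for (snr in c(0.5, 2)) {
    out <- generate_neural(comps, big$confounds, geom, snr = snr,
                           frac_null = 0, confound_gain = 0, ar1 = 0.4, seed = 3)
    lagged <- shift_frames(comps$scores, out$truth$lag_frames)
    signal <- lagged %*% t(out$truth$beta_true)
    noise <- t(out$recording$hfb) - signal
    ratio <- apply(signal, 2, var) / apply(noise, 2, var)
    expect_lt(abs(mean(ratio) - snr) / snr, 0.2)
  }
})

test_that("electrode geometry lies on the unit sphere with per-subject patches", {
  geom <- generate_geometry(6, 7, seed = 2)
  expect_equal(nrow(geom), 42)
  norms <- sqrt(geom$x^2 + geom$y^2 + geom$z^2)
  expect_true(all(abs(norms - 1) < 1e-9))
  expect_equal(length(unique(geom$subject)), 6)
  # patches are compact: within-subject spread below between-subject spread
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  same <- outer(geom$subject, geom$subject, `==`) & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[upper.tri(d) & !same]))
})
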