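test_that("pixel features flatten frames deterministically", {
  set.seed(8)
  img <- array(runif(4 * 20 * 16 * 3), c(4, 20, 16, 3))
  img[2, , , ] <- 0.5                      # constant-colour frame
  img[4, , , ] <- img[1, , , ]             # duplicate frame
  fs <- pixel_features(img)
  expect_equal(ncol(fs$values), 20 * 16 * 3)
  expect_true(all(fs$values[2, ] == 0.5))
  expect_equal(fs$values[4, ], fs$values[1, ])
  expect_equal(cor(fs$values[4, ], fs$values[1, ]), 1)
})

test_that("Gabor energies are orientation-tuned, phase-invariant and vanish on blanks", {
  h <- w <- 32
  yy <- matrix(rep(1:h, w), h, w) / h
  xx <- matrix(rep(1:w, each = h), h, w) / w
  stack_from <- function(imgs) {
    out <- array(0, c(length(imgs), h, w, 3))
    for (i in seq_along(imgs)) for (c3 in 1:3) out[i, , , c3] <- imgs[[i]]
    out
  }
  # grating matched to scale 2 (4 cycles/image), horizontal orientation
  grat <- function(phase) 0.5 + 0.5 * sin(2 * pi * 4 * xx + phase)
  img <- stack_from(lapply(seq(0, 2 * pi, length.out = 9)[1:8], grat))
  fs <- gabor_features(img, scales = 3, orientations = 4)
  meta <- attr(fs, "filters")

  # orientation tuning: summed energy at the matched (scale, orientation)
  # beats every other orientation at that scale
  e_by_or <- vapply(sort(unique(meta[, "theta"])), function(th) {
    sum(fs$values[1, meta[, "scale"] == 2 & meta[, "theta"] == th])
  }, numeric(1))
  expect_equal(which.max(e_by_or), 1L)     # theta = 0 matches d/dx grating

  # quadrature-pair energy is phase invariant (< 1% relative change) for the
  # central filter, whose envelope lies fully inside the image
  ctr <- which(meta[, "scale"] == 2 & meta[, "theta"] == 0 &
                 abs(meta[, "x"] - 0.375) < 1e-9 & abs(meta[, "y"] - 0.375) < 1e-9)
  tot <- fs$values[, ctr]
  expect_lt((max(tot) - min(tot)) / mean(tot), 0.01)

  # blank image: all energies zero
  blank <- stack_from(list(matrix(0, h, w)))
  expect_equal(max(gabor_features(blank, 3, 4)$values), 0)
})

test_that("signed-rank model comparison matches enumeration and handles identity", {
  # identical fits: z = 0 and one-sided p = 0.5 by convention
  fa <- make_fit(seq(0.1, 0.5, length.out = 9), rep(TRUE, 9))
  cmp <- compare_models(fa, fa)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 0.5)

  # 10 hand-written pairs: statistic equals explicit rank enumeration
  a <- c(0.30, 0.25, 0.40, 0.10, 0.55, 0.32, 0.28, 0.47, 0.05, 0.60)
  b <- a - c(0.10, -0.02, 0.18, -0.03, 0.25, 0.01, 0.17, 0.015, -0.025, 0.40)
  ww <- semenc:::signed_rank_z(a, b, "greater")
  d <- a - b
  rk <- rank(abs(d))
  expect_equal(ww$statistic, sum(rk[d > 0]))
  # and its p value matches wilcox.test (exact for small untied samples)
  ref <- stats::wilcox.test(a, b, paired = TRUE, alternative = "greater")
  expect_equal(ww$p, ref$p.value, tolerance = 1e-10)

  # comparison set is the union of significant electrodes
  fb <- make_fit(b, c(rep(TRUE, 3), rep(FALSE, 7)))
  fa2 <- make_fit(a, c(rep(FALSE, 8), TRUE, TRUE))
  out <- compare_models(fa2, fb)
  expect_equal(out$n_electrodes, 5)
  expect_equal(attr(out, "electrode_set"), c(1:3, 9, 10))

  expect_error(compare_models(make_fit(a, rep(FALSE, 10)),
                              make_fit(b, rep(FALSE, 10))), "significant")
  expect_error(compare_models(fa, make_fit(fa$r_cv, rep(TRUE, 9), time_shift = 0)),
               "shift")
})

test_that("signed-rank rejection under exchangeable nulls stays near nominal", {
  set.seed(12)
  rej <- mean(vapply(1:300, function(i) {
    x <- rnorm(30); y <- rnorm(30)
    semenc:::signed_rank_z(x, y, "greater")$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("representational similarity matches a double-loop oracle", {
  set.seed(13)
  comps <- make_components(matrix(rnorm(5 * 3), 5, 3))
  layerA <- matrix(rnorm(5 * 4), 5, 4)
  res <- representational_similarity(
    list(self = comps$scores, other = layerA), comps, n_boot = 20, seed = 1)
  expect_equal(res$similarity[res$layer == "self"], 1, tolerance = 1e-10)

  # double-loop oracle for the other layer
  pc <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  simvec <- function(m) {
    out <- c()
    for (i in 1:4) for (j in (i + 1):5) out <- c(out, pc(m[i, ], m[j, ]))
    out
  }
  oracle <- pc(simvec(layerA), simvec(comps$scores))
  expect_equal(res$similarity[res$layer == "other"], oracle, tolerance = 1e-10)
  expect_true(all(res$ci_lower <= res$similarity & res$similarity <= res$ci_upper))

  # constant frames are dropped with a warning
  layerB <- layerA; layerB[2, ] <- 7
  expect_warning(representational_similarity(list(b = layerB), comps,
                                             n_boot = 10, seed = 1), "constant")
  expect_error(representational_similarity(list(a = layerA[1:2, ]),
                                           make_components(matrix(rnorm(4), 2, 2))),
               "3 frames")
})

test_that("synthetic layer hierarchies grow monotonically similar to the target", {
  set.seed(14)
  comps <- make_components(matrix(rnorm(120 * 6), 120, 6))
  layers <- synthetic_hierarchy(comps, weights = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                n_features = 40, seed = 2)
  res <- representational_similarity(layers, comps, n_boot = 20, seed = 3)
  expect_true(all(diff(res$similarity) > 0))
})

test_that("model comparison is invariant to orthogonal feature rotation before PCA", {
  s <- small_study()
  n <- 400
  set.seed(15)
  Fwide <- matrix(rnorm(n * 12), n, 12)
  rot <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  f1 <- reduce_features(structure(list(name = "a", values = Fwide, reduced = NULL),
                                  class = "feature_set"), 6)
  f2 <- reduce_features(structure(list(name = "b", values = Fwide %*% rot,
                                       reduced = NULL), class = "feature_set"), 6)
  hfb <- t(matrix(rnorm(n * 5), n, 5) + f1$reduced %*% matrix(rnorm(6 * 5), 6, 5))
  block <- rep(rep(c(1, -1), each = 50), 4)
  plan <- make_fold_plan(n, 25, block, fragment_seconds = 0.4, seed = 1)
  r1 <- fit_ridge_cv(f1$reduced, hfb, plan, 0, df_method = "frames")
  r2 <- fit_ridge_cv(f2$reduced, hfb, plan, 0, df_method = "frames")
  expect_equal(r1$r_cv, r2$r_cv, tolerance = 1e-8)
})
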