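planted_betas <- function(n_per = 20, K = 10, jitter = 0.05, seed = 2) {
  set.seed(seed)
  proto <- qr.Q(qr(matrix(rnorm(K * K), K, K)))[1:3, ]
  z <- rep(1:3, each = n_per)
  list(betas = proto[z, ] + matrix(rnorm(3 * n_per * K, sd = jitter),
                                   3 * n_per, K),
       z = z)
}

test_that("affinity propagation recovers well-separated planted prototypes", {
  pl <- planted_betas()
  # planted separation: within-prototype correlation high, between low
  cm <- cor(t(pl$betas))
  within <- cm[outer(pl$z, pl$z, `==`) & upper.tri(cm)]
  between <- cm[!outer(pl$z, pl$z, `==`) & upper.tri(cm)]
  expect_gt(min(within), 0.9)
  expect_lt(max(abs(between)), 0.45)

  cl <- cluster_betas(pl$betas, seed = 1)
  expect_gte(ari(cl$assignment, pl$z), 0.9)

  # exemplar of each cluster maximizes summed within-cluster affinity (brute force)
  for (k in seq_along(cl$exemplar)) {
    members <- which(cl$assignment == k)
    sums <- vapply(members, function(i) {
      sum(cl$affinity[i, setdiff(members, i)])
    }, numeric(1))
    expect_equal(cl$exemplar[k], members[which.max(sums)])
  }
})

test_that("degenerate weight profiles collapse to a single cluster", {
  b <- matrix(rep(c(1, 2, 3, 4), each = 8), 8, 4)
  cl <- cluster_betas(b, seed = 1)
  expect_equal(length(cl$exemplar), 1)
  expect_true(all(cl$assignment == 1))
})

test_that("cluster count grows with the preference value", {
  pl <- planted_betas(n_per = 12, jitter = 0.2)
  counts <- vapply(c(-12, -3, 0.5), function(p) {
    length(cluster_betas(pl$betas, seed = 1, preference = p)$exemplar)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_lt(counts[1], counts[3])
})

test_that("subject-specific clusters are filtered by span and share rules", {
  assignment <- rep(1:3, each = 12)
  subj <- c(sprintf("S%d", c(rep(1, 8), 2, 3, 4, 5)),          # 65%+ from S1
            sprintf("S%d", rep(1:6, 2)),                        # even spread
            sprintf("S%d", c(rep(1, 4), rep(2, 4), rep(3, 4)))) # exactly 1/3
  geom <- tibble::tibble(electrode = 1:36, subject = subj)
  cl <- structure(list(assignment = assignment, exemplar = c(1L, 13L, 25L)),
                  class = "beta_clusters")
  out <- filter_clusters(cl, geom)
  expect_equal(out$retained, c(FALSE, TRUE, TRUE))
  expect_match(out$reason[1], "one subject")
  expect_equal(out$max_subject_share[3], 1 / 3)
})

test_that("activation time courses match the projection identity and loop oracle", {
  comps <- make_components(matrix(rnorm(60 * 4), 60, 4))
  # unit weight on component 1 reproduces its scores exactly
  act <- activation_time_course(comps, c(1, 0, 0, 0), rbind(c(1, 0, 0, 0)))
  expect_equal(act$activation, comps$scores[, 1])
  expect_equal(act$sem_band, rep(0, 60))

  # 4-member cluster: activation and SEM against an explicit loop
  mb <- matrix(rnorm(16), 4, 4)
  act4 <- activation_time_course(comps, mb[2, ], mb)
  for (t in c(1, 17, 60)) {
    expect_equal(act4$activation[t], sum(comps$scores[t, ] * mb[2, ]))
    dots <- vapply(1:4, function(m) sum(comps$scores[t, ] * mb[m, ]), numeric(1))
    expect_equal(act4$sem_band[t], sd(dots) / 2)
  }
})

test_that("the shuffle null brackets degenerate activations and orders selections", {
  s <- small_study()
  pl <- planted_betas(n_per = 10, K = 12, seed = 5)
  comps <- make_components(matrix(rnorm(300 * 12), 300, 12))
  cl <- cluster_betas(pl$betas, seed = 1)
  sel <- peak_dip_null(cl, 1, pl$betas, comps, n_shuffles = 200, seed = 3)
  expect_true(all(sel$activation[sel$peak_frames] > sel$upper_threshold))
  expect_true(all(sel$activation[sel$dip_frames] < sel$lower_threshold))
  expect_length(intersect(sel$peak_frames, sel$dip_frames), 0)
  # ordered by extremity
  expect_true(all(diff(sel$activation[sel$peak_frames]) <= 0))
  expect_true(all(diff(sel$activation[sel$dip_frames]) >= 0))

  # zero weights everywhere: constant (zero) activation, empty selections flagged
  bdeg <- matrix(0, 6, 3)
  cld <- cluster_betas(bdeg, seed = 1)
  compsd <- make_components(matrix(rnorm(50 * 3), 50, 3))
  expect_warning(seld <- peak_dip_null(cld, 1, bdeg, compsd,
                                       n_shuffles = 100, seed = 1),
                 "empty")
  expect_length(seld$peak_frames, 0)
  expect_length(seld$dip_frames, 0)
})

test_that("component contributions detect planted shifts and respect the null", {
  comps <- make_components(matrix(rnorm(200 * 5), 200, 5))
  # planted 2-sd shift on component 2 between peak and dip frames
  comps$scores[1:30, 2] <- comps$scores[1:30, 2] + 2
  sel <- structure(list(peak_frames = 1:30, dip_frames = 31:60,
                        activation = rep(0, 200), n_shuffles = 100),
                   class = "peak_dip_selection")
  out <- component_contribution(sel, comps, k_top = 5, n_clusters = 1)
  expect_true(out$significant[2])
  expect_gt(out$statistic[2], 0)
  expect_equal(sign(out$adjusted_statistic[2]), sign(out$statistic[2]))

  # identical peak and dip frames: zero statistic, p = 1
  sel0 <- structure(list(peak_frames = 1:20, dip_frames = 1:20,
                         activation = rep(0, 200), n_shuffles = 100),
                    class = "peak_dip_selection")
  out0 <- component_contribution(sel0, comps, k_top = 3, n_clusters = 1)
  expect_true(all(out0$statistic == 0))
  expect_true(all(out0$p_value == 1))

  # unequal sets are trimmed with a message
  selu <- structure(list(peak_frames = 1:10, dip_frames = 11:25,
                         activation = rep(0, 200), n_shuffles = 100),
                    class = "peak_dip_selection")
  expect_message(outu <- component_contribution(selu, comps, k_top = 2,
                                                n_clusters = 1), "trimming")
  expect_true(all(outu$n_pairs == 10))
})
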