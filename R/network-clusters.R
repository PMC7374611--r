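# Affinity propagation by responsibility/availability message passing
# (Frey & Dueck). S: similarity matrix with preferences on the diagonal.
affinity_propagation <- function(S, damping = 0.9, max_iter = 1000,
                                 conv_iter = 50) {
  n <- nrow(S)
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  last <- rep(-1L, n)
  stable <- 0L
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    arg1 <- max.col(AS, ties.method = "first")
    max2 <- vapply(seq_len(n), function(i) {
      max(AS[i, -arg1[i]])
    }, numeric(1))
    Rmax <- matrix(max1, n, n)
    Rmax[cbind(seq_len(n), arg1)] <- max2
    Rnew <- S - Rmax
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    # convergence on the exemplar set
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last) && length(ex) > 0) stable <- stable + 1L else stable <- 0L
    last <- ex
    if (stable >= conv_iter) break
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  if (stable < conv_iter && it >= max_iter) {
    cond <- structure(class = c("semenc_ap_no_convergence", "error", "condition"),
                      list(message = "affinity propagation did not converge",
                           call = NULL, exemplars = ex, iterations = it))
    stop(cond)
  }
  assign <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign[ex] <- ex
  # refine exemplars: within each cluster take the point maximizing the
  # summed within-cluster similarity
  for (e in unique(assign)) {
    members <- which(assign == e)
    if (length(members) > 1) {
      sub <- S[members, members, drop = FALSE]
      diag(sub) <- 0
      best <- members[which.max(rowSums(sub))]
      assign[members] <- best
    }
  }
  list(assignment = assign, exemplars = sort(unique(assign)), iterations = it)
}

#' Cluster encoding weights by affinity propagation
#'
#' Groups electrodes by the similarity of their (fold-averaged) encoding
#' weight profiles: columns are z-scored over electrodes per component, the
#' affinity matrix is the pairwise Pearson correlation of the z-scored rows,
#' and affinity propagation with a shared preference of `min(A) - 2` returns
#' a cluster assignment and one exemplar electrode per cluster.
#'
#' @param betas electrodes x K weight matrix (typically the significant
#'   electrodes only).
#' @param preference_rule currently `"min_affinity_minus_2"`.
#' @param affinity currently `"pearson"`.
#' @param damping message damping in `[0.5, 1)` (default 0.9).
#' @param max_iter maximum message-passing iterations (default 1000).
#' @param seed seed for the symmetry-breaking jitter added to the affinities.
#' @param preference optional numeric override of the shared preference value
#'   (larger values give more clusters); by default `min(A) - 2`.
#' @return a `beta_clusters`: list with `assignment` (cluster id per
#'   electrode, ids are 1..n_clusters in exemplar order), `exemplar`
#'   (electrode row index per cluster), `affinity` (the jittered affinity
#'   matrix), `z_betas` and `iterations`.
#' @export
cluster_betas <- function(betas, preference_rule = "min_affinity_minus_2",
                          affinity = "pearson", damping = 0.9,
                          max_iter = 1000, seed = 1, preference = NULL) {
  preference_rule <- match.arg(preference_rule, "min_affinity_minus_2")
  affinity <- match.arg(affinity, "pearson")
  betas <- as.matrix(betas)
  n <- nrow(betas)
  if (n < 2) {
    return(structure(list(assignment = rep(1L, n), exemplar = if (n) 1L else integer(0),
                          affinity = matrix(0, n, n), z_betas = betas,
                          iterations = 0L),
                     class = "beta_clusters"))
  }
  # degenerate: all profiles identical
  if (max(abs(sweep(betas, 2, betas[1, ]))) < 1e-12) {
    return(structure(list(assignment = rep(1L, n), exemplar = 1L,
                          affinity = matrix(1, n, n), z_betas = betas * 0,
                          iterations = 0L),
                     class = "beta_clusters"))
  }
  sds <- apply(betas, 2, stats::sd)
  Z <- sweep(betas, 2, colMeans(betas))
  Z[, sds > 0] <- sweep(Z[, sds > 0, drop = FALSE], 2, sds[sds > 0], `/`)
  keep_cols <- sds > 0
  zchk <- Z[, keep_cols, drop = FALSE]
  stopifnot(max(abs(colMeans(zchk))) < 1e-8,
            max(abs(apply(zchk, 2, stats::sd) - 1)) < 1e-8)

  S <- suppressWarnings(stats::cor(t(Z)))
  if (anyNA(S)) stop("undefined affinities: constant weight profile present", call. = FALSE)
  jit <- with_seed(seed, matrix(stats::rnorm(n * n, sd = 1e-9), n, n))
  S <- S + (jit + t(jit)) / 2
  pref <- if (is.null(preference)) min(S[row(S) != col(S)]) - 2 else preference
  diag(S) <- pref

  ap <- affinity_propagation(S, damping = damping, max_iter = max_iter)
  ex <- ap$exemplars
  assignment <- match(ap$assignment, ex)
  structure(list(assignment = assignment, exemplar = ex, affinity = S,
                 z_betas = Z, iterations = ap$iterations),
            class = "beta_clusters")
}

#' @export
print.beta_clusters <- function(x, ...) {
  cat(sprintf("<beta_clusters> %d electrodes in %d clusters\n",
              length(x$assignment), length(x$exemplar)))
  invisible(x)
}

#' @rdname cluster_betas
#' @param x a `beta_clusters`.
#' @param ... unused.
#' @export
tidy.beta_clusters <- function(x, ...) {
  tibble::tibble(electrode = seq_along(x$assignment), cluster = x$assignment,
                 is_exemplar = seq_along(x$assignment) %in% x$exemplar)
}

#' Discard subject-specific clusters
#'
#' Retains a cluster only if it spans at least `min_subject_fraction` of all
#' subjects and no single subject contributes more than
#' `max_single_subject_fraction` of its electrodes (boundary shares are
#' retained).
#'
#' @param clusters a `beta_clusters`.
#' @param geometry `electrode_geometry` rows for the clustered electrodes, in
#'   the same order as the rows that were clustered.
#' @param min_subject_fraction minimum fraction of all subjects represented
#'   (default 1/3; the threshold is `ceiling(fraction * n_subjects)`).
#' @param max_single_subject_fraction maximum share of one subject
#'   (default 1/3, inclusive).
#' @return tibble `cluster`, `n_electrodes`, `n_subjects`,
#'   `max_subject_share`, `retained`, `reason`.
#' @export
filter_clusters <- function(clusters, geometry,
                            min_subject_fraction = 1 / 3,
                            max_single_subject_fraction = 1 / 3) {
  stopifnot(inherits(clusters, "beta_clusters"))
  subj <- geometry$subject
  stopifnot(length(subj) == length(clusters$assignment), !anyNA(subj))
  n_subjects_total <- length(unique(subj))
  need <- ceiling(min_subject_fraction * n_subjects_total)
  rows <- lapply(sort(unique(clusters$assignment)), function(cl) {
    members <- which(clusters$assignment == cl)
    tab <- table(subj[members])
    share <- max(tab) / length(members)
    ok_span <- length(tab) >= need
    ok_share <- share <= max_single_subject_fraction + 1e-12
    tibble::tibble(cluster = cl, n_electrodes = length(members),
                   n_subjects = length(tab), max_subject_share = share,
                   retained = ok_span && ok_share,
                   reason = dplyr::case_when(
                     ok_span && ok_share ~ "",
                     !ok_span ~ sprintf("spans %d < %d subjects", length(tab), need),
                     TRUE ~ sprintf("one subject holds %.0f%%", 100 * share)))
  })
  dplyr::bind_rows(rows)
}

#' Cluster activation time course from the exemplar weights
#'
#' The activation of a cluster at frame `t` is the dot product between the
#' component scores at `t` and the exemplar electrode's weights; the
#' uncertainty band is the standard error over member electrodes of the
#' member-wise dot products.
#'
#' @param components a `semantic_components`.
#' @param exemplar_betas length-K weight vector of the exemplar.
#' @param member_betas members x K weight matrix (including the exemplar).
#' @return list with `activation` (length n_frames) and `sem_band` (standard
#'   error per frame; zero for single-member clusters).
#' @export
activation_time_course <- function(components, exemplar_betas, member_betas) {
  stopifnot(inherits(components, "semantic_components"))
  S <- components$scores
  member_betas <- matrix(member_betas, ncol = ncol(S))
  stopifnot(length(exemplar_betas) == ncol(S))
  activation <- as.numeric(S %*% exemplar_betas)
  m <- nrow(member_betas)
  if (m > 1) {
    proj <- S %*% t(member_betas)            # frames x members
    sem_band <- apply(proj, 1, stats::sd) / sqrt(m)
  } else {
    sem_band <- numeric(nrow(S))
  }
  list(activation = activation, sem_band = sem_band)
}

#' Permutation null for activation peaks and dips
#'
#' Builds a baseline distribution of activation values by shuffling the
#' cluster assignment over electrodes `n_shuffles` times, recomputing the
#' target cluster's exemplar (the member maximizing summed within-cluster
#' affinity) and its activation time course each time, and pooling the
#' resulting values. Frames above the 97.5th percentile of the pooled
#' baseline are peak candidates, frames below the 2.5th are dip candidates;
#' the final sets are the top/bottom `fraction` of candidates by activation
#' value.
#'
#' @param clusters a `beta_clusters` over the significant electrodes.
#' @param cluster_id the cluster to test.
#' @param all_betas the electrodes x K matrix that was clustered.
#' @param components a `semantic_components`.
#' @param n_shuffles number of assignment shuffles (default 10000).
#' @param fraction fraction of candidates kept per tail (default 0.10).
#' @param probs baseline percentiles (default `c(0.025, 0.975)`).
#' @param seed integer seed.
#' @return a `peak_dip_selection`: list with `peak_frames` and `dip_frames`
#'   (ordered by decreasing |activation|), `upper_threshold`,
#'   `lower_threshold`, `activation`, `n_shuffles`.
#' @export
peak_dip_null <- function(clusters, cluster_id, all_betas, components,
                          n_shuffles = 10000, fraction = 0.10,
                          probs = c(0.025, 0.975), seed = 1) {
  stopifnot(inherits(clusters, "beta_clusters"))
  n_shuffles <- check_count(n_shuffles, "n_shuffles", min = 100L)
  assignment <- clusters$assignment
  S <- clusters$affinity
  all_betas <- as.matrix(all_betas)
  n <- length(assignment)

  pick_exemplar <- function(members) {
    if (length(members) == 1) return(members)
    sub <- S[members, members, drop = FALSE]
    diag(sub) <- 0
    members[which.max(rowSums(sub))]
  }

  members0 <- which(assignment == cluster_id)
  ex0 <- pick_exemplar(members0)
  act <- activation_time_course(components, all_betas[ex0, ],
                                all_betas[members0, , drop = FALSE])

  # activation of every electrode's weight vector, cached: a shuffle only
  # changes which electrode becomes the exemplar
  act_all <- components$scores %*% t(all_betas)   # frames x electrodes

  baseline_ex <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- sample.int(n)
      pick_exemplar(which(assignment[perm] == cluster_id))
    }, integer(1))
  })
  thresholds <- stats::quantile(act_all[, baseline_ex], probs = probs,
                                names = FALSE)
  lower <- thresholds[1]; upper <- thresholds[2]

  peak_cand <- which(act$activation > upper)
  dip_cand <- which(act$activation < lower)
  n_peak <- ceiling(fraction * length(peak_cand))
  n_dip <- ceiling(fraction * length(dip_cand))
  peak_frames <- peak_cand[order(-act$activation[peak_cand])][seq_len(n_peak)]
  dip_frames <- dip_cand[order(act$activation[dip_cand])][seq_len(n_dip)]
  if (length(peak_cand) == 0 || length(dip_cand) == 0) {
    warning("no frames beyond the baseline thresholds; empty peak/dip set")
  }
  structure(list(peak_frames = as.integer(peak_frames),
                 dip_frames = as.integer(dip_frames),
                 upper_threshold = upper, lower_threshold = lower,
                 activation = act$activation, sem_band = act$sem_band,
                 n_shuffles = n_shuffles, cluster_id = cluster_id),
            class = "peak_dip_selection")
}

#' Per-component contribution of peaks versus dips
#'
#' For each of the top `k_top` components, compares the component values at
#' peak frames against dip frames with a paired two-sided Wilcoxon
#' signed-rank test (pairs formed by descending |activation| rank, trimmed to
#' the smaller set). P values are Bonferroni-corrected by
#' `n_clusters * k_top`; the statistic is additionally reported divided by
#' the component's explained-variance percentage, which normalizes the
#' shrinking score range of later components (reported alongside, never used
#' for the significance decision).
#'
#' @param selection a `peak_dip_selection`.
#' @param components a `semantic_components`.
#' @param k_top number of leading components (default 5).
#' @param alpha corrected significance level (default 0.001).
#' @param n_clusters total clusters tested (Bonferroni factor).
#' @return tibble `component`, `statistic` (signed-rank z), `p_value`
#'   (corrected), `significant`, `adjusted_statistic`, `n_pairs`.
#' @export
component_contribution <- function(selection, components, k_top = 5,
                                   alpha = 0.001, n_clusters = 1) {
  stopifnot(inherits(selection, "peak_dip_selection"),
            inherits(components, "semantic_components"))
  k_top <- min(check_count(k_top, "k_top"), ncol(components$scores))
  np <- length(selection$peak_frames)
  nd <- length(selection$dip_frames)
  m <- min(np, nd)
  if (np != nd) {
    message(sprintf("trimming peak/dip sets from (%d, %d) to %d pairs", np, nd, m))
  }
  peaks <- selection$peak_frames[seq_len(m)]
  dips <- selection$dip_frames[seq_len(m)]
  evr_pct <- components$explained_variance_ratio * 100
  rows <- lapply(seq_len(k_top), function(k) {
    if (m == 0) {
      return(tibble::tibble(component = k, statistic = NA_real_, p_value = NA_real_,
                            significant = FALSE, adjusted_statistic = NA_real_,
                            n_pairs = 0L))
    }
    ww <- signed_rank_z(components$scores[peaks, k],
                        components$scores[dips, k], "two.sided")
    p_corr <- min(1, ww$p * n_clusters * k_top)
    tibble::tibble(component = k, statistic = ww$z, p_value = p_corr,
                   significant = p_corr < alpha,
                   adjusted_statistic = ww$z / evr_pct[k], n_pairs = m)
  })
  dplyr::bind_rows(rows)
}
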