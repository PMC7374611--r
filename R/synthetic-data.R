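#' Generate a topic-structured embedding lexicon
#'
#' Emulates a pretrained word-embedding vocabulary: every concept label gets a
#' `dim`-dimensional vector drawn around one of `n_topics` unit-norm topic
#' centroids, so labels from the same topic are closer (in cosine similarity)
#' than labels from different topics. The topic assignment is retained as
#' ground truth for recovery tests; real embedding lexica carry no such map.
#'
#' @param n_labels number of concept labels (default 129, a small curated
#'   film vocabulary).
#' @param n_topics number of semantic topics the labels cluster into.
#' @param dim embedding dimensionality (default 300).
#' @param spread standard deviation of the isotropic noise around each topic
#'   centroid; smaller values give tighter topics.
#' @param seed integer seed; identical arguments give identical output.
#' @return an `embedding_lexicon`: list with `labels` (character),
#'   `vectors` (`n_labels` x `dim` matrix, rownames = labels) and `topic_of`
#'   (named integer vector).
#' @export
generate_lexicon <- function(n_labels = 129, n_topics = 8, dim = 300,
                             spread = 0.35, seed = 1) {
  n_labels <- check_count(n_labels, "n_labels")
  n_topics <- check_count(n_topics, "n_topics")
  dim <- check_count(dim, "dim", min = 2L)
  if (n_topics > n_labels) stop("`n_topics` must not exceed `n_labels`", call. = FALSE)
  if (!is.numeric(spread) || spread <= 0) stop("`spread` must be > 0", call. = FALSE)

  with_seed(seed, {
    centroids <- matrix(stats::rnorm(n_topics * dim), n_topics, dim)
    centroids <- centroids / sqrt(rowSums(centroids^2))
    topic_of <- rep_len(seq_len(n_topics), n_labels)
    vectors <- centroids[topic_of, , drop = FALSE] +
      matrix(stats::rnorm(n_labels * dim, sd = spread / sqrt(dim)), n_labels, dim)
    labels <- sprintf("label%03d", seq_len(n_labels))
    rownames(vectors) <- labels
    names(topic_of) <- labels
    structure(list(labels = labels, vectors = vectors, topic_of = topic_of),
              class = "embedding_lexicon")
  })
}

#' @export
print.embedding_lexicon <- function(x, ...) {
  cat(sprintf("<embedding_lexicon> %d labels x %d dims, %d topics\n",
              length(x$labels), ncol(x$vectors), length(unique(x$topic_of))))
  invisible(x)
}

#' Generate a block-design film stimulus with persistent scenes
#'
#' Builds a frame-by-frame concept-label table plus the two stimulus confounds
#' of a clinical film task: a strictly alternating speech/music block design
#' and a smoothed, rectified audio envelope whose mean differs by block type.
#' Scene structure is a first-order Markov chain over topics: the active topic
#' persists from one frame to the next with probability `scene_persistence`,
#' which induces temporal autocorrelation in the frame-averaged embeddings.
#' Labels are drawn per frame without replacement, weighted toward the active
#' topic; label probabilities are Uniform(0.85, 1) so a 90% probability filter
#' retains most but not all entries.
#'
#' @param lexicon an [generate_lexicon()] result.
#' @param n_blocks number of alternating blocks (default 13).
#' @param block_seconds block duration in seconds (default 30).
#' @param frame_rate frames per second (default 25).
#' @param labels_per_frame labels assigned to each frame (default 20).
#' @param scene_persistence probability in `[0, 1)` that the scene topic
#'   carries over to the next frame (default 0.96, about one second of median
#'   persistence at 25 fps).
#' @param topic_weight sampling weight of active-topic labels relative to
#'   out-of-topic labels.
#' @param seed integer seed.
#' @return list with `labels` (a `frame_label_table` tibble: `frame`, `label`,
#'   `probability`, plus `n_frames`/`frame_rate` attributes) and `confounds`
#'   (a `stimulus_confounds` tibble: `frame`, `block` (+1 speech / -1 music),
#'   `block_id`, `envelope`).
#' @export
generate_stimulus <- function(lexicon, n_blocks = 13, block_seconds = 30,
                              frame_rate = 25, labels_per_frame = 20,
                              scene_persistence = 0.96, topic_weight = 12,
                              seed = 1) {
  stopifnot(inherits(lexicon, "embedding_lexicon"))
  n_blocks <- check_count(n_blocks, "n_blocks")
  labels_per_frame <- check_count(labels_per_frame, "labels_per_frame")
  if (frame_rate <= 0) stop("`frame_rate` must be > 0", call. = FALSE)
  check_prob(scene_persistence, "scene_persistence")
  if (scene_persistence >= 1) stop("`scene_persistence` must be < 1", call. = FALSE)
  n_labels <- length(lexicon$labels)
  if (labels_per_frame > n_labels) {
    stop("`labels_per_frame` exceeds the lexicon size", call. = FALSE)
  }

  frames_per_block <- round(block_seconds * frame_rate)
  n_frames <- n_blocks * frames_per_block
  n_topics <- max(lexicon$topic_of)

  with_seed(seed, {
    # scene topic chain
    topic <- integer(n_frames)
    topic[1] <- sample.int(n_topics, 1)
    keep <- stats::runif(n_frames) < scene_persistence
    for (t in seq_len(n_frames)[-1]) {
      topic[t] <- if (keep[t]) topic[t - 1] else sample.int(n_topics, 1)
    }

    # weighted sampling without replacement per frame via the Gumbel top-k
    # (exponential race) construction, vectorized over frames
    W <- matrix(1, n_topics, n_labels)
    for (tp in seq_len(n_topics)) W[tp, lexicon$topic_of == tp] <- topic_weight
    logw <- log(W)[topic, , drop = FALSE]
    keys <- logw - log(-log(matrix(stats::runif(n_frames * n_labels),
                                   n_frames, n_labels)))
    lab_idx <- t(apply(keys, 1, function(k) {
      order(k, decreasing = TRUE)[seq_len(labels_per_frame)]
    }))
    probs <- matrix(stats::runif(n_frames * labels_per_frame, 0.85, 1),
                    n_frames, labels_per_frame)

    labels_tbl <- tibble::tibble(
      frame = rep(seq_len(n_frames), each = labels_per_frame),
      label = lexicon$labels[as.vector(t(lab_idx))],
      probability = as.vector(t(probs))
    )
    attr(labels_tbl, "n_frames") <- n_frames
    attr(labels_tbl, "frame_rate") <- frame_rate
    attr(labels_tbl, "scene_topic") <- topic
    class(labels_tbl) <- c("frame_label_table", class(labels_tbl))

    # block design: +1 speech / -1 music, strictly alternating
    block_id <- rep(seq_len(n_blocks), each = frames_per_block)
    block <- ifelse(block_id %% 2 == 1, 1, -1)

    # audio envelope: rectified smoothed Gaussian process, block-dependent mean
    kern_w <- max(3L, round(frame_rate / 2))
    kern <- stats::dnorm(seq(-3, 3, length.out = kern_w))
    kern <- kern / sum(kern)
    raw <- stats::rnorm(n_frames + 2 * kern_w)
    sm <- stats::filter(raw, kern, sides = 2)
    sm <- as.numeric(sm[(kern_w + 1):(kern_w + n_frames)])
    mu <- ifelse(block > 0, 1.0, 0.6)
    envelope <- pmax(mu + sm / stats::sd(sm) * 0.3, 0)

    confounds <- tibble::tibble(frame = seq_len(n_frames), block = block,
                                block_id = block_id, envelope = envelope)
    attr(confounds, "frame_rate") <- frame_rate
    attr(confounds, "block_seconds") <- block_seconds
    class(confounds) <- c("stimulus_confounds", class(confounds))

    list(labels = labels_tbl, confounds = confounds)
  })
}

#' Generate subdural-grid-like electrode geometry on the unit sphere
#'
#' Places one contiguous rectangular patch of electrodes per subject on the
#' unit sphere, mimicking subdural grids projected to an average spherical
#' surface. Coordinates are unit vectors.
#'
#' @param n_subjects number of subjects.
#' @param electrodes_per_subject electrodes per subject's patch.
#' @param patch_spacing angular spacing between neighbouring electrodes
#'   (radians).
#' @param seed integer seed.
#' @return an `electrode_geometry` tibble: `electrode`, `subject`, `x`, `y`,
#'   `z`, `anat`.
#' @export
generate_geometry <- function(n_subjects = 10, electrodes_per_subject = 6,
                              patch_spacing = 0.06, seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  electrodes_per_subject <- check_count(electrodes_per_subject, "electrodes_per_subject")
  anat_pool <- c("fusiform", "supramarginal", "precentral", "mtg", "stg",
                 "latocc", "ifg", "spg")
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_subjects), function(s) {
      c0 <- stats::rnorm(3)
      c0 <- c0 / sqrt(sum(c0^2))
      # tangent basis
      u <- c(-c0[2], c0[1], 0)
      if (sum(u^2) < 1e-8) u <- c(1, 0, 0)
      u <- u / sqrt(sum(u^2))
      v <- c(c0[2] * u[3] - c0[3] * u[2],
             c0[3] * u[1] - c0[1] * u[3],
             c0[1] * u[2] - c0[2] * u[1])
      side <- ceiling(sqrt(electrodes_per_subject))
      g <- expand.grid(a = seq_len(side), b = seq_len(side))[seq_len(electrodes_per_subject), ]
      pts <- t(apply(g, 1, function(ab) {
        p <- c0 + patch_spacing * ((ab[1] - (side + 1) / 2) * u +
                                     (ab[2] - (side + 1) / 2) * v)
        p / sqrt(sum(p^2))
      }))
      tibble::tibble(subject = sprintf("S%02d", s),
                     x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     anat = sample(anat_pool, electrodes_per_subject, replace = TRUE))
    })
    geom <- dplyr::bind_rows(rows)
    geom <- tibble::add_column(geom, electrode = seq_len(nrow(geom)), .before = 1)
    class(geom) <- c("electrode_geometry", class(geom))
    geom
  })
}

#' Render procedural frame images from label sets
#'
#' Produces a toy RGB image per frame by averaging label-keyed procedural
#' textures (oriented sinusoidal gratings with label-specific frequency,
#' orientation, phase and colour). Frames sharing labels are therefore more
#' pixel-correlated than frames sharing none, which is all the low-level
#' control features downstream require. Rendering is deterministic in
#' (labels, seed).
#'
#' @param table a `frame_label_table`.
#' @param lexicon the matching `embedding_lexicon`.
#' @param height,width image size in pixels (>= 16).
#' @param seed integer seed keying the label textures.
#' @return a `frame_image_stack`: array `(n_frames, height, width, 3)` with
#'   values in `[0, 1]`.
#' @export
render_frames <- function(table, lexicon, height = 32, width = 32, seed = 1) {
  stopifnot(inherits(table, "frame_label_table"))
  if (height < 16 || width < 16) stop("`height` and `width` must be >= 16", call. = FALSE)
  n_frames <- attr(table, "n_frames")
  n_labels <- length(lexicon$labels)
  npix <- height * width

  yy <- matrix(rep(seq_len(height), width), height, width) / height
  xx <- matrix(rep(seq_len(width), each = height), height, width) / width

  textures <- with_seed(seed, {
    tx <- matrix(0, n_labels, npix * 3)
    for (i in seq_len(n_labels)) {
      f <- stats::runif(1, 2, 8)
      th <- stats::runif(1, 0, pi)
      ph <- stats::runif(1, 0, 2 * pi)
      colw <- stats::runif(3, 0.2, 1)
      g <- 0.5 + 0.5 * sin(2 * pi * f * (cos(th) * xx + sin(th) * yy) + ph)
      tx[i, ] <- as.vector(outer(as.vector(g), colw))
    }
    rownames(tx) <- lexicon$labels
    tx
  })

  frames_list <- split(match(table$label, lexicon$labels), table$frame)
  img <- matrix(0, n_frames, npix * 3)
  for (f in seq_len(n_frames)) {
    idx <- frames_list[[as.character(f)]]
    if (!is.null(idx) && length(idx)) {
      idx <- unique(idx)
      img[f, ] <- colMeans(textures[idx, , drop = FALSE])
    }
  }
  img <- pmin(pmax(img, 0), 1)
  out <- array(img, dim = c(n_frames, height, width, 3))
  class(out) <- c("frame_image_stack", class(out))
  out
}

#' Generate HFB responses with planted encoding structure
#'
#' Simulates the high-frequency-band amplitude of every electrode as a lagged
#' linear readout of the semantic component scores plus block-design and
#' audio-envelope confounds plus AR(1) Gaussian noise:
#' `hfb(e, t) = sum_k beta(e, k) comp(k, t - lag) + g_blk(e) block(t) +
#' g_env(e) envelope(t) + noise(e, t)`.
#' Non-null electrodes draw their weight vector from a small set of
#' orthogonalized cluster prototypes concentrated on the top five components,
#' with per-electrode jitter; a `frac_null` fraction of electrodes has all-zero
#' semantic weights. Noise variance is scaled per electrode so the
#' semantic-signal-to-noise variance ratio equals `snr`.
#'
#' @param components a `semantic_components` object ([fit_components()]).
#' @param confounds a `stimulus_confounds` tibble.
#' @param geometry an `electrode_geometry` tibble.
#' @param lag_true planted stimulus-to-response lag in seconds; must be an
#'   integer number of frames (default 0.32 s = 8 frames at 25 fps).
#' @param snr semantic signal variance / noise variance (> 0).
#' @param frac_null fraction of electrodes with zero semantic weights.
#' @param ar1 lag-one coefficient of the AR(1) noise, `|ar1| < 1`.
#' @param confound_gain scale of the block/envelope gains relative to the
#'   per-electrode signal standard deviation; 0 disables confounds.
#' @param n_prototypes number of planted cluster prototypes (4-6 sensible).
#' @param proto_jitter total jitter norm around a prototype relative to the
#'   unit prototype norm.
#' @param proto_tail total norm of the weak structured prototype weights on
#'   the components beyond the top five (profiles are concentrated on, not
#'   confined to, the leading components).
#' @param seed integer seed.
#' @return list with `recording` (a `neural_recording`: `hfb` electrodes x
#'   frames matrix, `frame_rate`, `geometry`) and `truth` (a `ground_truth`:
#'   `beta_true` (raw score units), `beta_std_true` (standardized units, the
#'   scale prototypes are planted on), `lag_true`, `g_block`, `g_env`,
#'   `null_electrodes`, `cluster_true`, `snr`).
#' @export
generate_neural <- function(components, confounds, geometry,
                            lag_true = 0.32, snr = 1, frac_null = 1 / 3,
                            ar1 = 0.6, confound_gain = 1,
                            n_prototypes = 5, proto_jitter = 0.2,
                            proto_tail = 0.4, seed = 1) {
  stopifnot(inherits(components, "semantic_components"),
            inherits(confounds, "stimulus_confounds"))
  if (snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  if (abs(ar1) >= 1) stop("`ar1` must satisfy |ar1| < 1", call. = FALSE)
  check_prob(frac_null, "frac_null")
  frame_rate <- attr(confounds, "frame_rate")
  n_frames <- nrow(confounds)
  lag_frames <- seconds_to_frames(lag_true, frame_rate, "lag_true")
  if (abs(lag_frames) >= n_frames) {
    stop("`lag_true` lies outside the stimulus duration", call. = FALSE)
  }
  scores <- components$scores
  if (nrow(scores) != n_frames) {
    stop("components and confounds disagree on the number of frames", call. = FALSE)
  }
  K <- ncol(scores)
  E <- nrow(geometry)

  with_seed(seed, {
    n_null <- round(frac_null * E)
    null_idx <- if (n_null > 0) sort(sample.int(E, n_null)) else integer(0)

    # prototypes concentrated on the top-5 components (orthonormal there),
    # with a weak structured tail over the remaining components: encoding
    # profiles are never exactly zero off their preferred axes, and the
    # per-component z-scoring of the clustering stage would otherwise
    # amplify pure jitter noise in the unused columns
    top <- min(5L, K)
    Q <- qr.Q(qr(matrix(stats::rnorm(top * top), top, top)))[seq_len(min(n_prototypes, top)), , drop = FALSE]
    if (n_prototypes > nrow(Q)) Q <- Q[rep_len(seq_len(nrow(Q)), n_prototypes), , drop = FALSE]
    proto <- matrix(0, n_prototypes, K)
    proto[, seq_len(top)] <- Q
    if (K > top) {
      proto[, (top + 1):K] <- matrix(
        stats::rnorm(n_prototypes * (K - top), sd = proto_tail / sqrt(K - top)),
        n_prototypes, K - top)
    }

    # prototypes and jitter live on the standardized-feature scale (one unit
    # of weight = one standard deviation of a component's score), so every
    # planted component contribution is both interpretable and estimable;
    # raw-scale weights follow by dividing by the score standard deviations
    sdx <- apply(scores, 2, stats::sd)
    sdx_safe <- ifelse(sdx > 0, sdx, Inf)
    cluster_true <- rep(NA_integer_, E)
    beta_std_true <- matrix(0, E, K)
    signal_idx <- setdiff(seq_len(E), null_idx)
    if (length(signal_idx)) {
      cluster_true[signal_idx] <- rep_len(seq_len(n_prototypes), length(signal_idx))
      jit_sd <- proto_jitter / sqrt(K)
      beta_std_true[signal_idx, ] <- proto[cluster_true[signal_idx], , drop = FALSE] +
        matrix(stats::rnorm(length(signal_idx) * K, sd = jit_sd), length(signal_idx), K)
    }
    beta_true <- sweep(beta_std_true, 2, sdx_safe, `/`)

    lagged <- shift_frames(scores, lag_frames)
    signal <- lagged %*% t(beta_true)            # frames x electrodes
    sig_var <- apply(signal, 2, stats::var)
    ref_var <- if (length(signal_idx)) mean(sig_var[signal_idx]) else 1
    noise_var <- ifelse(seq_len(E) %in% signal_idx, sig_var, ref_var) / snr
    sd_ref <- sqrt(ifelse(seq_len(E) %in% signal_idx, sig_var, ref_var))

    g_block <- confound_gain * sd_ref * stats::rnorm(E)
    g_env <- confound_gain * sd_ref * stats::rnorm(E)

    innov_sd <- sqrt(noise_var * (1 - ar1^2))
    noise <- vapply(seq_len(E), function(e) {
      if (innov_sd[e] == 0) return(numeric(n_frames))
      as.numeric(stats::arima.sim(list(ar = ar1), n_frames,
                                  innov = stats::rnorm(n_frames, sd = innov_sd[e])))
    }, numeric(n_frames))

    hfb_tx <- signal +
      outer(confounds$block, g_block) +
      outer(confounds$envelope, g_env) +
      noise
    hfb <- t(hfb_tx)
    rownames(hfb) <- geometry$electrode

    recording <- structure(list(hfb = hfb, frame_rate = frame_rate,
                                geometry = geometry),
                           class = "neural_recording")
    truth <- structure(list(beta_true = beta_true,
                            beta_std_true = beta_std_true,
                            lag_true = lag_true,
                            lag_frames = lag_frames, g_block = g_block,
                            g_env = g_env, null_electrodes = null_idx,
                            cluster_true = cluster_true, snr = snr),
                       class = "ground_truth")
    list(recording = recording, truth = truth)
  })
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf("<neural_recording> %d electrodes x %d frames at %g Hz\n",
              nrow(x$hfb), ncol(x$hfb), x$frame_rate))
  invisible(x)
}

#' Simulate a complete film-watching study
#'
#' Convenience wrapper chaining the synthetic generators and the stimulus-side
#' feature pipeline: lexicon, stimulus, probability filter, frame embedding,
#' PCA components, electrode geometry and planted neural responses. Defaults
#' reproduce the study conditions (129 labels, 20 labels/frame, 13 x 30 s
#' alternating blocks at 25 fps, 50 components, 320 ms planted lag).
#'
#' @param seed integer seed driving every stage.
#' @param n_labels,n_topics,dim,spread lexicon parameters.
#' @param n_blocks,block_seconds,frame_rate,labels_per_frame,scene_persistence
#'   stimulus parameters.
#' @param min_probability label probability filter threshold.
#' @param n_components number of semantic components.
#' @param n_subjects,electrodes_per_subject geometry parameters.
#' @param lag_true,snr,frac_null,ar1,confound_gain neural parameters.
#' @return list with `lexicon`, `stimulus`, `labels_filtered`, `embeddings`,
#'   `components`, `geometry`, `recording`, `truth`.
#' @export
simulate_study <- function(seed = 1, n_labels = 129, n_topics = 8, dim = 300,
                           spread = 0.35, n_blocks = 13, block_seconds = 30,
                           frame_rate = 25, labels_per_frame = 20,
                           scene_persistence = 0.96, min_probability = 0.9,
                           n_components = 50, n_subjects = 10,
                           electrodes_per_subject = 6, lag_true = 0.32,
                           snr = 1, frac_null = 1 / 3, ar1 = 0.6,
                           confound_gain = 1) {
  lex <- generate_lexicon(n_labels, n_topics, dim, spread, seed = child_seed(seed, 1))
  stim <- generate_stimulus(lex, n_blocks, block_seconds, frame_rate,
                            labels_per_frame, scene_persistence,
                            seed = child_seed(seed, 2))
  flt <- filter_labels(stim$labels, min_probability, lex$labels)
  emb <- embed_frames(flt, lex)
  comps <- fit_components(emb, n_components)
  geom <- generate_geometry(n_subjects, electrodes_per_subject,
                            seed = child_seed(seed, 3))
  neural <- generate_neural(comps, stim$confounds, geom, lag_true, snr,
                            frac_null, ar1, confound_gain,
                            seed = child_seed(seed, 4))
  list(lexicon = lex, stimulus = stim, labels_filtered = flt, embeddings = emb,
       components = comps, geometry = geom, recording = neural$recording,
       truth = neural$truth)
}
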