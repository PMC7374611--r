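#' Read and write embedding lexica in word2vec text format
#'
#' The text format has a `"<n> <dim>"` header line followed by one
#' `label v1 ... vD` line per label.
#'
#' @param lexicon an `embedding_lexicon`.
#' @param path file path.
#' @return `read_lexicon` returns an `embedding_lexicon` (without topic
#'   ground truth); `write_lexicon` returns `path` invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(lexicon$labels), ncol(lexicon$vectors)), con)
  for (i in seq_along(lexicon$labels)) {
    writeLines(paste(lexicon$labels[i],
                     paste(sprintf("%.8g", lexicon$vectors[i, ]),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  n <- hdr[1]; d <- hdr[2]
  parts <- lapply(strsplit(lines[1 + seq_len(n)], " "), function(p) p[nzchar(p)])
  labels <- vapply(parts, `[[`, character(1), 1)
  vectors <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(vectors) <- labels
  structure(list(labels = labels, vectors = vectors,
                 topic_of = stats::setNames(rep(NA_integer_, n), labels)),
            class = "embedding_lexicon")
}

#' Read and write frame label tables as TSV
#'
#' Columns `frame`, `label`, `probability`, tab-separated with a header.
#'
#' @param table a `frame_label_table`.
#' @param path file path.
#' @param frame_rate frame rate to attach on read (default 25).
#' @param n_frames total frame count on read; defaults to the maximum frame
#'   index present.
#' @return `read_frame_labels` returns a `frame_label_table`.
#' @export
write_frame_labels <- function(table, path) {
  utils::write.table(as.data.frame(table)[c("frame", "label", "probability")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_labels
#' @export
read_frame_labels <- function(path, frame_rate = 25, n_frames = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "numeric"))
  out <- tibble::as_tibble(df)
  attr(out, "n_frames") <- if (is.null(n_frames)) max(out$frame) else n_frames
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("frame_label_table", class(out))
  out
}

#' Write semantic components as TSV plus a JSON sidecar
#'
#' Writes `scores.tsv` (frames x K), `loadings.tsv` (D x K) and
#' `components.json` (explained-variance ratios, centering mean, excluded
#' frames and the sign convention) into `dir`.
#'
#' @param components a `semantic_components`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_components <- function(components, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(components$scores, file.path(dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(components$loadings, file.path(dir, "loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(explained_variance_ratio = components$explained_variance_ratio,
         mean = components$mean,
         excluded_frames = components$excluded_frames,
         frame_rate = components$frame_rate,
         sign_convention = "largest-magnitude loading coefficient positive"),
    file.path(dir, "components.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_components
#' @export
read_components <- function(dir) {
  scores <- as.matrix(utils::read.table(file.path(dir, "scores.tsv"),
                                        sep = "\t", header = TRUE))
  loadings <- as.matrix(utils::read.table(file.path(dir, "loadings.tsv"),
                                          sep = "\t", header = TRUE))
  meta <- jsonlite::read_json(file.path(dir, "components.json"),
                              simplifyVector = TRUE)
  structure(list(scores = scores, loadings = loadings, mean = meta$mean,
                 explained_variance_ratio = meta$explained_variance_ratio,
                 excluded_frames = as.integer(meta$excluded_frames),
                 frame_rate = meta$frame_rate),
            class = "semantic_components")
}

#' Write and read a neural recording as a TSV directory layout
#'
#' `hfb.tsv` holds the electrodes x frames matrix; `electrodes.tsv` the
#' geometry table (subject, anatomical label, x, y, z); `stimulus.tsv` the
#' confounds, when given.
#'
#' @param recording a `neural_recording`.
#' @param dir output directory.
#' @param confounds optional `stimulus_confounds` to store alongside.
#' @return `dir` / a list with `recording` and `confounds`.
#' @export
write_recording <- function(recording, dir, confounds = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(recording$hfb, file.path(dir, "hfb.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(recording$geometry)) {
    utils::write.table(as.data.frame(recording$geometry),
                       file.path(dir, "electrodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cat(sprintf("frame_rate\t%g\n", recording$frame_rate),
      file = file.path(dir, "meta.tsv"))
  if (!is.null(confounds)) {
    utils::write.table(as.data.frame(confounds), file.path(dir, "stimulus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  hfb <- as.matrix(utils::read.table(file.path(dir, "hfb.tsv"), sep = "\t"))
  dimnames(hfb) <- NULL
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            row.names = 1)
  geometry <- NULL
  gp <- file.path(dir, "electrodes.tsv")
  if (file.exists(gp)) {
    geometry <- tibble::as_tibble(utils::read.table(gp, sep = "\t", header = TRUE))
    class(geometry) <- c("electrode_geometry", class(geometry))
  }
  confounds <- NULL
  sp <- file.path(dir, "stimulus.tsv")
  if (file.exists(sp)) {
    confounds <- tibble::as_tibble(utils::read.table(sp, sep = "\t", header = TRUE))
    attr(confounds, "frame_rate") <- meta["frame_rate", 1]
    class(confounds) <- c("stimulus_confounds", class(confounds))
  }
  rec <- structure(list(hfb = hfb, frame_rate = meta["frame_rate", 1],
                        geometry = geometry),
                   class = "neural_recording")
  list(recording = rec, confounds = confounds)
}
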