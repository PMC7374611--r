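#' Shift a series by an integer number of frames
#'
#' Moves values forward in time by `k` frames (positive `k` delays the series),
#' padding the vacated positions with zeros so the output has the same length.
#' This is the alignment primitive used both by the response generator (to
#' plant a stimulus-to-response lag) and by the encoding model (to evaluate a
#' candidate time shift), so the two sides share one convention:
#' `shift_frames(x, k)[t] == x[t - k]` for valid `t`.
#'
#' @param x numeric vector or matrix (time along rows for matrices).
#' @param k integer shift in frames; positive delays, negative advances.
#' @return object of the same shape as `x`.
#' @export
#' @examples
#' shift_frames(1:5, 2)
shift_frames <- function(x, k) {
  k <- as.integer(round(k))
  if (is.matrix(x)) {
    n <- nrow(x)
    out <- matrix(0, n, ncol(x), dimnames = dimnames(x))
    if (abs(k) < n) {
      if (k >= 0) out[(k + 1L):n, ] <- x[1L:(n - k), , drop = FALSE]
      else out[1L:(n + k), ] <- x[(1L - k):n, , drop = FALSE]
    }
    out
  } else {
    n <- length(x)
    out <- numeric(n)
    if (abs(k) < n) {
      if (k >= 0) out[(k + 1L):n] <- x[1L:(n - k)]
      else out[1L:(n + k)] <- x[(1L - k):n]
    }
    out
  }
}

# Convert a shift in seconds to an integer frame count, erroring if it is not
# (numerically) an integer multiple of the frame period.
seconds_to_frames <- function(seconds, frame_rate, what = "shift") {
  k <- seconds * frame_rate
  if (abs(k - round(k)) > 1e-6) {
    stop(sprintf("%s of %g s is not an integer multiple of the frame period (1/%g s)",
                 what, seconds, frame_rate), call. = FALSE)
  }
  as.integer(round(k))
}

# Fast column-wise Pearson correlation between two matrices with matched
# columns; returns one r per column. Zero-variance columns give NA.
col_cor <- function(a, b) {
  n <- nrow(a)
  am <- colMeans(a)
  bm <- colMeans(b)
  num <- colSums(a * b) - n * am * bm
  da <- colSums(a^2) - n * am^2
  db <- colSums(b^2) - n * bm^2
  den <- sqrt(pmax(da, 0) * pmax(db, 0))
  ifelse(den > 0, num / den, NA_real_)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483563) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
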