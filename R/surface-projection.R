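#' Great-circle distance between unit vectors on a sphere
#'
#' `d = r * arccos(u . v)` with the dot product clipped to `[-1, 1]`.
#' Vectorized over matrices: if `u` is `n x 3` and `v` is `m x 3` the result
#' is the `n x m` distance matrix.
#'
#' @param u,v unit vectors (length 3) or matrices of row unit vectors.
#' @param r sphere radius (default 1; use mm to keep distances in mm).
#' @return scalar or matrix of distances.
#' @export
great_circle_distance <- function(u, v, r = 1) {
  um <- if (is.matrix(u)) u else matrix(u, 1)
  vm <- if (is.matrix(v)) v else matrix(v, 1)
  nu <- sqrt(rowSums(um^2)); nv <- sqrt(rowSums(vm^2))
  if (any(nu < 1e-12) || any(nv < 1e-12)) stop("zero vector", call. = FALSE)
  um <- um / nu; vm <- vm / nv
  d <- r * acos(pmin(pmax(um %*% t(vm), -1), 1))
  if (!is.matrix(u) && !is.matrix(v)) d[1, 1] else d
}

#' Build a spherical grid by icosahedron subdivision
#'
#' Starts from the regular icosahedron, subdivides each triangular face
#' `order` times (each subdivision splits a triangle into four) and projects
#' vertices back to the sphere — the same family of uniform spherical grids
#' as the FreeSurfer `ico` meshes (order 5 has 10242 vertices).
#'
#' @param order subdivision order (>= 0; default 3 = 642 vertices).
#' @param radius sphere radius stored with the grid.
#' @return a `sphere_grid`: list with `points` (G x 3 unit vectors) and
#'   `radius`.
#' @export
icosphere_grid <- function(order = 3, radius = 100) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (o in seq_len(order)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  structure(list(points = v, radius = radius), class = "sphere_grid")
}

#' Gaussian-process projection of electrode values onto a spherical grid
#'
#' Smooths per-electrode scalar values onto a regular grid on the sphere
#' with the kernel interpolator
#' `g = Kc' (Ks + eta I)^{-1} y`, where
#' `Ks = exp(-Ds^2 / (2 sigma^2))` over electrode-electrode great-circle
#' distances and `Kc = exp(-Dc^2 / (2 sigma^2))` over electrode-grid
#' distances. The map is linear in `y`; as `eta -> 0` it interpolates the
#' electrode values exactly at electrode-coincident grid points.
#'
#' @param values per-electrode scalars (length E).
#' @param electrodes E x 3 unit-vector electrode coordinates.
#' @param grid a `sphere_grid` (or G x 3 matrix of unit vectors).
#' @param sigma smoothing length in the same units as the distances
#'   (default 8, matching an 8 mm smoothing scale on a radius-in-mm sphere).
#' @param eta non-negative noise parameter (default 1e-3).
#' @return numeric vector of length G.
#' @export
gp_project <- function(values, electrodes, grid, sigma = 8, eta = 1e-3) {
  pts <- if (inherits(grid, "sphere_grid")) grid$points else as.matrix(grid)
  radius <- if (inherits(grid, "sphere_grid")) grid$radius else 1
  electrodes <- if (is.matrix(electrodes)) electrodes else matrix(electrodes, 1)
  stopifnot(length(values) == nrow(electrodes), sigma > 0, eta >= 0)
  Ds <- great_circle_distance(electrodes, electrodes, radius)
  Dc <- great_circle_distance(electrodes, pts, radius)
  Ks <- exp(-Ds^2 / (2 * sigma^2))
  Kc <- exp(-Dc^2 / (2 * sigma^2))
  w <- tryCatch(solve(Ks + eta * diag(nrow(Ks)), values),
                error = function(e) {
                  stop("(Ks + eta I) is numerically singular; use eta > 0 or remove duplicate electrodes",
                       call. = FALSE)
                })
  as.numeric(crossprod(Kc, w))
}

#' Combine per-subject grid projections
#'
#' `mode = "density"` sums the per-subject projections (used with indicator
#' values to map electrode coverage); `mode = "mean"` averages, per grid
#' point, over the subjects contributing non-missing values.
#'
#' @param per_subject list of equal-length numeric grid-value vectors (NA =
#'   no contribution at that point).
#' @param mode `"mean"` or `"density"`.
#' @return numeric grid-value vector.
#' @export
combine_subjects <- function(per_subject, mode = c("mean", "density")) {
  mode <- match.arg(mode)
  lens <- vapply(per_subject, length, 1L)
  if (length(unique(lens)) != 1) stop("mismatched grids", call. = FALSE)
  M <- do.call(rbind, per_subject)
  if (mode == "density") {
    M[is.na(M)] <- 0
    colSums(M)
  } else {
    out <- colMeans(M, na.rm = TRUE)
    out[colSums(!is.na(M)) == 0] <- NA_real_
    out
  }
}
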