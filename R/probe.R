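#' Define a linear transducer array
#'
#' Creates the geometry of a 1D linear array: equispaced elements on the
#' `z = 0` line, centered on `center_x`, with `z` pointing into the imaging
#' medium. All coordinates are in meters.
#'
#' @param n_elements Number of transducer elements (>= 2).
#' @param pitch Inter-element spacing in meters (> 0).
#' @param center_x Lateral coordinate of the array center in meters.
#'
#' @return An object of class `sparsus_probe` with fields `element_x`,
#'   `element_z`, `pitch`, `n_elements` and `aperture` (distance between the
#'   first and the last element).
#'
#' @examples
#' probe <- make_linear_probe(128, 100e-6)
#' probe$aperture # 12.7 mm
#' @export
make_linear_probe <- function(n_elements, pitch, center_x = 0) {
  if (length(n_elements) != 1L || !is.finite(n_elements) ||
      n_elements < 2 || n_elements != round(n_elements)) {
    rlang::abort("`n_elements` must be a single integer >= 2.",
                 class = "sparsus_error_geometry")
  }
  if (length(pitch) != 1L || !is.finite(pitch) || pitch <= 0) {
    rlang::abort("`pitch` must be a single positive length in meters.",
                 class = "sparsus_error_geometry")
  }
  n <- as.integer(n_elements)
  x <- (seq_len(n) - (n + 1) / 2) * pitch + center_x
  structure(
    list(
      element_x = x,
      element_z = rep(0, n),
      pitch = pitch,
      n_elements = n,
      aperture = x[n] - x[1]
    ),
    class = "sparsus_probe"
  )
}

#' @export
print.sparsus_probe <- function(x, ...) {
  cat(sprintf(
    "<sparsus_probe> %d elements, pitch %.1f um, aperture %.2f mm\n",
    x$n_elements, x$pitch * 1e6, x$aperture * 1e3
  ))
  invisible(x)
}

#' Select a subset of array elements at constant aperture
#'
#' Returns an ordered subset of element indices for sparse-array imaging.
#' For the `"regular"` and `"random"` schemes with `N >= 2` the first and the
#' last element of the full array are always included, so the selected
#' aperture — and with it the conventional diffraction limit — equals the
#' full-array aperture. Regular interior elements sit at the rounded
#' positions of an even partition between the fixed endpoints; random
#' interior elements are drawn uniformly without replacement.
#'
#' @param probe A [make_linear_probe()] geometry.
#' @param N Number of elements to select, `2 <= N <= n_elements`.
#' @param scheme `"regular"`, `"random"`, or `"all"`.
#' @param seed Integer seed for the `"random"` scheme (ignored otherwise);
#'   selection is bit-reproducible for a given seed.
#'
#' @return A `sparsus_subset`: list with integer `indices` (1-based, sorted),
#'   `scheme` and `n_total`.
#' @export
select_elements <- function(probe, N, scheme = c("regular", "random", "all"),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(probe, "sparsus_probe"))
  n_tot <- probe$n_elements
  if (scheme == "all") N <- n_tot
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N < 2 || N > n_tot) {
    rlang::abort(
      sprintf("`N` must be an integer in [2, %d].", n_tot),
      class = "sparsus_error_subset"
    )
  }
  N <- as.integer(N)
  idx <- switch(scheme,
    all = seq_len(n_tot),
    regular = {
      # even partition of the index range [1, n_tot] into N - 1 intervals,
      # endpoints fixed, interior positions rounded half-up
      pos <- 1 + (seq_len(N) - 1) * (n_tot - 1) / (N - 1)
      unique(as.integer(floor(pos + 0.5)))
    },
    random = {
      interior <- if (N > 2) {
        withr::with_seed(as.integer(seed),
                         sort(sample(2:(n_tot - 1), N - 2)))
      } else {
        integer(0)
      }
      c(1L, interior, n_tot)
    }
  )
  if (length(idx) != N) {
    rlang::abort("Subset construction produced duplicate indices.",
                 class = "sparsus_error_subset")
  }
  structure(
    list(indices = idx, scheme = scheme, n_total = n_tot),
    class = "sparsus_subset"
  )
}

#' @export
print.sparsus_subset <- function(x, ...) {
  cat(sprintf("<sparsus_subset> %d/%d elements (%s)\n",
              length(x$indices), x$n_total, x$scheme))
  invisible(x)
}

#' Build a uniform 2D reconstruction grid
#'
#' Inclusive cartesian grid over a lateral x depth window with a common step.
#' Grid points are indexed depth-major (the depth index varies fastest):
#' point `p` corresponds to `ix = (p - 1) %/% n_z + 1`,
#' `iz = (p - 1) %% n_z + 1`. This raster order is the column order of the
#' forward-model matrix and the vector order of reconstructed objects.
#'
#' @param x_min,x_max Lateral window in meters (`x_max > x_min` or equal for
#'   a single column).
#' @param z_min,z_max Depth window in meters.
#' @param step Grid spacing in meters (> 0), shared by both axes.
#'
#' @return A `sparsus_grid`: list with `x`, `z` (coordinate vectors), `step`,
#'   `n_x`, `n_z`, `n_points`.
#' @export
make_grid <- function(x_min, x_max, z_min, z_max, step) {
  if (!is.finite(step) || step <= 0) {
    rlang::abort("`step` must be a positive length in meters.",
                 class = "sparsus_error_grid")
  }
  if (x_max < x_min || z_max < z_min) {
    rlang::abort("Empty grid window: max must be >= min on both axes.",
                 class = "sparsus_error_grid")
  }
  x <- seq(x_min, x_max + step / 2, by = step)
  z <- seq(z_min, z_max + step / 2, by = step)
  structure(
    list(
      x = x, z = z, step = step,
      n_x = length(x), n_z = length(z),
      n_points = length(x) * length(z)
    ),
    class = "sparsus_grid"
  )
}

#' @export
print.sparsus_grid <- function(x, ...) {
  cat(sprintf(
    "<sparsus_grid> %d x %d = %d points, step %.2f um\n",
    x$n_x, x$n_z, x$n_points, x$step * 1e6
  ))
  invisible(x)
}

#' Map between linear point index and (ix, iz) grid indices
#'
#' @param grid A [make_grid()] object.
#' @param p Linear point index (depth-major raster order).
#' @return `grid_point_ij()`: a two-column matrix `ix`, `iz`;
#'   `grid_point_index()`: the linear index.
#' @export
grid_point_ij <- function(grid, p) {
  stopifnot(all(p >= 1), all(p <= grid$n_points))
  cbind(ix = (p - 1) %/% grid$n_z + 1, iz = (p - 1) %% grid$n_z + 1)
}

#' @rdname grid_point_ij
#' @param ix,iz Lateral / depth grid indices (1-based).
#' @export
grid_point_index <- function(grid, ix, iz) {
  stopifnot(all(ix >= 1), all(ix <= grid$n_x), all(iz >= 1), all(iz <= grid$n_z))
  (ix - 1) * grid$n_z + iz
}

#' Coordinates of every grid point in raster order
#'
#' @param grid A [make_grid()] object.
#' @return A tibble with columns `point`, `x`, `z`.
#' @export
grid_coords <- function(grid) {
  tibble::tibble(
    point = seq_len(grid$n_points),
    x = rep(grid$x, each = grid$n_z),
    z = rep(grid$z, times = grid$n_x)
  )
}

#' Reshape a raster-ordered vector to an n_z x n_x image matrix
#'
#' Rows index depth, columns index lateral position, matching the
#' depth-major raster order of [make_grid()].
#'
#' @param v Numeric vector of length `n_points`.
#' @param grid A [make_grid()] object.
#' @return An `n_z x n_x` matrix.
#' @export
grid_image <- function(v, grid) {
  stopifnot(length(v) == grid$n_points)
  matrix(v, nrow = grid$n_z, ncol = grid$n_x)
}

#' @rdname grid_image
#' @param img An `n_z x n_x` matrix.
#' @return `grid_vector()`: the raster-ordered vector.
#' @export
grid_vector <- function(img, grid) {
  stopifnot(nrow(img) == grid$n_z, ncol(img) == grid$n_x)
  as.vector(img)
}
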