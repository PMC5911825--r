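#' Umbrella-window grid specification along one axis
#'
#' A ladder of window centres from `start` to `stop` (both included) with a
#' signed `step`. Matches the way reaction-coordinate ladders are usually
#' quoted for umbrella sampling, e.g. 3.6 to 1.8 Angstrom in steps of 0.1.
#'
#' @param start,stop First and last window centre (inclusive).
#' @param step Signed step; its sign must match `stop - start` (any sign is
#'   accepted when `start == stop`).
#' @return A `grid_spec` object with the derived window count `n`.
#' @export
grid_spec <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step), step != 0)
  if (start != stop && sign(step) != sign(stop - start))
    stop("step sign inconsistent with start -> stop direction")
  n <- as.integer(round(abs(stop - start) / abs(step))) + 1L
  structure(list(start = start, stop = stop, step = step, n = n),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g -> %g by %g (%d windows)\n",
              x$start, x$stop, x$step, x$n))
  invisible(x)
}

.grid_centers <- function(spec) spec$start + spec$step * seq(0L, spec$n - 1L)

#' Build the ordered window-centre table for a 1D ladder or 2D grid
#'
#' Cartesian product in x-major order (x varies fastest), endpoints included.
#'
#' @param spec_x A [grid_spec()] for the first coordinate.
#' @param spec_y Optional [grid_spec()] for the second coordinate.
#' @return A tibble with columns `window`, `center_x` (and `center_y`).
#' @export
build_window_grid <- function(spec_x, spec_y = NULL) {
  stopifnot(inherits(spec_x, "grid_spec"))
  cx <- .grid_centers(spec_x)
  if (is.null(spec_y)) {
    out <- tibble::tibble(window = seq_along(cx), center_x = cx)
  } else {
    stopifnot(inherits(spec_y, "grid_spec"))
    cy <- .grid_centers(spec_y)
    out <- tidyr::expand_grid(center_y = cy, center_x = cx)[, c("center_x", "center_y")]
    out <- tibble::tibble(window = seq_len(nrow(out)), out)
  }
  out
}

#' Summarise an umbrella-sampling plan
#'
#' Window counts per axis and the total simulation time implied by a fixed
#' per-window sampling length.
#'
#' @param spec_x,spec_y Grid specifications (see [grid_spec()]).
#' @param ps_per_window Sampling time per window in picoseconds.
#' @return A one-row tibble with `n_windows_x`, `n_windows_y`, `n_windows`,
#'   `ps_per_window`, `total_ps` and `total_ns`.
#' @export
sampling_plan <- function(spec_x, spec_y = NULL, ps_per_window = 50) {
  nx <- spec_x$n
  ny <- if (is.null(spec_y)) NA_integer_ else spec_y$n
  n <- if (is.null(spec_y)) nx else nx * ny
  tibble::tibble(
    n_windows_x = nx, n_windows_y = ny, n_windows = n,
    ps_per_window = ps_per_window,
    total_ps = n * ps_per_window,
    total_ns = n * ps_per_window / 1000
  )
}
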