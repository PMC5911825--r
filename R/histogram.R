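#' Bin edges from start/stop/width
#'
#' Left-closed, right-open bins `[e_i, e_{i+1})`; the stop value is extended
#' upward to a whole number of bins when `stop - start` is not an exact
#' multiple of `width`.
#'
#' @param start,stop Range to cover (`stop > start`).
#' @param width Bin width (> 0).
#' @return Strictly increasing numeric vector of edges.
#' @export
bin_edges <- function(start, stop, width) .edges_from_width(start, stop, width)

#' Histogram samples on a 1D or 2D grid
#'
#' Left-closed right-open convention: a value exactly on an interior edge
#' belongs to the bin to its right; values outside the grid (including the
#' top edge) are tallied as out-of-range, so
#' `sum(counts) + out_of_range == n`.
#'
#' @param values Numeric vector (1D) or a 2-column matrix / data frame (2D).
#' @param edges Numeric edge vector (1D) or `list(x = edges, y = edges)`.
#' @return A `histogram_grid` object with fields `counts` (vector or
#'   matrix), `edges`, `n`, `out_of_range`.
#' @export
histogram_grid <- function(values, edges) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  n <- nrow(values)
  if (n == 0) stop("empty series: nothing to histogram")
  if (is.numeric(edges)) edges <- list(x = edges)
  stopifnot(ncol(values) == length(edges))
  for (e in edges) stopifnot(all(diff(e) > 0))
  ix <- .bin_index(values[, 1], edges[[1]])
  if (length(edges) == 2L) {
    iy <- .bin_index(values[, 2], edges[[2]])
    ok <- !is.na(ix) & !is.na(iy)
    nx <- length(edges[[1]]) - 1L
    ny <- length(edges[[2]]) - 1L
    counts <- matrix(0L, nx, ny)
    if (any(ok)) {
      tab <- table(factor(ix[ok], levels = seq_len(nx)),
                   factor(iy[ok], levels = seq_len(ny)))
      counts <- matrix(as.integer(tab), nx, ny)
    }
  } else {
    ok <- !is.na(ix)
    nx <- length(edges[[1]]) - 1L
    counts <- tabulate(ix[ok], nbins = nx)
  }
  structure(list(counts = counts, edges = edges, n = n,
                 out_of_range = sum(!ok)),
            class = "histogram_grid")
}

#' @export
print.histogram_grid <- function(x, ...) {
  dims <- if (is.matrix(x$counts)) paste(dim(x$counts), collapse = " x ")
          else length(x$counts)
  cat(sprintf("<histogram_grid> %s bins, %d samples (%d out of range)\n",
              dims, x$n, x$out_of_range))
  invisible(x)
}
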