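#' Free-energy surface on a binned grid
#'
#' Container for a 1D or 2D free-energy surface: per-axis bin centres and
#' edges, free energies A in kcal mol^-1 (NA = masked empty bin), and the
#' temperature the surface refers to. On construction A is referenced so
#' the minimum over unmasked bins is 0.
#'
#' @param values Numeric vector (1D) or matrix (2D) of free energies;
#'   NA marks masked bins.
#' @param axes List of per-axis lists with `centers` and optionally `edges`
#'   (named `x`, and `y` for 2D).
#' @param temperature Temperature in kelvin.
#' @return A `free_energy_surface` object.
#' @export
free_energy_surface <- function(values, axes, temperature = 300) {
  d <- if (is.matrix(values)) 2L else 1L
  stopifnot(length(axes) == d)
  names(axes) <- c("x", "y")[seq_len(d)]
  for (j in seq_len(d)) {
    nj <- if (d == 2L) dim(values)[j] else length(values)
    stopifnot(length(axes[[j]]$centers) == nj)
  }
  if (all(is.na(values))) stop("free-energy surface has no unmasked bins")
  values <- values - min(values, na.rm = TRUE)
  structure(list(values = values, axes = axes, temperature = temperature,
                 dim = d),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  dims <- if (x$dim == 2L) paste(dim(x$values), collapse = " x ")
          else length(x$values)
  cat(sprintf(
    "<free_energy_surface> %s bins at %g K, %d masked, max A = %.3f kcal/mol\n",
    dims, x$temperature, sum(is.na(x$values)),
    max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn free_energy_surface Long-format tibble: `center_x`
#'   (`center_y`), `A`, `masked`.
#' @param x A `free_energy_surface`.
#' @param ... Unused.
#' @method tidy free_energy_surface
#' @export
tidy.free_energy_surface <- function(x, ...) {
  if (x$dim == 2L) {
    out <- tidyr::expand_grid(center_y = x$axes$y$centers,
                              center_x = x$axes$x$centers)[, c("center_x", "center_y")]
    out$A <- as.numeric(x$values)[
      match(paste(match(out$center_x, x$axes$x$centers),
                  match(out$center_y, x$axes$y$centers)),
            paste(rep(seq_along(x$axes$x$centers), times = length(x$axes$y$centers)),
                  rep(seq_along(x$axes$y$centers), each = length(x$axes$x$centers))))]
  } else {
    out <- tibble::tibble(center_x = x$axes$x$centers, A = x$values)
  }
  out$masked <- is.na(out$A)
  out
}

# linear index helpers (column-major, x = rows)
.fes_dims <- function(fes) {
  if (fes$dim == 2L) dim(fes$values) else c(length(fes$values), 1L)
}

.fes_matrix <- function(fes) {
  if (fes$dim == 2L) fes$values else matrix(fes$values, ncol = 1)
}

#' Locate free-energy basins by steepest-descent assignment
#'
#' Local minima under 8-connectivity (2 neighbours in 1D); every unmasked
#' cell follows its steepest-descent pointer (lowest-energy strictly lower
#' neighbour, ties broken by lexicographic cell index) to a terminal cell,
#' and terminal cells connected at equal energy are merged into one basin.
#' A basin whose minimum is a multi-cell plateau (e.g. a uniform surface)
#' is flagged degenerate.
#'
#' @param fes A [free_energy_surface()].
#' @return A tibble with one row per basin (`basin`, `ix`, `iy`,
#'   `center_x`, `center_y`, `A_min`, `n_cells`, `degenerate`), ordered by
#'   `A_min`; attribute `assignment` holds the per-cell basin index (same
#'   shape as `fes$values`).
#' @export
find_minima <- function(fes) {
  stopifnot(inherits(fes, "free_energy_surface"))
  V <- .fes_matrix(fes)
  nr <- nrow(V); nc <- ncol(V); n <- nr * nc
  vals <- as.numeric(V)
  ok <- !is.na(vals)
  if (!any(ok)) stop("no unmasked cells")
  nbr_offsets <- expand.grid(dr = -1:1, dc = -1:1)
  nbr_offsets <- nbr_offsets[!(nbr_offsets$dr == 0 & nbr_offsets$dc == 0), ]

  ptr <- rep(NA_integer_, n)
  for (i in which(ok)) {
    r <- (i - 1L) %% nr + 1L
    c <- (i - 1L) %/% nr + 1L
    rr <- r + nbr_offsets$dr
    cc <- c + nbr_offsets$dc
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    j <- rr[keep] + (cc[keep] - 1L) * nr
    j <- j[!is.na(vals[j])]
    lower <- j[vals[j] < vals[i]]
    if (length(lower) > 0) {
      best <- min(vals[lower])
      cand <- lower[vals[lower] == best]
      ptr[i] <- min(cand)
    } else {
      ptr[i] <- i  # sink
    }
  }
  # resolve pointers to terminal sinks (sinks are fixed points of ptr)
  root <- ptr
  repeat {
    nxt <- root
    nxt[ok] <- ptr[root[ok]]
    if (identical(nxt, root)) break
    root <- nxt
  }
  sinks <- which(ok & ptr == seq_len(n))
  # merge adjacent equal-energy sinks (plateaus)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sink_set <- rep(FALSE, n); sink_set[sinks] <- TRUE
  for (i in sinks) {
    r <- (i - 1L) %% nr + 1L
    c <- (i - 1L) %/% nr + 1L
    rr <- r + nbr_offsets$dr
    cc <- c + nbr_offsets$dc
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    j <- rr[keep] + (cc[keep] - 1L) * nr
    for (jj in j[sink_set[j]]) {
      if (vals[jj] == vals[i]) {
        ri <- findp(i); rj <- findp(jj)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  sink_root <- vapply(sinks, findp, 1L)
  basin_roots <- sort(unique(sink_root))
  basin_of_root <- setNames(seq_along(basin_roots), basin_roots)
  assignment <- rep(NA_integer_, n)
  assignment[ok] <- basin_of_root[as.character(vapply(root[ok], findp, 1L))]

  rows <- lapply(seq_along(basin_roots), function(b) {
    cell <- basin_roots[b]
    plateau <- sinks[sink_root == cell]
    r <- (cell - 1L) %% nr + 1L
    c <- (cell - 1L) %/% nr + 1L
    tibble::tibble(
      basin = b, ix = r, iy = if (fes$dim == 2L) c else NA_integer_,
      center_x = fes$axes$x$centers[r],
      center_y = if (fes$dim == 2L) fes$axes$y$centers[c] else NA_real_,
      A_min = vals[cell], n_cells = sum(assignment == b, na.rm = TRUE),
      degenerate = length(plateau) > 1
    )
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(out$A_min, out$ix)
  relabel <- integer(nrow(out)); relabel[ord] <- seq_len(nrow(out))
  out$basin <- relabel[out$basin]
  amap <- assignment
  amap[!is.na(assignment)] <- relabel[assignment[!is.na(assignment)]]
  out <- out[order(out$basin), ]
  attr(out, "assignment") <- if (fes$dim == 2L) matrix(amap, nr, nc) else amap
  out
}

.basin_cell <- function(fes, minima, which) {
  if (length(which) == 2L && fes$dim == 2L) return(as.integer(which))
  row <- minima[minima$basin == which, ]
  if (nrow(row) != 1) stop("no such basin: ", which)
  c(row$ix, if (fes$dim == 2L) row$iy else 1L)
}

#' Minimax (lowest-saddle) reaction path between two basins
#'
#' Finds the grid path (8-connected) from the start-basin minimum to the
#' end-basin minimum that minimises the maximum free energy along it — the
#' discrete minimum free-energy path whose highest cell is the transition
#' state. Ties in the bottleneck are broken by lower total path energy
#' (measured above the grid minimum), then by cell index, so the result is
#' deterministic.
#'
#' @param fes A [free_energy_surface()].
#' @param from,to Basin ids (rows of [find_minima()] output) or `c(ix, iy)`
#'   cell indices.
#' @param minima Optional precomputed [find_minima()] table.
#' @return A `reaction_path`: tibble (`position`, `ix`, `iy`, `center_x`,
#'   `center_y`, `A`) with attributes `ts_index` (arg-max position) and
#'   `ts_A`.
#' @export
minimax_path <- function(fes, from = 1, to = 2, minima = NULL) {
  stopifnot(inherits(fes, "free_energy_surface"))
  if (is.null(minima) && (length(from) == 1L || length(to) == 1L))
    minima <- find_minima(fes)
  V <- .fes_matrix(fes)
  nr <- nrow(V)
  s <- .basin_cell(fes, minima, from)
  e <- .basin_cell(fes, minima, to)
  lin0 <- function(cell) (cell[1] - 1L) + (cell[2] - 1L) * nr  # 0-based
  idx <- cpp_minimax_path(V, lin0(s), lin0(e))
  if (length(idx) == 0)
    stop("no path: basins are disconnected by masked bins")
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  out <- tibble::tibble(
    position = seq_along(idx), ix = r,
    iy = if (fes$dim == 2L) c else NA_integer_,
    center_x = fes$axes$x$centers[r],
    center_y = if (fes$dim == 2L) fes$axes$y$centers[c] else NA_real_,
    A = V[cbind(r, c)]
  )
  ts <- which.max(out$A)
  attr(out, "ts_index") <- ts
  attr(out, "ts_A") <- out$A[ts]
  class(out) <- c("reaction_path", class(out))
  out
}

#' Activation and reaction free energies along a reaction path
#'
#' `delta_A_act = A(TS) - A(start)` (always >= 0 since the path maximum is
#' at least the start energy) and `delta_A_reac = A(end) - A(start)`.
#'
#' @param path A `reaction_path` from [minimax_path()].
#' @return A one-row tibble: `delta_A_act`, `delta_A_reac`, `A_ts`,
#'   `ts_position`, `path_length`.
#' @export
activation_reaction_energies <- function(path) {
  stopifnot(inherits(path, "reaction_path"), nrow(path) >= 1)
  a <- path$A
  ts <- which.max(a)
  tibble::tibble(
    delta_A_act = a[ts] - a[1],
    delta_A_reac = a[length(a)] - a[1],
    A_ts = a[ts], ts_position = ts, path_length = length(a)
  )
}

#' Free-energy difference between two minima of a 1D profile
#'
#' `A(basin b minimum) - A(basin a minimum)` on a one-dimensional
#' free-energy profile, e.g. the thiolate/thiol ionization-state difference
#' along a proton-transfer coordinate.
#'
#' @param fes A 1D [free_energy_surface()].
#' @param a,b Basin ids as returned by [find_minima()] (default: the two
#'   lowest minima).
#' @return Free-energy difference in kcal mol^-1.
#' @export
profile_delta <- function(fes, a = 1, b = 2) {
  stopifnot(inherits(fes, "free_energy_surface"), fes$dim == 1L)
  minima <- find_minima(fes)
  if (nrow(minima) < max(a, b))
    stop("missing basin: profile has ", nrow(minima),
         " basin(s), need basin ", max(a, b))
  minima$A_min[minima$basin == b] - minima$A_min[minima$basin == a]
}

#' Boltzmann-weighted basin populations of a surface
#'
#' Sums `exp(-A/kB T)` over each basin's member cells (steepest-descent
#' assignment) and normalises.
#'
#' @param fes A [free_energy_surface()].
#' @param minima Optional precomputed [find_minima()] table.
#' @return A tibble (`basin`, `population`).
#' @export
basin_populations <- function(fes, minima = NULL) {
  if (is.null(minima)) minima <- find_minima(fes)
  assignment <- attr(minima, "assignment")
  w <- exp(-fes$values / kT(fes$temperature))
  pops <- vapply(minima$basin, function(b) {
    sum(w[which(assignment == b)], na.rm = TRUE)
  }, 1)
  tibble::tibble(basin = minima$basin, population = pops / sum(pops))
}
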