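#' 2D bin specification for conformational (distance, dihedral) surfaces
#'
#' Defaults follow the common histogram-analysis convention for a
#' nucleophile-electrophile distance against a rotatable-bond dihedral:
#' distance from 2.5 to 9.5 Angstrom in 0.1 Angstrom classes, dihedral from
#' -160 to +160 degrees in 15 degree classes. Because 320 is not an integer
#' multiple of 15, the default `dihedral_mode = "centered"` uses 21 bins of
#' exactly 15 degrees centred on multiples of 15 (spanning [-157.5,
#' +157.5)); records outside either axis are counted as out-of-range.
#' `dihedral_mode = "exact"` instead spans the stated range with
#' ceiling(320/15) = 22 bins, the last one truncated at +170.
#'
#' @param dist_start,dist_stop,dist_width Distance axis (Angstrom).
#' @param dih_start,dih_stop,dih_width Dihedral axis (degrees).
#' @param dihedral_mode `"centered"` (default) or `"exact"`; see Details.
#' @return A `bin_spec_2d` object: `list(x = edges, y = edges)` with the
#'   distance on x and the dihedral on y.
#' @export
bin_spec_2d <- function(dist_start = 2.5, dist_stop = 9.5, dist_width = 0.1,
                        dih_start = -160, dih_stop = 160, dih_width = 15,
                        dihedral_mode = c("centered", "exact")) {
  dihedral_mode <- match.arg(dihedral_mode)
  x <- bin_edges(dist_start, dist_stop, dist_width)
  y <- if (dihedral_mode == "centered") {
    lo <- ceiling(dih_start / dih_width)
    hi <- floor(dih_stop / dih_width)
    seq(lo * dih_width - dih_width / 2, by = dih_width,
        length.out = hi - lo + 2L)
  } else {
    bin_edges(dih_start, dih_stop, dih_width)
  }
  structure(list(x = x, y = y), class = "bin_spec_2d",
            dihedral_mode = dihedral_mode)
}

#' Pool feature series from several replicas
#'
#' Concatenates per-replica feature tables, preserving replica ids; the
#' pooled record count is the sum of the inputs.
#'
#' @param series A list of data frames with identical columns (or a single
#'   data frame, returned as a tibble unchanged).
#' @return A pooled tibble.
#' @export
pool_features <- function(series) {
  if (is.data.frame(series)) return(tibble::as_tibble(series))
  stopifnot(is.list(series), length(series) >= 1)
  cols <- lapply(series, function(s) sort(names(s)))
  if (!all(vapply(cols, identical, TRUE, cols[[1]])))
    stop("column mismatch across series: ",
         paste(unique(unlist(cols)), collapse = ", "))
  dplyr::bind_rows(lapply(series, tibble::as_tibble))
}

#' Boltzmann-inversion conformational free-energy surface
#'
#' Histograms the (distance, dihedral) features of an unbiased trajectory,
#' normalises over in-range counts to a probability distribution P, and
#' inverts it to free energies A = -kB T ln P, referenced to the global
#' minimum. Empty bins are masked; the out-of-range count is reported as an
#' attribute.
#'
#' @param features Data frame of pooled snapshots.
#' @param bins A [bin_spec_2d()].
#' @param temperature Temperature in kelvin.
#' @param distance_col,dihedral_col Column names (defaults `"s_cb"`,
#'   `"dihedral"`).
#' @return A [free_energy_surface()] (distance on x, dihedral on y) with
#'   attributes `out_of_range` and `n`.
#' @export
boltzmann_fes <- function(features, bins = bin_spec_2d(), temperature = 300,
                          distance_col = "s_cb", dihedral_col = "dihedral") {
  stopifnot(is.data.frame(features))
  miss <- setdiff(c(distance_col, dihedral_col), names(features))
  if (length(miss) > 0) stop("features missing columns: ", paste(miss, collapse = ", "))
  h <- histogram_grid(cbind(features[[distance_col]], features[[dihedral_col]]),
                      list(x = bins$x, y = bins$y))
  if (sum(h$counts) == 0) stop("all samples fall outside the binning range")
  P <- h$counts / sum(h$counts)
  A <- -kT(temperature) * log(P)
  A[!is.finite(A)] <- NA
  fes <- free_energy_surface(
    A,
    axes = list(x = list(edges = bins$x, centers = .centers(bins$x)),
                y = list(edges = bins$y, centers = .centers(bins$y))),
    temperature = temperature)
  attr(fes, "out_of_range") <- h$out_of_range
  attr(fes, "n") <- h$n
  fes
}

#' Reactive-conformation statistics
#'
#' Fraction of snapshots in which the nucleophile-electrophile distance is
#' strictly smaller than the cutoff (default 3.9 Angstrom, the AMBER99SB
#' sum of sulfur and sp2-carbon van der Waals radii taken here as a
#' configuration constant). Exact integer counts are kept per replica, and
#' the pooled fraction is the count-weighted mean of the per-replica
#' fractions.
#'
#' @param features Data frame with distance and replica columns.
#' @param cutoff Distance cutoff in Angstrom (> 0); the comparison is
#'   strict (`<`).
#' @param distance_col,replica_col Column names.
#' @return A `reactive_stats` object: list with `cutoff`, `pooled`
#'   (one-row tibble: `n_reactive`, `n_total`, `fraction`) and
#'   `per_replica` (tibble by replica).
#' @export
reactive_fraction <- function(features, cutoff = 3.9,
                              distance_col = "s_cb", replica_col = "replica") {
  stopifnot(is.data.frame(features), cutoff > 0)
  if (nrow(features) == 0) stop("empty input: no snapshots")
  if (!distance_col %in% names(features))
    stop("features missing distance column '", distance_col, "'")
  d <- features[[distance_col]]
  rep_id <- if (replica_col %in% names(features)) features[[replica_col]] else 1L
  per <- tibble::tibble(replica = rep_id, reactive = d < cutoff) |>
    dplyr::group_by(.data$replica) |>
    dplyr::summarise(n_reactive = sum(.data$reactive),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_reactive / .data$n_total)
  pooled <- tibble::tibble(n_reactive = sum(per$n_reactive),
                           n_total = sum(per$n_total))
  pooled$fraction <- pooled$n_reactive / pooled$n_total
  structure(list(cutoff = cutoff, pooled = pooled, per_replica = per),
            class = "reactive_stats")
}

#' @export
print.reactive_stats <- function(x, ...) {
  cat(sprintf("<reactive_stats> cutoff %.2f A: %d / %d snapshots (%.2f%%)\n",
              x$cutoff, x$pooled$n_reactive, x$pooled$n_total,
              100 * x$pooled$fraction))
  invisible(x)
}

#' @method tidy reactive_stats
#' @export
tidy.reactive_stats <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$per_replica, scope = "replica"),
    dplyr::mutate(x$pooled, replica = NA_integer_, scope = "pooled")
  )
}

#' Conformational state definition
#'
#' A labelled rectangular region in (dihedral, optionally distance) space,
#' e.g. the reactive state near -55 degrees / 3.5 Angstrom or the
#' non-reactive state at +100..+120 degrees.
#'
#' @param label State label (unique across definitions).
#' @param dihedral Length-2 numeric interval in degrees.
#' @param distance Optional length-2 numeric interval in Angstrom.
#' @return A `state_definition` object.
#' @export
state_definition <- function(label, dihedral, distance = NULL) {
  stopifnot(is.character(label), length(dihedral) == 2, dihedral[1] < dihedral[2])
  if (!is.null(distance))
    stopifnot(length(distance) == 2, distance[1] < distance[2])
  structure(list(label = label, dihedral = dihedral, distance = distance),
            class = "state_definition")
}

#' Default reactive/non-reactive state definitions
#'
#' State `a`: dihedral -55 +/- 20 degrees (reactive arrangement); state
#' `b`: dihedral +100 to +120 degrees with the distance dispersed over
#' 4.5-6.5 Angstrom (non-reactive arrangement).
#'
#' @return A list of two [state_definition()]s.
#' @export
default_states <- function() {
  list(state_definition("a", dihedral = c(-75, -35)),
       state_definition("b", dihedral = c(100, 120), distance = c(4.5, 6.5)))
}

.state_match <- function(def, distance, dihedral) {
  ok <- dihedral >= def$dihedral[1] & dihedral <= def$dihedral[2]
  if (!is.null(def$distance))
    ok <- ok & distance >= def$distance[1] & distance <= def$distance[2]
  ok
}

#' Assign snapshots to conformational states
#'
#' Labels each record with the first (and only, since definitions must not
#' overlap) matching state, or `"other"`; reports occupancies per replica
#' and pooled.
#'
#' @param features Data frame of snapshots.
#' @param states List of [state_definition()]s with unique labels.
#' @param distance_col,dihedral_col,replica_col Column names.
#' @return The features tibble with an added `.state` column; attribute
#'   `occupancy` holds a tibble of per-replica and pooled occupancies.
#' @export
assign_states <- function(features, states = default_states(),
                          distance_col = "s_cb", dihedral_col = "dihedral",
                          replica_col = "replica") {
  stopifnot(is.data.frame(features))
  if (inherits(states, "state_definition")) states <- list(states)
  labels <- vapply(states, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("state labels must be unique")
  d <- features[[distance_col]]
  phi <- features[[dihedral_col]]
  match_mat <- vapply(states, .state_match, logical(length(phi)),
                      distance = d, dihedral = phi)
  if (length(phi) == 1) match_mat <- matrix(match_mat, nrow = 1)
  if (any(rowSums(match_mat) > 1))
    stop("overlapping state definitions: a record matched more than one state")
  lab <- rep("other", length(phi))
  for (j in seq_along(states)) lab[match_mat[, j]] <- labels[j]
  out <- tibble::as_tibble(features)
  out$.state <- lab
  rep_id <- if (replica_col %in% names(out)) out[[replica_col]] else 1L
  occ <- tibble::tibble(replica = rep_id, .state = lab) |>
    dplyr::count(.data$replica, .data$.state) |>
    dplyr::group_by(.data$replica) |>
    dplyr::mutate(occupancy = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  pooled <- tibble::tibble(.state = lab) |>
    dplyr::count(.data$.state) |>
    dplyr::mutate(replica = NA_integer_, occupancy = .data$n / sum(.data$n))
  attr(out, "occupancy") <- dplyr::bind_rows(occ, pooled)
  out
}

#' Free-energy gap between two conformational states
#'
#' `delta_A(a -> b) = -kB T ln(P_b / P_a)`: negative when b is the more
#' populated (more stable) state. Accepts assigned features (uses pooled
#' occupancies), a [free_energy_surface()] (uses Boltzmann-weighted basin
#' populations), or a named numeric vector of populations/counts.
#'
#' @param x Assigned features from [assign_states()], a
#'   `free_energy_surface`, or a named numeric vector.
#' @param a,b State labels (or basin ids for a surface).
#' @param temperature Temperature in kelvin.
#' @return Free-energy gap in kcal mol^-1; `basin_delta(x, a, b) ==
#'   -basin_delta(x, b, a)`.
#' @export
basin_delta <- function(x, a = "a", b = "b", temperature = 300) {
  if (inherits(x, "free_energy_surface")) {
    pops <- basin_populations(x)
    temperature <- x$temperature
    p <- setNames(pops$population, pops$basin)
    a <- as.character(a); b <- as.character(b)
  } else if (is.data.frame(x) && ".state" %in% names(x)) {
    tab <- table(x$.state)
    p <- setNames(as.numeric(tab), names(tab))
  } else if (is.numeric(x) && !is.null(names(x))) {
    p <- x
  } else {
    stop("x must be assigned features, a free_energy_surface, or a named vector")
  }
  if (!a %in% names(p) || !b %in% names(p) || p[[a]] == 0 || p[[b]] == 0)
    stop("zero population for state '", if (!a %in% names(p) || p[[a]] == 0) a else b,
         "': longer sampling (or wider state definitions) needed")
  -kT(temperature) * log(p[[b]] / p[[a]])
}

#' Distance-dihedral coupling report
#'
#' Quantifies how tightly the nucleophile-electrophile distance is coupled
#' to the dihedral-defined conformational state: (i) the point-biserial
#' correlation between the distance and the binary state label, with a
#' permutation p-value (label shuffles, fixed seed); (ii) the fraction of
#' state switches at which the distance series crosses the `midline`
#' within `lag` records (per replica, then pooled).
#'
#' @param features Assigned features (see [assign_states()]) containing a
#'   `.state` column with exactly the two labels `a` and `b` present.
#' @param a,b The two state labels (binary coding b = 1).
#' @param distance_col,replica_col Column names.
#' @param midline Crossing threshold in Angstrom (default 4.5).
#' @param lag Half-width of the crossing window in records (default 5).
#' @param n_perm Permutation count for the p-value (default 1000).
#' @param seed Seed for the permutation null (default 1).
#' @return A one-row tibble: `r_point_biserial`, `p_permutation`,
#'   `n_switches`, `co_occurrence`.
#' @export
coupling_report <- function(features, a = "a", b = "b",
                            distance_col = "s_cb", replica_col = "replica",
                            midline = 4.5, lag = 5, n_perm = 1000, seed = 1) {
  stopifnot(is.data.frame(features), ".state" %in% names(features),
            nrow(features) >= 2)
  keep <- features$.state %in% c(a, b)
  f <- features[keep, , drop = FALSE]
  d <- f[[distance_col]]
  y <- as.integer(f$.state == b)
  if (length(unique(y)) < 2)
    stop("undefined correlation: only one state present in the data")
  r <- cor(d, y)
  set.seed(seed)
  r_null <- replicate(n_perm, cor(d, sample(y)))
  p_perm <- (1 + sum(abs(r_null) >= abs(r))) / (n_perm + 1)

  rep_id <- if (replica_col %in% names(f)) f[[replica_col]] else rep(1L, nrow(f))
  n_sw <- 0L; n_co <- 0L
  for (r_id in unique(rep_id)) {
    i <- which(rep_id == r_id)
    yy <- y[i]; dd <- d[i]
    sw <- which(diff(yy) != 0)
    for (s in sw) {
      lo <- max(1, s - lag + 1)
      hi <- min(length(dd), s + lag)
      seg <- dd[lo:hi]
      n_sw <- n_sw + 1L
      if (min(seg) < midline && max(seg) > midline) n_co <- n_co + 1L
    }
  }
  tibble::tibble(
    r_point_biserial = r, p_permutation = p_perm,
    n_switches = n_sw,
    co_occurrence = if (n_sw > 0) n_co / n_sw else NA_real_
  )
}

#' Hydrogen-bond occupancy
#'
#' Fraction of snapshots whose hydrogen-bond distance is at most `cutoff`
#' (default 3.5 Angstrom heavy-atom criterion; the comparison is `<=`, in
#' contrast to the strict `<` of [reactive_fraction()]).
#'
#' @param features Data frame with the hydrogen-bond distance column.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param hbond_col,replica_col Column names.
#' @return A tibble of per-replica fractions plus a pooled row
#'   (`replica = NA`).
#' @export
hbond_occupancy <- function(features, cutoff = 3.5, hbond_col = "hbond",
                            replica_col = "replica") {
  stopifnot(is.data.frame(features), cutoff > 0)
  if (nrow(features) == 0) stop("empty input: no snapshots")
  if (!hbond_col %in% names(features))
    stop("features missing hydrogen-bond column '", hbond_col, "'")
  h <- features[[hbond_col]]
  rep_id <- if (replica_col %in% names(features)) features[[replica_col]] else 1L
  per <- tibble::tibble(replica = rep_id, bonded = h <= cutoff) |>
    dplyr::group_by(.data$replica) |>
    dplyr::summarise(fraction = mean(.data$bonded), n = dplyr::n(),
                     .groups = "drop")
  pooled <- tibble::tibble(replica = NA_integer_, fraction = mean(h <= cutoff),
                           n = length(h))
  dplyr::bind_rows(per, pooled)
}
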