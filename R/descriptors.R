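#' Euclidean distance between two points
#'
#' @param p1,p2 Numeric xyz vectors (Angstrom).
#' @return Distance in Angstrom; symmetric in its arguments.
#' @export
dist3d <- function(p1, p2) {
  stopifnot(is.numeric(p1), is.numeric(p2), length(p1) == 3, length(p2) == 3,
            all(is.finite(p1)), all(is.finite(p2)))
  sqrt(sum((p1 - p2)^2))
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: cis = 0 degrees, right-handed positive rotation,
#' range (-180, 180] with the boundary mapped to +180. Invariant under rigid
#' rotation and translation; negated by mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10 || nb2 < 1e-10)
    stop("undefined dihedral: three consecutive points are collinear")
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * b2) / nb2
  wrap_angle(atan2(y, x) * 180 / pi)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Difference-of-distances coordinate
#'
#' Antisymmetric proton-transfer style coordinate d(A-B) - d(C-D), e.g. the
#' (H-S) minus (H-O) difference that tracks a proton moving from a
#' carboxylate oxygen to a thiolate sulfur.
#'
#' @param d_ab,d_cd Distances in Angstrom (>= 0).
#' @return `d_ab - d_cd` in Angstrom.
#' @export
difference_coordinate <- function(d_ab, d_cd) {
  stopifnot(all(d_ab >= 0), all(d_cd >= 0))
  d_ab - d_cd
}

#' Geometric descriptor declarations
#'
#' A descriptor names a scalar geometric observable: a distance (2 atoms),
#' a dihedral (4 atoms) or a difference of distances ((A-B) - (C-D),
#' 4 atoms). Atom selectors are `"chain.resno.name"` strings (e.g.
#' `"A.797.SG"`); each must resolve to exactly one atom per snapshot.
#'
#' @param name Descriptor (column) name.
#' @param ... Atom selectors: 2 for `distance`, 4 for `dihedral` and for
#'   `distance_difference` (paired as (1-2) - (3-4)).
#' @return A `geometric_descriptor` object.
#' @export
descriptor_distance <- function(name, ...) .descriptor(name, "distance", 2L, ...)

#' @rdname descriptor_distance
#' @export
descriptor_dihedral <- function(name, ...) .descriptor(name, "dihedral", 4L, ...)

#' @rdname descriptor_distance
#' @export
descriptor_difference <- function(name, ...)
  .descriptor(name, "distance_difference", 4L, ...)

.descriptor <- function(name, kind, n_atoms, ...) {
  sel <- c(...)
  if (length(sel) != n_atoms)
    stop(sprintf("%s descriptor needs %d atom selectors, got %d",
                 kind, n_atoms, length(sel)))
  structure(list(name = name, kind = kind, selectors = sel,
                 units = if (kind == "dihedral") "degrees" else "angstrom"),
            class = "geometric_descriptor")
}

.resolve_selector <- function(snapshot, sel, descriptor_name) {
  parts <- strsplit(sel, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("bad selector '", sel, "': expected 'chain.resno.name'")
  a <- snapshot$atoms
  hit <- which(a$chain == parts[1] & a$resno == as.integer(parts[2]) &
                 a$name == parts[3])
  if (length(hit) != 1)
    stop(sprintf(
      "selector '%s' of descriptor '%s' resolved to %d atoms (snapshot t = %s)",
      sel, descriptor_name, length(hit), format(snapshot$time)))
  as.numeric(a[hit, c("x", "y", "z")])
}

.eval_descriptor <- function(snapshot, d) {
  pts <- lapply(d$selectors, .resolve_selector, snapshot = snapshot,
                descriptor_name = d$name)
  switch(d$kind,
    distance = dist3d(pts[[1]], pts[[2]]),
    dihedral = dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
    distance_difference = difference_coordinate(
      dist3d(pts[[1]], pts[[2]]), dist3d(pts[[3]], pts[[4]]))
  )
}

#' Evaluate descriptors over snapshots into a feature series
#'
#' One record per snapshot; descriptor columns appear in declaration order.
#'
#' @param snapshots A list of `snapshot` objects (see [read_pdb_snapshot()]).
#' @param descriptors A list of descriptors (see [descriptor_distance()]).
#' @return A tibble with columns `time`, `replica`, then one column per
#'   descriptor.
#' @export
evaluate_descriptors <- function(snapshots, descriptors) {
  if (inherits(snapshots, "snapshot")) snapshots <- list(snapshots)
  if (inherits(descriptors, "geometric_descriptor"))
    descriptors <- list(descriptors)
  nm <- vapply(descriptors, `[[`, "", "name")
  if (length(snapshots) == 0) {
    out <- tibble::tibble(time = numeric(0), replica = integer(0))
    for (n in nm) out[[n]] <- numeric(0)
    return(out)
  }
  rows <- lapply(snapshots, function(s) {
    vals <- vapply(descriptors, .eval_descriptor, 1, snapshot = s)
    tibble::tibble(time = s$time, replica = s$replica,
                   !!!setNames(as.list(vals), nm))
  })
  dplyr::bind_rows(rows)
}
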