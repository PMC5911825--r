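#' Read a PDB snapshot
#'
#' Fixed-column parsing of ATOM/HETATM records (coordinates in Angstrom);
#' insertion codes are preserved and non-coordinate records are ignored.
#' Only the first MODEL of a multi-model file is read.
#'
#' @param x Path to a PDB file, or a character vector of PDB lines.
#' @param time Snapshot time in ps (metadata, optional).
#' @param replica Replica id (metadata, optional).
#' @return A `snapshot` object: list with an `atoms` tibble (`record`,
#'   `serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `element`) plus `time` and `replica`.
#' @export
read_pdb_snapshot <- function(x, time = NA_real_, replica = NA_integer_) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  # first model only
  ends <- which(grepl("^ENDMDL", lines))
  if (length(ends) > 0) lines <- lines[seq_len(ends[1] - 1)]
  idx <- which(grepl("^(ATOM  |HETATM)", lines))
  if (length(idx) == 0) stop("empty input: no ATOM/HETATM records")
  fw <- function(ln, from, to) substr(ln, from, to)
  ln <- lines[idx]
  num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s)))
    if (length(bad) > 0)
      stop(sprintf("parse error at line %d: malformed %s field '%s'",
                   lineno[bad[1]], what, s[bad[1]]))
    v
  }
  atoms <- tibble::tibble(
    record = trimws(fw(ln, 1, 6)),
    serial = suppressWarnings(as.integer(trimws(fw(ln, 7, 11)))),
    name = trimws(fw(ln, 13, 16)),
    altloc = trimws(fw(ln, 17, 17)),
    resname = trimws(fw(ln, 18, 20)),
    chain = trimws(fw(ln, 22, 22)),
    resno = suppressWarnings(as.integer(trimws(fw(ln, 23, 26)))),
    insert = trimws(fw(ln, 27, 27)),
    x = num(fw(ln, 31, 38), "x coordinate", idx),
    y = num(fw(ln, 39, 46), "y coordinate", idx),
    z = num(fw(ln, 47, 54), "z coordinate", idx),
    element = trimws(fw(ln, 77, 78))
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in PDB input")
  structure(list(atoms = atoms, time = time, replica = replica),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot> %d atoms", nrow(x$atoms)))
  if (!is.na(x$time)) cat(sprintf(", t = %g ps", x$time))
  cat("\n")
  invisible(x)
}

#' Write a snapshot as PDB text
#'
#' @param snapshot A `snapshot` object.
#' @param file Optional path; when `NULL` the PDB text is returned as a
#'   character vector.
#' @return The PDB lines (invisibly when writing to a file).
#' @export
write_pdb_snapshot <- function(snapshot, file = NULL) {
  a <- snapshot$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$record, a$serial %||% seq_len(nrow(a)),
    ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
    a$altloc, a$resname, a$chain, a$resno, a$insert,
    a$x, a$y, a$z, 1.00, 0.00, a$element)
  lines <- c(lines, "END")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Build toy PDB snapshots realising target descriptor values
#'
#' Constructs minimal ATOM records whose computed descriptors equal the
#' requested targets to 1e-3 Angstrom / degrees. Useful as self-validating
#' fixtures for the geometry operations. Supply a `distance` target (two
#' atoms `P1`, `P2`), a `dihedral` target (four atoms `C1`, `C2`, `N1`,
#' `C3` with 1.5 A bonds and 90 degree bond angles), or both (six atoms).
#'
#' @param distance Target inter-atomic distance in Angstrom (>= 0), or NULL.
#' @param dihedral Target dihedral in degrees (wrapped to (-180, 180]), or
#'   NULL.
#' @return PDB text as a character vector.
#' @export
make_toy_snapshots <- function(distance = NULL, dihedral = NULL) {
  if (is.null(distance) && is.null(dihedral))
    stop("supply at least one of distance or dihedral")
  atoms <- list()
  resno <- 0L
  if (!is.null(dihedral)) {
    phi <- wrap_angle(dihedral) * pi / 180
    b <- 40  # long arms: 3-decimal PDB rounding stays within 1e-3 degrees
    p2 <- c(0, 0, 0)
    p3 <- c(b, 0, 0)
    p1 <- c(0, b, 0)
    # half-plane of p4 about the p2->p3 axis rotated by phi from p1's side
    p4 <- p3 + b * c(0, cos(phi), sin(phi))
    nm <- c("C1", "C2", "N1", "C3")
    el <- c("C", "C", "N", "C")
    for (i in 1:4) {
      resno <- resno + 1L
      atoms[[length(atoms) + 1]] <- list(name = nm[i], element = el[i],
                                         xyz = list(p1, p2, p3, p4)[[i]],
                                         resno = resno)
    }
  }
  if (!is.null(distance)) {
    if (distance < 0) stop("unrealizable target: distance < 0")
    off <- c(0, 0, 10)  # keep away from the dihedral fixture
    for (i in 1:2) {
      resno <- resno + 1L
      atoms[[length(atoms) + 1]] <- list(
        name = paste0("P", i), element = "S",
        xyz = off + c(if (i == 1) 0 else distance, 0, 0), resno = resno)
    }
  }
  a <- tibble::tibble(
    record = "ATOM",
    serial = seq_along(atoms),
    name = vapply(atoms, `[[`, "", "name"),
    altloc = "",
    resname = "TOY",
    chain = "A",
    resno = vapply(atoms, function(z) as.integer(z$resno), 1L),
    insert = "",
    x = vapply(atoms, function(z) z$xyz[1], 1),
    y = vapply(atoms, function(z) z$xyz[2], 1),
    z = vapply(atoms, function(z) z$xyz[3], 1),
    element = vapply(atoms, `[[`, "", "element")
  )
  write_pdb_snapshot(structure(list(atoms = a, time = NA_real_,
                                    replica = NA_integer_),
                               class = "snapshot"))
}
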