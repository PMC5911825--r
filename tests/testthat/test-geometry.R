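test_that("distance obeys closed-form cases and symmetry", {
  expect_equal(dist3d(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(dist3d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(21)
  for (i in 1:20) {
    p <- rnorm(3); q <- rnorm(3)
    expect_equal(dist3d(p, q), sqrt(sum((p - q)^2)))
    expect_equal(dist3d(p, q), dist3d(q, p))
  }
})

test_that("dihedral reproduces cis/trans and an independent atan2 reference", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)), 180)
  skip_if_not_installed("bio3d")
  set.seed(33)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 2), 3)
    ref <- bio3d::torsion.xyz(as.numeric(pts))
    mine <- dihedral_angle(pts[, 1], pts[, 2], pts[, 3], pts[, 4])
    d <- abs(mine - ref) %% 360
    expect_lt(min(d, 360 - d), 1e-6)
  }
})

test_that("descriptors are invariant under rigid motion, dihedrals flip under reflection", {
  set.seed(7)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 2), 3)
    R <- random_rotation()
    t <- rnorm(3, sd = 5)
    moved <- R %*% pts + t
    expect_lt(abs(dist3d(moved[, 1], moved[, 2]) - dist3d(pts[, 1], pts[, 2])),
              1e-9)
    expect_lt(abs(dihedral_angle(moved[, 1], moved[, 2], moved[, 3], moved[, 4]) -
                    dihedral_angle(pts[, 1], pts[, 2], pts[, 3], pts[, 4])),
              1e-6)
    # mirror reflection negates the dihedral
    mir <- pts * c(1, 1, -1)
    expect_lt(abs(dihedral_angle(mir[, 1], mir[, 2], mir[, 3], mir[, 4]) +
                    dihedral_angle(pts[, 1], pts[, 2], pts[, 3], pts[, 4])) %% 360,
              1e-6)
    # reversing atom order preserves the dihedral magnitude and sign
    expect_equal(dihedral_angle(pts[, 4], pts[, 3], pts[, 2], pts[, 1]),
                 dihedral_angle(pts[, 1], pts[, 2], pts[, 3], pts[, 4]),
                 tolerance = 1e-9)
  }
})

test_that("collinear points make the dihedral undefined", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("difference coordinate is the antisymmetric distance difference", {
  expect_equal(difference_coordinate(2, 2), 0)
  expect_equal(difference_coordinate(1, 2.8), -1.8)
  expect_equal(difference_coordinate(3, 1), -difference_coordinate(1, 3))
  p <- c(0, 0, 0); q <- c(1, 1, 0); r <- c(0, 0, 2)
  expect_equal(difference_coordinate(dist3d(p, q), dist3d(p, r)),
               dist3d(p, q) - dist3d(p, r))
})

test_that("PDB snapshots parse fixed columns and report malformed input", {
  line <- "ATOM      1  SG  CYS A 797       1.000   2.000   3.000  1.00  0.00           S"
  s <- read_pdb_snapshot(c(line, "END"))
  expect_equal(nrow(s$atoms), 1)
  expect_equal(c(s$atoms$x, s$atoms$y, s$atoms$z), c(1, 2, 3))
  expect_equal(s$atoms$name, "SG")
  expect_equal(s$atoms$resno, 797L)

  expect_error(read_pdb_snapshot(c("REMARK nothing here", "END")), "empty input")
  bad <- sub("   1.000", "   x.000", line, fixed = TRUE)
  expect_error(read_pdb_snapshot(c(bad, "END")), "line 1")
})

test_that("snapshot write/read round-trips coordinates to PDB precision", {
  set.seed(14)
  atoms <- tibble::tibble(
    record = "ATOM", serial = 1:4, name = c("C1", "C2", "N1", "C3"),
    altloc = "", resname = "TOY", chain = "A", resno = 1:4, insert = "",
    x = round(rnorm(4, sd = 5), 3), y = round(rnorm(4, sd = 5), 3),
    z = round(rnorm(4, sd = 5), 3), element = c("C", "C", "N", "C"))
  snap <- structure(list(atoms = atoms, time = 1, replica = 1L),
                    class = "snapshot")
  back <- read_pdb_snapshot(write_pdb_snapshot(snap))
  expect_equal(back$atoms$x, atoms$x, tolerance = 1e-9)
  expect_equal(back$atoms$y, atoms$y, tolerance = 1e-9)
  expect_equal(back$atoms$z, atoms$z, tolerance = 1e-9)
})

test_that("toy fixtures realise their descriptor targets through the full path", {
  for (target in c(5.0, 3.917)) {
    snap <- read_pdb_snapshot(make_toy_snapshots(distance = target))
    d <- evaluate_descriptors(snap, descriptor_distance("d", "A.1.P1", "A.2.P2"))
    expect_lt(abs(d$d - target), 1e-3)
  }
  for (target in c(180, -55, 120, -178.25)) {
    snap <- read_pdb_snapshot(make_toy_snapshots(dihedral = target))
    phi <- evaluate_descriptors(
      snap, descriptor_dihedral("phi", "A.1.C1", "A.2.C2", "A.3.N1", "A.4.C3"))
    dd <- abs(phi$phi - target) %% 360
    expect_lt(min(dd, 360 - dd), 1e-3)
  }
  expect_error(make_toy_snapshots(distance = -1), "unrealizable")
})

test_that("evaluate_descriptors shapes output and flags unresolved selectors", {
  pdb <- make_toy_snapshots(distance = 4, dihedral = 90)
  snaps <- list(read_pdb_snapshot(pdb, time = 1),
                read_pdb_snapshot(pdb, time = 2),
                read_pdb_snapshot(pdb, time = 3))
  descs <- list(
    descriptor_distance("d", "A.5.P1", "A.6.P2"),
    descriptor_dihedral("phi", "A.1.C1", "A.2.C2", "A.3.N1", "A.4.C3"))
  fs <- evaluate_descriptors(snaps, descs)
  expect_equal(dim(fs), c(3L, 4L))
  expect_equal(names(fs), c("time", "replica", "d", "phi"))

  empty <- evaluate_descriptors(list(), descs)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("d", "phi") %in% names(empty)))

  expect_error(
    evaluate_descriptors(snaps, descriptor_distance("d", "A.99.XX", "A.5.P1")),
    "resolved to 0")
})

test_that("difference descriptors equal the two-distance composition", {
  pdb <- make_toy_snapshots(distance = 4, dihedral = 90)
  snap <- read_pdb_snapshot(pdb)
  fs <- evaluate_descriptors(snap, list(
    descriptor_difference("r", "A.1.C1", "A.2.C2", "A.1.C1", "A.3.N1"),
    descriptor_distance("d1", "A.1.C1", "A.2.C2"),
    descriptor_distance("d2", "A.1.C1", "A.3.N1")))
  expect_equal(fs$r, fs$d1 - fs$d2)
})

test_that("descriptor arity is enforced", {
  expect_error(descriptor_distance("d", "A.1.C1"), "2 atom selectors")
  expect_error(descriptor_dihedral("phi", "A.1.C1", "A.2.C2"), "4 atom")
})
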