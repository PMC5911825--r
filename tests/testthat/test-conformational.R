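two_state_features <- function(seed = 2, n_rep = 4, n = 5000, ...) {
  make_two_state_trajectory(
    two_state_model(n_replicas = n_rep, n_per_replica = n, ...), seed = seed)
}

test_that("pooling concatenates replicas and rejects mismatched columns", {
  reps <- lapply(1:4, function(r) {
    tibble::tibble(time = 1:30000, replica = r, s_cb = 0, dihedral = 0)
  })
  pooled <- pool_features(reps)
  expect_equal(nrow(pooled), 120000)
  expect_equal(sort(unique(pooled$replica)), 1:4)
  expect_identical(pool_features(reps[[1]]), reps[[1]])
  bad <- reps
  names(bad[[2]])[3] <- "distance"
  expect_error(pool_features(bad), "column mismatch")
})

test_that("Boltzmann inversion turns count ratios into free-energy gaps", {
  # two occupied bins with counts e:1 -> gap of exactly kT
  n1 <- 2718; n2 <- 1000
  f <- tibble::tibble(s_cb = c(rep(3.05, n1), rep(6.05, n2)),
                      dihedral = c(rep(-55, n1), rep(110, n2)))
  fes <- boltzmann_fes(f)
  vals <- sort(as.numeric(fes$values)[!is.na(as.numeric(fes$values))])
  expect_equal(length(vals), 2)
  expect_equal(vals[2] - vals[1], kT(300) * log(n1 / n2), tolerance = 1e-9)
  expect_equal(kT(300), 0.59616, tolerance = 1e-4)

  # record order and whole-dataset duplication leave the surface unchanged
  set.seed(10)
  g <- f[sample(nrow(f)), ]
  expect_equal(boltzmann_fes(g)$values, fes$values)
  expect_equal(boltzmann_fes(rbind(f, f))$values, fes$values)
})

test_that("default conformational binning covers 70 x 21 classes", {
  b <- bin_spec_2d()
  expect_equal(length(b$x) - 1, 70)
  expect_equal(length(b$y) - 1, 21)
  expect_equal(b$y[1], -157.5)
  expect_equal(b$y[length(b$y)], 157.5)
  # the exact-span alternative keeps the stated start
  b2 <- bin_spec_2d(dihedral_mode = "exact")
  expect_equal(b2$y[1], -160)
  f <- tibble::tibble(s_cb = c(5, 5), dihedral = c(-159, 10))
  expect_equal(attr(boltzmann_fes(f), "out_of_range"), 1)
})

test_that("reactive fractions are exact counts per replica and pooled", {
  f <- tibble::tibble(
    replica = rep(1:2, each = 5),
    s_cb = c(3.0, 3.0, 5.0, 3.8999, 3.9, 5.0, 5.0, 5.0, 3.0, 3.9001))
  rs <- reactive_fraction(f)
  expect_equal(rs$per_replica$n_reactive, c(3L, 1L))  # strict <, 3.9 excluded
  expect_equal(rs$pooled$n_reactive, 4L)
  expect_equal(rs$pooled$fraction, 0.4)
  # pooled fraction == count-weighted mean of per-replica fractions
  expect_equal(rs$pooled$fraction,
               sum(rs$per_replica$fraction * rs$per_replica$n_total) /
                 sum(rs$per_replica$n_total))

  all_close <- tibble::tibble(replica = 1, s_cb = rep(3, 7))
  expect_equal(reactive_fraction(all_close)$pooled$fraction, 1)
  all_far <- tibble::tibble(replica = 1, s_cb = rep(5, 7))
  expect_equal(reactive_fraction(all_far)$pooled$fraction, 0)
  expect_error(reactive_fraction(all_far[0, ]), "empty")

  # against a direct per-record oracle on simulated data
  tr <- two_state_features(seed = 6, n = 3000)
  rs2 <- reactive_fraction(tr)
  expect_identical(rs2$pooled$n_reactive, sum(tr$s_cb < 3.9))
})

test_that("state assignment labels the canonical basin geometries", {
  f <- tibble::tibble(replica = 1,
                      s_cb = c(3.5, 5.5, 8.0),
                      dihedral = c(-55, 110, 0))
  lab <- assign_states(f)
  expect_equal(lab$.state, c("a", "b", "other"))
  occ <- attr(lab, "occupancy")
  pooled <- occ[is.na(occ$replica), ]
  expect_equal(sum(pooled$occupancy), 1)

  overlapping <- list(state_definition("u", c(-90, 0)),
                      state_definition("v", c(-10, 50)))
  expect_error(assign_states(f, overlapping), "overlapping")
  expect_error(assign_states(f, list(state_definition("u", c(-90, 0)),
                                     state_definition("u", c(10, 50)))),
               "unique")
})

test_that("basin gaps follow -kT log occupancy ratios and antisymmetry", {
  counts <- c(a = 1000, b = 1000)
  expect_equal(basin_delta(counts), 0)
  expect_equal(basin_delta(c(a = 1000, b = exp(1) * 1000)), -kT(300),
               tolerance = 1e-9)
  expect_equal(basin_delta(counts, "a", "b"), -basin_delta(counts, "b", "a"))
  expect_error(basin_delta(c(a = 10, b = 0)), "zero population")
})

test_that("two-state trajectories recover their stationary basin gap", {
  # stationary occupancies 0.35 / 0.65
  m <- two_state_model(p_ab = 0.013, p_ba = 0.007, n_replicas = 4,
                       n_per_replica = 30000)
  expect_equal(stationary_occupancy(m), 0.35)
  tr <- make_two_state_trajectory(m, seed = 9)
  # half-plane dihedral states: no emission truncation, so the assigned
  # occupancy ratio estimates the hidden-state ratio directly
  halves <- list(state_definition("a", c(-180, 0)),
                 state_definition("b", c(1e-9, 180)))
  lab <- assign_states(tr, halves)
  occ_a <- mean(tr$state == "a")
  truth <- -kT(300) * log((1 - occ_a) / occ_a)
  expect_lt(abs(basin_delta(lab) - truth), 0.05)
})

test_that("parameter recovery holds across a grid of stationary occupancies", {
  for (pi_a in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    p_total <- 0.02
    m <- two_state_model(p_ab = p_total * (1 - pi_a), p_ba = p_total * pi_a,
                         n_replicas = 4, n_per_replica = 30000)
    tr <- make_two_state_trajectory(m, seed = round(1000 * pi_a))
    occ_a <- mean(tr$state == "a")
    se <- sqrt(pi_a * (1 - pi_a) * (2 / p_total - 1) / 120000)
    expect_lt(abs(occ_a - pi_a), 3 * se)
    halves <- list(state_definition("a", c(-180, 0)),
                   state_definition("b", c(1e-9, 180)))
    gap <- basin_delta(assign_states(tr, halves))
    truth <- -kT(300) * log((1 - occ_a) / occ_a)
    expect_lt(abs(gap - truth), 0.05)
  }
})

test_that("distance-dihedral coupling is perfect without noise and null under shuffles", {
  f <- tibble::tibble(replica = 1,
                      s_cb = rep(c(3.5, 6.0), each = 50),
                      dihedral = rep(c(-55, 110), each = 50),
                      .state = rep(c("a", "b"), each = 50))
  cr <- coupling_report(f)
  expect_equal(abs(cr$r_point_biserial), 1, tolerance = 1e-12)
  expect_lt(cr$p_permutation, 0.01)

  # shuffled labels: r compatible with zero
  set.seed(44)
  g <- f
  g$.state <- sample(g$.state)
  crs <- coupling_report(g)
  expect_gt(crs$p_permutation, 0.001)

  single <- f
  single$.state <- "a"
  expect_error(coupling_report(single), "one state")
})

test_that("coupling strength matches the closed-form point-biserial value", {
  m <- two_state_model(p_ab = 0.01, p_ba = 0.01, n_replicas = 4,
                       n_per_replica = 10000,
                       emissions = tibble::tibble(
                         state = c("a", "b"), dist_mean = c(3.5, 5.8),
                         dist_sd = 0.4, dihedral_mean = c(-55, 110),
                         dihedral_sd = c(10, 10)))
  tr <- make_two_state_trajectory(m, seed = 13)
  tr$.state <- tr$state  # use ground-truth labels for the closed form
  cr <- coupling_report(tr, n_perm = 200)
  p1 <- mean(tr$state == "b")
  r_exp <- point_biserial_closed_form(3.5, 5.8, 0.4, 0.4, p1)
  expect_lt(abs(cr$r_point_biserial - r_exp), 3 * (1 - r_exp^2) / sqrt(40000))
  expect_gt(cr$co_occurrence, 0.9)  # distance crosses 4.5 A at state switches
})

test_that("hydrogen-bond occupancy uses an inclusive cutoff", {
  f <- tibble::tibble(replica = rep(1:2, each = 3),
                      hbond = c(2.9, 2.9, 2.9, 6, 6, 3.5))
  occ <- hbond_occupancy(f)
  expect_equal(occ$fraction[which(occ$replica == 1)], 1)
  expect_equal(occ$fraction[which(occ$replica == 2)], 1 / 3)  # 3.5 <= 3.5
  expect_equal(occ$fraction[which(is.na(occ$replica))], 4 / 6)
  expect_error(hbond_occupancy(f[0, ]), "empty")
})
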