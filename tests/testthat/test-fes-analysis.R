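fes_from_matrix <- function(V, temperature = 300) {
  free_energy_surface(V, axes = list(x = list(centers = seq_len(nrow(V))),
                                     y = list(centers = seq_len(ncol(V)))),
                      temperature = temperature)
}

test_that("basin finding handles single wells, two wells, and flat plateaus", {
  x <- seq(-1, 1, length.out = 21)
  para <- fes_from_matrix(outer(x, x, function(a, b) a^2 + b^2))
  m <- find_minima(para)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$ix, m$iy), c(11L, 11L))
  expect_false(m$degenerate)

  flat <- fes_from_matrix(matrix(1, 5, 5))
  mf <- find_minima(flat)
  expect_equal(nrow(mf), 1)
  expect_true(mf$degenerate)

  s <- cached_reference_surface()
  xs <- seq(1.7, 3.7, by = 0.05)
  ys <- seq(-2.3, 2.9, by = 0.05)
  V <- outer(xs, ys, function(a, b) surface_potential(s, a, b))
  fes <- free_energy_surface(V, axes = list(x = list(centers = xs),
                                            y = list(centers = ys)))
  m2 <- find_minima(fes)
  two <- m2[order(m2$A_min)[1:2], ]
  expect_lt(min(abs(two$center_x - 1.9) + abs(two$center_y + 1.5)), 0.1)
  expect_lt(min(abs(two$center_x - 3.4) + abs(two$center_y - 2.0)), 0.1)
})

test_that("minimax path equals exhaustive enumeration on random small grids", {
  set.seed(123)
  for (i in 1:200) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    V <- matrix(sample(1:9, nr * nc, replace = TRUE), nr, nc)
    start <- c(sample(nr, 1), sample(nc, 1))
    end <- c(sample(nr, 1), sample(nc, 1))
    fes <- fes_from_matrix(V)
    Vr <- fes$values  # min-referenced copy the path actually sees
    p <- minimax_path(fes, start, end)
    oracle <- threshold_minimax(Vr, start, end)
    expect_equal(max(p$A), oracle$max)
    expect_equal(sum(p$A), oracle$sum)
    if (nr * nc <= 12) {
      bf <- brute_force_minimax(Vr, start, end)
      expect_equal(oracle$max, bf$max)
      expect_equal(oracle$sum, bf$sum)
    }
    # returned path is valid: 8-connected, starts and ends correctly
    expect_equal(c(p$ix[1], p$iy[1]), start)
    expect_equal(c(p$ix[nrow(p)], p$iy[nrow(p)]), end)
    if (nrow(p) > 1) {
      expect_true(all(abs(diff(p$ix)) <= 1 & abs(diff(p$iy)) <= 1))
    }
  }
})

test_that("minimax bottleneck is symmetric in its endpoints", {
  set.seed(77)
  for (i in 1:20) {
    V <- matrix(runif(36), 6, 6)
    fes <- fes_from_matrix(V)
    p1 <- minimax_path(fes, c(1, 1), c(6, 6))
    p2 <- minimax_path(fes, c(6, 6), c(1, 1))
    expect_equal(max(p1$A), max(p2$A))
  }
})

test_that("single-cell paths and masked disconnections behave as specified", {
  V <- matrix(1:9, 3, 3)
  fes <- fes_from_matrix(V)
  p <- minimax_path(fes, c(2, 2), c(2, 2))
  expect_equal(nrow(p), 1)
  expect_equal(activation_reaction_energies(p)$delta_A_act, 0)

  Vm <- matrix(1, 3, 3)
  Vm[, 2] <- NA  # full masked column disconnects left from right
  fesm <- fes_from_matrix(Vm)
  expect_error(minimax_path(fesm, c(1, 1), c(1, 3)), "disconnected")
})

test_that("activation/reaction energies are simple path arithmetic", {
  p <- structure(
    tibble::tibble(position = 1:3, ix = 1:3, iy = 1L,
                   center_x = 1:3, center_y = 1, A = c(0, 5, -3)),
    class = c("reaction_path", class(tibble::tibble())))
  e <- activation_reaction_energies(p)
  expect_equal(e$delta_A_act, 5)
  expect_equal(e$delta_A_reac, -3)
  # A(TS) >= max(A(start), A(end)) always
  expect_gte(e$A_ts, max(p$A[1], p$A[3]))

  down <- structure(
    tibble::tibble(position = 1:3, ix = 1:3, iy = 1L,
                   center_x = 1:3, center_y = 1, A = c(2, 1, 0)),
    class = c("reaction_path", class(tibble::tibble())))
  expect_equal(activation_reaction_energies(down)$delta_A_act, 0)
})

test_that("adding a constant to the surface leaves the energetics unchanged", {
  set.seed(55)
  V <- matrix(runif(30, 0, 5), 5, 6)
  f1 <- fes_from_matrix(V)
  f2 <- fes_from_matrix(V + 7.3)  # min-referencing removes the constant
  p1 <- minimax_path(f1, c(1, 1), c(5, 6))
  p2 <- minimax_path(f2, c(1, 1), c(5, 6))
  expect_equal(activation_reaction_energies(p1),
               activation_reaction_energies(p2))
})

test_that("1D profile deltas match quadrature and flag missing basins", {
  s1 <- cached_1d_double_well()
  xs <- seq(-1.2, 1.2, by = 0.01)
  fes <- free_energy_surface(surface_potential(s1, xs),
                             axes = list(x = list(centers = xs)))
  m <- find_minima(fes)
  a <- m$basin[which.min(abs(m$center_x + 0.5))]
  b <- m$basin[which.min(abs(m$center_x - 0.5))]
  # dense evaluation of U: min-to-min equals the quadrature delta A within
  # the anharmonic correction left by the curvature-matched construction
  expect_lt(abs(profile_delta(fes, a, b) - attr(s1, "ground_truth")$delta_A),
            0.1)

  sym <- free_energy_surface(xs^4 - 0.5 * xs^2,
                             axes = list(x = list(centers = xs)))
  msym <- find_minima(sym)
  expect_equal(profile_delta(sym, 1, 2), 0, tolerance = 1e-9)

  single <- free_energy_surface(xs^2, axes = list(x = list(centers = xs)))
  expect_error(profile_delta(single), "missing basin")
})

test_that("trapezoidal TI integrates linear gradients exactly", {
  sched <- lambda_schedule_16()
  expect_equal(length(sched), 16)
  expect_equal(sched[2] - sched[1], 0.066)

  # constant gradient g -> g * (lambda_n - lambda_1)
  g <- 3.7
  grads <- lapply(sched, function(l) rep(g, 30))
  out <- ti_integrate(grads, schedule = sched)
  expect_equal(out$delta_A, g * (0.995 - 0.005), tolerance = 1e-12)

  # gradient 2*lambda -> lambda_n^2 - lambda_1^2 (trapezoid exact for linear)
  grads2 <- lapply(sched, function(l) rep(2 * l, 30))
  out2 <- ti_integrate(grads2, schedule = sched)
  expect_equal(out2$delta_A, 0.995^2 - 0.005^2, tolerance = 1e-12)

  # burn-in discards the first third of each series
  grads3 <- lapply(sched, function(l) c(rep(1e6, 10), rep(g, 20)))
  out3 <- ti_integrate(grads3, schedule = sched, burn_in_fraction = 1/3)
  expect_equal(out3$delta_A, g * 0.99, tolerance = 1e-9)

  expect_error(ti_integrate(grads[1:5], schedule = sched), "mismatch")
  expect_error(lambda_schedule(c(0.5, 0.4)), "increasing")
  expect_error(lambda_schedule(c(0, 0.5)), "0, 1")
})

test_that("a lambda schedule parses from printed text", {
  txt <- "0.005, 0.071, 0.137, 0.203, 0.269, 0.335, 0.401, 0.467, 0.533, 0.599, 0.665, 0.731, 0.797, 0.863, 0.929, 0.995"
  sched <- lambda_schedule(txt)
  expect_equal(length(sched), 16)
  expect_equal(as.numeric(sched), as.numeric(lambda_schedule_16()),
               tolerance = 1e-12)
})

test_that("replicate aggregation reports mean, SD and SEM", {
  agg <- aggregate_replicates(c(1, 1, 1))
  expect_equal(c(agg$mean, agg$sd, agg$sem), c(1, 0, 0))

  agg2 <- aggregate_replicates(c(7.7, 7.8, 7.9), mode = "sd")
  expect_equal(agg2$mean, 7.8)
  expect_equal(agg2$sd, 0.1)
  expect_equal(agg2$uncertainty, 0.1)

  set.seed(31)
  sems <- replicate(400, aggregate_replicates(rnorm(10))$sem)
  # SEM of N(0,1) with n = 10 concentrates near 1/sqrt(10)
  expect_lt(abs(mean(sems) - 1 / sqrt(10)), 3 * sd(sems) / sqrt(400))

  one <- aggregate_replicates(5)
  expect_equal(one$sd, 0)
  expect_true(attr(one, "single_replicate"))
  expect_error(aggregate_replicates(numeric(0)), "empty")
})
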