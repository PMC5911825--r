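make_gaussian_window <- function(center, k, n, seed, sd = NULL) {
  set.seed(seed)
  if (is.null(sd)) sd <- sqrt(kT(300) / (2 * k))
  umbrella_window(harmonic_bias(center, k),
                  tibble::tibble(step = seq_len(n),
                                 value_x = rnorm(n, center, sd)))
}

test_that("window grids reproduce ladder and grid counts in x-major order", {
  g2 <- build_window_grid(grid_spec(3.6, 1.8, -0.1), grid_spec(2.8, -2.2, -0.2))
  expect_equal(nrow(g2), 494)
  expect_equal(g2$center_x[1:2], c(3.6, 3.5))  # x varies fastest
  expect_equal(g2$center_y[1], 2.8)
  g1 <- build_window_grid(grid_spec(1, -1, -0.1))
  expect_equal(nrow(g1), 21)
  expect_equal(nrow(build_window_grid(grid_spec(0, 0, 0.1))), 1)
  expect_error(grid_spec(0, 1, -0.1), "sign")
})

test_that("k = 0 single-window WHAM equals Boltzmann inversion exactly", {
  set.seed(5)
  v <- rnorm(3000, 0, 0.3)
  w0 <- umbrella_window(harmonic_bias(0, 0),
                        tibble::tibble(step = 1:3000, value_x = v))
  edges <- bin_edges(-1, 1, 0.1)
  wr <- wham(w0, bins = edges)
  h <- histogram_grid(v, edges)
  P <- h$counts / sum(h$counts)
  A <- -kT(300) * log(P)
  A[!is.finite(A)] <- NA
  A <- A - min(A, na.rm = TRUE)
  expect_equal(as.numeric(wr$fes$values), as.numeric(A))
  expect_true(wr$converged)
})

test_that("offset gauge invariance: shifting window data, not bias form, matters", {
  # permuting window order leaves the FES identical
  win <- lapply(1:6, function(i)
    make_gaussian_window(-0.5 + 0.2 * (i - 1), 50, 2000, seed = 100 + i))
  edges <- bin_edges(-0.8, 0.8, 0.05)
  a <- wham(win, bins = edges)
  b <- wham(win[c(4, 2, 6, 1, 3, 5)], bins = edges)
  # identical up to the solver's 1e-7 kcal/mol offset tolerance
  expect_equal(a$fes$values, b$fes$values, tolerance = 1e-6)
  # offsets are reported relative to the first window
  expect_equal(a$offsets$f[1], 0)
})

test_that("1D double-well free-energy difference matches the quadrature oracle", {
  s1 <- cached_1d_double_well()
  truth <- attr(s1, "ground_truth")
  win <- generate_us_dataset(s1, grid_spec(1, -1, -0.1), k = 100,
                             n_per_window = 5e4, seed = 7)
  wr <- wham(win)
  expect_true(wr$converged)
  m <- find_minima(wr$fes)
  from <- m$basin[which.min(abs(m$center_x + 0.5))]
  to <- m$basin[which.min(abs(m$center_x - 0.5))]
  dA <- m$A_min[m$basin == to] - m$A_min[m$basin == from]
  expect_lt(abs(dA - truth$delta_A), 0.1)
})

test_that("flat-potential sampling recovers a flat profile within bootstrap error", {
  flat <- flat_1d_surface()
  win <- generate_us_dataset(flat, grid_spec(1, -1, -0.1), k = 100,
                             n_per_window = 2000, seed = 3)
  wr <- wham(win, n_boot = 50, seed = 11, keep_boot = TRUE)
  A <- wr$fes$values
  dev <- A - mean(A, na.rm = TRUE)
  bdev <- sweep(wr$boot_A, 2, colMeans(wr$boot_A, na.rm = TRUE))
  se_dev <- apply(bdev, 1, sd, na.rm = TRUE)
  expect_lt(max(abs(dev) / pmax(se_dev, 1e-9), na.rm = TRUE), 3)
})

test_that("unconverged WHAM is flagged, never silent", {
  win <- lapply(1:3, function(i)
    make_gaussian_window(-0.2 + 0.2 * (i - 1), 50, 500, seed = 40 + i))
  wr <- wham(win, bins = bin_edges(-0.5, 0.5, 0.05), tolerance = 0,
             max_iter = 3)
  expect_false(wr$converged)
  expect_equal(wr$iterations, 3)
})

test_that("a window entirely outside the grid names itself in the error", {
  w_far <- make_gaussian_window(10, 100, 100, seed = 1)
  w_in <- make_gaussian_window(0, 100, 100, seed = 2)
  expect_error(wham(list(w_in, w_far), bins = bin_edges(-0.5, 0.5, 0.05)),
               "window 2")
})

test_that("the surface is min-referenced and masks exactly the empty bins", {
  win <- lapply(1:5, function(i)
    make_gaussian_window(-0.4 + 0.2 * (i - 1), 80, 1500, seed = 60 + i))
  edges <- bin_edges(-0.7, 0.7, 0.05)
  wr <- wham(win, bins = edges)
  expect_true(all(wr$fes$values >= 0, na.rm = TRUE))
  expect_equal(min(wr$fes$values, na.rm = TRUE), 0)
  pooled <- unlist(lapply(win, function(w) w$samples$value_x))
  h <- histogram_grid(pooled, edges)
  expect_equal(is.na(as.numeric(wr$fes$values)), as.numeric(h$counts) == 0)
})

test_that("window overlap matches trivial cases and the Gaussian min-density integral", {
  w1 <- make_gaussian_window(0, 50, 5000, seed = 1)
  w2 <- w1
  ov_same <- window_overlap(list(w1, w2), bins = bin_edges(-1, 1, 0.02))
  expect_equal(ov_same$matrix[1, 2], 1)

  w3 <- make_gaussian_window(0, 50, 5000, seed = 2, sd = 0.05)
  w4 <- make_gaussian_window(5, 50, 5000, seed = 3, sd = 0.05)
  ov_dis <- window_overlap(list(w3, w4), bins = bin_edges(-1, 6, 0.05))
  expect_equal(ov_dis$matrix[1, 2], 0)

  # unit Gaussians one sigma apart: overlap = 2 Phi(-1/2)
  set.seed(9)
  g1 <- umbrella_window(harmonic_bias(0, 1),
                        tibble::tibble(step = 1:2e5, value_x = rnorm(2e5, 0, 1)))
  g2 <- umbrella_window(harmonic_bias(1, 1),
                        tibble::tibble(step = 1:2e5, value_x = rnorm(2e5, 1, 1)))
  ov <- window_overlap(list(g1, g2), bins = bin_edges(-5, 6, 0.1))
  expect_lt(abs(ov$matrix[1, 2] - 2 * pnorm(-0.5)), 0.02)
})

test_that("normality reporting has the nominal type-I error and real power", {
  win <- lapply(1:200, function(i) make_gaussian_window(0, 50, 200, seed = i))
  rep <- normality_report(win, alpha = 0.05)
  frac <- attr(rep, "pass_fraction")
  expect_lt(abs(frac - 0.95), 3 * sqrt(0.95 * 0.05 / 200))

  set.seed(1)
  w_unif <- umbrella_window(harmonic_bias(0.5, 10),
                            tibble::tibble(step = 1:1000, value_x = runif(1000)))
  expect_false(normality_report(list(w_unif))$pass)

  w_tiny <- umbrella_window(harmonic_bias(0, 10),
                            tibble::tibble(step = 1:3, value_x = rnorm(3)))
  expect_error(normality_report(list(w_tiny)), "window 1")
})

test_that("convergence blocks are stable for stationary data and exact for identical blocks", {
  s1 <- cached_1d_double_well()
  win <- generate_us_dataset(s1, grid_spec(1, -1, -0.1), k = 100,
                             n_per_window = 3000, seed = 17)
  extract <- function(wr) {
    m <- find_minima(wr$fes)
    m$A_min[which.min(abs(m$center_x - 0.5))] -
      m$A_min[which.min(abs(m$center_x + 0.5))]
  }
  cb <- convergence_blocks(win, c(1800, 2400, 3000), extract)
  expect_equal(nrow(cb), 3)
  expect_lt(attr(cb, "sd"), 0.15)
  expect_lt(abs(attr(cb, "mean") - attr(s1, "ground_truth")$delta_A), 0.2)

  # blocks with identical empirical distributions (second half duplicates
  # the first) give identical estimates -> SD exactly 0
  win_dup <- lapply(1:3, function(i) {
    w <- make_gaussian_window(-0.2 + 0.2 * (i - 1), 50, 400, seed = 70 + i)
    w$samples <- tibble::tibble(step = 1:800,
                                value_x = rep(w$samples$value_x, 2))
    w
  })
  cb2 <- convergence_blocks(win_dup, c(400, 800),
                            function(wr) max(wr$fes$values, na.rm = TRUE),
                            bins = bin_edges(-0.6, 0.6, 0.05))
  expect_equal(attr(cb2, "sd"), 0)

  expect_error(convergence_blocks(win, c(100, 5000), extract), "block")
})
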