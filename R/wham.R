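# WHAM solver: combine biased window histograms into one unbiased FES.
#
# Notation (all energies in kT units internally):
#   c_wb  bias energy of window w evaluated at bin centre b
#   g_w   window free-energy offset f_w / kT, gauge g_1 = 0
#   N_b   total count in bin b, n_w samples of window w (in range)
# Self-consistent equations:
#   p_b       = N_b / sum_w n_w exp(g_w - c_wb)
#   exp(-g_w) = sum_b p_b exp(-c_wb)
# These are the stationary point of the convex likelihood
#   F(g) = -sum_w n_w g_w + sum_b N_b log sum_w n_w exp(g_w - c_wb),
# which we minimise first (BFGS, analytic gradient) and then polish with
# the plain self-consistent iteration until the offset-change tolerance is
# met, so the convergence contract is stated in terms of the iteration.

.default_wham_bins <- function(windows, refine = 4L) {
  centers <- do.call(rbind, lapply(windows, function(w) w$bias$center))
  d <- ncol(centers)
  out <- list()
  for (j in seq_len(d)) {
    cs <- sort(unique(centers[, j]))
    spacing <- if (length(cs) > 1) min(diff(cs)) else 0.1
    width <- spacing / refine
    out[[c("x", "y")[j]]] <- seq(min(cs) - spacing, max(cs) + spacing,
                                 by = width)
  }
  out
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Histograms every window on a common grid, then finds the self-consistent
#' unbiased bin probabilities and per-window free-energy offsets. The
#' solution is obtained by minimising the convex WHAM likelihood (BFGS with
#' analytic gradient) followed by self-consistent iteration until the
#' maximum offset change per sweep is at most `tolerance`; if `max_iter`
#' sweeps do not reach it the result is flagged unconverged (never
#' silently). Bins with zero total count are masked, not pseudo-counted.
#'
#' @param windows List of [umbrella_window()] objects (>= 1).
#' @param bins `NULL` (default: the window-centre grid refined `refine`
#'   times per axis, extended one window spacing beyond the outermost
#'   centres), a numeric edge vector (1D), or `list(x =, y =)` of edges.
#' @param refine Default-bin refinement factor per axis (default 4; WHAM
#'   evaluates each window's bias at bin centres, so bins must be fine
#'   enough that a stiff restraint varies little across one bin).
#' @param temperature Temperature in kelvin.
#' @param tolerance Convergence tolerance on the maximum per-sweep change of
#'   any offset f_i, kcal mol^-1.
#' @param max_iter Maximum self-consistent sweeps.
#' @param n_boot Number of Bayesian-bootstrap resamples (Dirichlet weights
#'   over each window's samples) for per-bin FES standard errors; 0 = none.
#'   Weights are drawn per block of `boot_block` consecutive samples so the
#'   error estimate covers the sampler's autocorrelation.
#' @param seed Seed for the bootstrap resampling (required if `n_boot` > 0).
#' @param boot_block Block length for the Bayesian bootstrap (default 50).
#' @param keep_boot Keep the per-resample min-referenced surfaces in
#'   `boot_A` (bins x resamples) for downstream uncertainty propagation.
#' @return A `wham_result`: list with `fes` (a [free_energy_surface]),
#'   `offsets` tibble (`window`, `f`), `iterations`, `converged`,
#'   `tolerance`, and (with bootstrap) `fes_se`, an array of per-bin
#'   standard errors.
#' @export
wham <- function(windows, bins = NULL, temperature = 300, tolerance = 1e-7,
                 max_iter = 1e5, n_boot = 0, seed = NULL, refine = 4L,
                 boot_block = 50, keep_boot = FALSE) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1)
  d <- length(windows[[1]]$bias$center)
  if (is.null(bins)) bins <- .default_wham_bins(windows, refine = refine)
  if (is.numeric(bins)) bins <- list(x = bins)
  stopifnot(length(bins) == d)
  kt <- kT(temperature)

  nx <- length(bins[[1]]) - 1L
  ny <- if (d == 2L) length(bins[[2]]) - 1L else 1L
  B <- nx * ny
  W <- length(windows)
  cx <- .centers(bins[[1]])
  centers_mat <- if (d == 2L) {
    cy <- .centers(bins[[2]])
    cbind(rep(cx, times = ny), rep(cy, each = nx))
  } else {
    matrix(cx, ncol = 1)
  }

  Nwb <- matrix(0, W, B)
  for (w in seq_len(W)) {
    h <- histogram_grid(.window_values(windows[[w]]), bins)
    cnt <- as.numeric(h$counts)
    if (sum(cnt) == 0)
      stop(sprintf("window %d: all samples fall outside the WHAM grid", w))
    Nwb[w, ] <- cnt
  }
  Cwb <- matrix(0, W, B)  # bias energies / kT
  for (w in seq_len(W)) Cwb[w, ] <- bias_energy(windows[[w]]$bias, centers_mat) / kt

  sol <- .wham_solve(Nwb, Cwb, tolerance / kt, max_iter)
  fes <- .wham_fes(sol$p, Nwb, bins, d, nx, ny, kt, temperature)
  out <- structure(list(
    fes = fes,
    offsets = tibble::tibble(window = seq_len(W), f = kt * sol$g),
    iterations = sol$iterations,
    converged = sol$converged,
    tolerance = tolerance,
    temperature = temperature
  ), class = "wham_result")

  if (n_boot > 0) {
    if (is.null(seed)) stop("bootstrap requires a seed")
    boot_A <- array(NA_real_, c(B, n_boot))
    for (r in seq_len(n_boot)) {
      set.seed(derive_seed(seed, r))
      Nwb_r <- matrix(0, W, B)
      for (w in seq_len(W)) {
        vals <- .window_values(windows[[w]])
        m <- nrow(vals)
        nb <- ceiling(m / boot_block)
        bw <- stats::rexp(nb)            # Dirichlet weights over blocks
        bw <- bw / sum(bw) * nb
        wt <- bw[ceiling(seq_len(m) / boot_block)]
        Nwb_r[w, ] <- .weighted_counts(vals, bins, wt, nx, ny)
      }
      sol_r <- .wham_solve(Nwb_r, Cwb, tolerance / kt, max_iter,
                           g0 = sol$g, skip_bfgs = TRUE)
      Nb_r <- colSums(Nwb_r)
      p_r <- sol_r$p
      p_r[Nb_r == 0] <- NA
      p_r <- p_r / sum(p_r, na.rm = TRUE)
      A_r <- -kt * log(p_r)
      boot_A[, r] <- A_r - min(A_r, na.rm = TRUE)
    }
    se <- apply(boot_A, 1, sd, na.rm = TRUE)
    out$fes_se <- if (d == 2L) matrix(se, nx, ny) else se
    if (keep_boot) out$boot_A <- boot_A
  }
  out
}

.weighted_counts <- function(vals, bins, wt, nx, ny) {
  ix <- .bin_index(vals[, 1], bins[[1]])
  if (length(bins) == 2L) {
    iy <- .bin_index(vals[, 2], bins[[2]])
    ok <- !is.na(ix) & !is.na(iy)
    lin <- ix[ok] + (iy[ok] - 1L) * nx
  } else {
    ok <- !is.na(ix)
    lin <- ix[ok]
  }
  out <- numeric(nx * ny)
  agg <- rowsum(wt[ok], lin)
  out[as.integer(rownames(agg))] <- agg
  out
}

# core solver in kT units; tol_g is the tolerance on max |delta g|
.wham_solve <- function(Nwb, Cwb, tol_g, max_iter, g0 = NULL,
                        skip_bfgs = FALSE) {
  W <- nrow(Nwb)
  Nb <- colSums(Nwb)
  nw <- rowSums(Nwb)
  keep <- Nb > 0
  lognw <- log(nw)
  g <- if (is.null(g0)) rep(0, W) else g0

  if (W > 1 && !skip_bfgs) {
    # g stays O(30) and c_wb >= 0, so the plain exponentials cannot
    # overflow and BLAS products beat a log-sum-exp formulation
    expCk <- exp(-Cwb[, keep, drop = FALSE])
    Nk <- Nb[keep]
    negll <- function(gfree) {
      gg <- c(0, gfree)
      D <- as.numeric(crossprod(expCk, nw * exp(gg)))
      sum(Nk * log(D)) - sum(nw * gg)
    }
    grad <- function(gfree) {
      gg <- c(0, gfree)
      eg <- nw * exp(gg)
      D <- as.numeric(crossprod(expCk, eg))
      gfull <- eg * as.numeric(expCk %*% (Nk / D)) - nw
      gfull[-1]
    }
    fit <- optim(g[-1], negll, grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))
    g <- c(0, fit$par)
  }

  # self-consistent polish (the convergence contract)
  iterations <- 0L
  converged <- FALSE
  expC <- exp(-Cwb)                      # W x B
  repeat {
    denom <- as.numeric(crossprod(expC, nw * exp(g)))  # sum_w n_w e^{g_w - c_wb}
    p <- ifelse(denom > 0, Nb / denom, 0)
    z <- as.numeric(expC %*% p)                        # sum_b p_b e^{-c_wb}
    g_new <- -log(z)
    g_new <- g_new - g_new[1]
    delta <- max(abs(g_new - g))
    g <- g_new
    iterations <- iterations + 1L
    if (delta <= tol_g) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  denom <- as.numeric(crossprod(expC, nw * exp(g)))
  p <- ifelse(denom > 0, Nb / denom, 0)
  list(g = g, p = p, iterations = iterations, converged = converged)
}

.wham_fes <- function(p, Nwb, bins, d, nx, ny, kt, temperature) {
  Nb <- colSums(Nwb)
  p[Nb == 0] <- NA
  p <- p / sum(p, na.rm = TRUE)
  A <- -kt * log(p)
  A <- A - min(A, na.rm = TRUE)
  values <- if (d == 2L) matrix(A, nx, ny) else A
  free_energy_surface(
    values,
    axes = lapply(bins, function(e) list(edges = e, centers = .centers(e))),
    temperature = temperature
  )
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("<wham_result> %s after %d iterations (tol %.1e kcal/mol)\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$iterations, x$tolerance))
  print(x$fes)
  invisible(x)
}

#' @method glance wham_result
#' @export
glance.wham_result <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 tolerance = x$tolerance, temperature = x$temperature,
                 n_windows = nrow(x$offsets),
                 n_bins_masked = sum(is.na(x$fes$values)))
}

#' Pairwise histogram overlap between umbrella windows
#'
#' Overlap coefficient `sum_b min(p_i(b), p_j(b))` of the normalised window
#' histograms, in `[0, 1]` (1 for identical sampling, 0 for disjoint
#' support). Adjacent window pairs (centres one grid spacing apart) with
#' overlap below `threshold` are flagged, since gaps between neighbouring
#' windows are what break WHAM.
#'
#' @param windows List of [umbrella_window()] (>= 2).
#' @param bins As in [wham()].
#' @param threshold Flagging threshold for adjacent pairs.
#' @return A list with `matrix` (symmetric overlap matrix) and `report`
#'   (tibble of adjacent pairs with `overlap` and `flag`).
#' @export
window_overlap <- function(windows, bins = NULL, threshold = 0.05) {
  stopifnot(length(windows) >= 2)
  if (is.null(bins)) bins <- .default_wham_bins(windows)
  if (is.numeric(bins)) bins <- list(x = bins)
  W <- length(windows)
  P <- matrix(0, W, prod(vapply(bins, function(e) length(e) - 1L, 1L)))
  for (w in seq_len(W)) {
    h <- histogram_grid(.window_values(windows[[w]]), bins)
    cnt <- as.numeric(h$counts)
    P[w, ] <- if (sum(cnt) > 0) cnt / sum(cnt) else 0
  }
  M <- matrix(1, W, W)
  for (i in seq_len(W - 1)) {
    for (j in (i + 1):W) {
      ov <- sum(pmin(P[i, ], P[j, ]))
      M[i, j] <- M[j, i] <- ov
    }
  }
  centers <- do.call(rbind, lapply(windows, function(w) w$bias$center))
  dmat <- as.matrix(stats::dist(centers))
  if (any(dmat > 0)) {
    spacing <- min(dmat[dmat > 0])
    adj <- which(abs(dmat - spacing) < 1e-9 & upper.tri(dmat), arr.ind = TRUE)
  } else {
    adj <- matrix(integer(0), 0, 2)  # coincident centres: no adjacency
  }
  report <- tibble::tibble(
    window_i = adj[, 1], window_j = adj[, 2],
    overlap = M[adj],
    flag = M[adj] < threshold
  )
  list(matrix = M, report = report)
}

#' Per-window normality check of the sampled reaction coordinate
#'
#' Shapiro-Wilk test on each biased coordinate of every window (the usual
#' umbrella-sampling sanity check that each restrained coordinate is
#' approximately Gaussian about its bias centre). Windows with more than
#' 5000 samples are tested on a deterministic 5000-sample subsample (the
#' test statistic is undefined above that size).
#'
#' @param windows List of [umbrella_window()].
#' @param alpha Significance level for the pass flag.
#' @return A tibble (`window`, `coord`, `n`, `statistic`, `p_value`,
#'   `pass`) with attribute `pass_fraction`.
#' @export
normality_report <- function(windows, alpha = 0.05) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  rows <- list()
  for (w in seq_along(windows)) {
    vals <- .window_values(windows[[w]])
    if (nrow(vals) < 8)
      stop(sprintf("window %d: too few samples (%d < 8) for a normality test",
                   w, nrow(vals)))
    for (j in seq_len(ncol(vals))) {
      v <- vals[, j]
      if (length(v) > 5000) {
        set.seed(derive_seed(8191, w * 10 + j))
        v <- sample(v, 5000)
      }
      st <- shapiro.test(v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        window = w, coord = windows[[w]]$bias$coord[j], n = nrow(vals),
        statistic = unname(st$statistic), p_value = st$p.value,
        pass = st$p.value >= alpha)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pass_fraction") <- mean(out$pass)
  out
}

#' Convergence of a WHAM-derived quantity over truncated sampling blocks
#'
#' Re-runs WHAM with every window truncated at each block end-point and
#' evaluates a summary extractor (for example the activation free energy)
#' per block; the headline value is the mean +/- SD over the listed blocks,
#' the convention used for time-block convergence reporting of
#' umbrella-sampling observables.
#'
#' @param windows List of [umbrella_window()].
#' @param block_ends Increasing sample counts at which to truncate each
#'   window (each > 0 and at most the shortest window length).
#' @param extractor Function mapping a `wham_result` to a single number.
#' @param ... Passed on to [wham()] (bins, temperature, tolerance, ...).
#' @return A tibble (`block_end`, `value`) with attributes `mean` and `sd`.
#' @export
convergence_blocks <- function(windows, block_ends, extractor, ...) {
  stopifnot(length(block_ends) >= 1, all(diff(block_ends) > 0))
  n_min <- min(vapply(windows, function(w) nrow(w$samples), 1L))
  if (any(block_ends < 1) || any(block_ends > n_min))
    stop("empty or over-long block: block ends must lie in [1, ", n_min, "]")
  vals <- vapply(block_ends, function(e) {
    trunc <- lapply(windows, function(w) {
      umbrella_window(w$bias, w$samples[seq_len(e), , drop = FALSE],
                      w$metadata)
    })
    extractor(wham(trunc, ...))
  }, 1)
  out <- tibble::tibble(block_end = block_ends, value = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- if (length(vals) > 1) sd(vals) else 0
  out
}
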