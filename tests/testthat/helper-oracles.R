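# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms (brute force, closed forms, quadrature).

# Exhaustive minimax-path oracle for tiny grids: enumerate all simple
# 8-connected paths, minimise (max energy, total energy) lexicographically.
# Energies must be > 0 so the total strictly grows (sound pruning). Only
# used on grids small enough to enumerate (<= ~3x4); larger cases use
# threshold_minimax below.
brute_force_minimax <- function(V, start, end) {
  nr <- nrow(V); nc <- ncol(V)
  best <- list(max = Inf, sum = Inf)
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(r, c, cur_max, cur_sum) {
    cur_max <- max(cur_max, V[r, c])
    cur_sum <- cur_sum + V[r, c]
    if (cur_max > best$max ||
        (cur_max == best$max && cur_sum > best$sum)) return()
    if (r == end[1] && c == end[2]) {
      best <<- list(max = cur_max, sum = cur_sum)
      return()
    }
    visited[r, c] <<- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && !visited[rr, cc])
        dfs(rr, cc, cur_max, cur_sum)
    }
    visited[r, c] <<- FALSE
  }
  dfs(start[1], start[2], -Inf, 0)
  best
}

# Polynomial independent oracle: the bottleneck is the smallest energy
# level at which start and end fall in one connected component of the
# thresholded grid (checked with igraph components, no union-find); the
# optimal total is then a node-weighted shortest path (edge weight =
# energy of the head cell) on the subgraph at that level, via igraph's
# Bellman-Ford/Dijkstra machinery.
threshold_minimax <- function(V, start, end) {
  nr <- nrow(V); nc <- ncol(V)
  lin <- function(r, c) r + (c - 1L) * nr
  s <- lin(start[1], start[2]); e <- lin(end[1], end[2])
  levels <- sort(unique(c(V[!is.na(V)])))
  edges_at <- function(keep) {
    out <- list()
    for (r in 1:nr) for (c in 1:nc) {
      if (!keep[r, c]) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && keep[rr, cc])
          out[[length(out) + 1]] <- c(lin(r, c), lin(rr, cc))
      }
    }
    if (length(out) == 0) matrix(integer(0), 0, 2) else do.call(rbind, out)
  }
  bneck <- NA_real_
  for (L in levels) {
    keep <- !is.na(V) & V <= L
    if (!keep[start[1], start[2]] || !keep[end[1], end[2]]) next
    ed <- edges_at(keep)
    g <- igraph::graph_from_edgelist(ed + 0, directed = TRUE)
    g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
    comp <- igraph::components(igraph::as_undirected(g))$membership
    if (s == e || (s <= length(comp) && e <= length(comp) &&
                   comp[s] == comp[e])) { bneck <- L; break }
  }
  if (is.na(bneck)) return(list(max = Inf, sum = Inf))
  if (s == e) return(list(max = V[start[1], start[2]],
                          sum = V[start[1], start[2]]))
  keep <- !is.na(V) & V <= bneck
  ed <- edges_at(keep)
  g <- igraph::graph_from_edgelist(ed + 0, directed = TRUE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  w <- as.numeric(V)[ed[, 2]]  # node weight of the head cell
  d <- igraph::distances(g, v = s, to = e, weights = w, mode = "out")
  list(max = bneck, sum = as.numeric(V)[s] + d[1, 1])
}

# Integrated autocorrelation time (initial positive sequence estimator);
# used to convert iid standard errors into effective ones for MCMC output.
tau_int <- function(x, max_lag = 200) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  pos <- which(a <= 0)
  if (length(pos) > 0) a <- a[seq_len(pos[1] - 1)]
  1 + 2 * sum(a)
}

# Closed-form point-biserial correlation for a two-component Gaussian
# mixture: labels y ~ Bernoulli(p1), x | y ~ N(mu_y, sd_y).
point_biserial_closed_form <- function(mu0, mu1, sd0, sd1, p1) {
  p0 <- 1 - p1
  num <- (mu1 - mu0) * sqrt(p0 * p1)
  var_tot <- p0 * sd0^2 + p1 * sd1^2 + p0 * p1 * (mu1 - mu0)^2
  num / sqrt(var_tot)
}

# The calibrated 2D reference surface is expensive to build; share one
# instance across test files.
.surface_cache <- new.env(parent = emptyenv())
cached_reference_surface <- function() {
  if (is.null(.surface_cache$s2d))
    .surface_cache$s2d <- make_reaction_surface(7.8, -10.3)
  .surface_cache$s2d
}
cached_1d_double_well <- function() {
  if (is.null(.surface_cache$s1d))
    .surface_cache$s1d <- make_reaction_surface(
      2.5, 0.5, reactant_center = -0.5, product_center = 0.5,
      width = 0.15, conf_k = 2)
  .surface_cache$s1d
}

flat_1d_surface <- function() {
  analytic_surface(
    tibble::tibble(center_x = c(-0.5, 0.5), depth = 0, width_x = 1),
    conf_k = 0, box = list(x = c(-1.5, 1.5)))
}

# random rigid motion: rotation matrix from QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
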