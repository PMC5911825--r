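#' Two-state Markov model for warhead conformational dynamics
#'
#' Hidden two-state Markov chain (states `a` and `b`) with Gaussian
#' emissions per state for the nucleophile-electrophile distance
#' (S-C-beta, Angstrom), the amide-phenyl rotation dihedral (degrees) and
#' an optional hydrogen-bond distance (Angstrom). State `a` emulates the
#' reactive arrangement (short S-C-beta distance, dihedral near -55 deg);
#' state `b` the non-reactive one (long distance, dihedral near +110 deg),
#' optionally stabilised by a short side-chain hydrogen bond to the
#' acrylamide carbonyl.
#'
#' The stationary occupancy of state `a` is
#' `p_ba / (p_ab + p_ba)` (closed form for a two-state chain).
#'
#' @param p_ab,p_ba Per-step switch probabilities, in `[0, 1]`.
#' @param emissions Data frame with columns `state` (`"a"`, `"b"`),
#'   `dist_mean`, `dist_sd`, `dihedral_mean`, `dihedral_sd`, and optionally
#'   `hbond_mean`, `hbond_sd`. Defaults mirror the reactive/non-reactive
#'   basin geometry: a = (3.5 +/- 0.4 A, -55 +/- 20 deg), b =
#'   (5.5 +/- 0.5 A, +110 +/- 7 deg), with the hydrogen bond short only in
#'   state b.
#' @param n_replicas Number of independent replicas (default 4).
#' @param n_per_replica Snapshots per replica (default 30000, i.e. a pooled
#'   total of 120000).
#' @param dt_ps Time between snapshots in ps (default 10).
#' @return A `two_state_model` object.
#' @export
two_state_model <- function(p_ab = 0.002, p_ba = 0.002,
                            emissions = NULL,
                            n_replicas = 4, n_per_replica = 30000,
                            dt_ps = 10) {
  stopifnot(p_ab >= 0, p_ab <= 1, p_ba >= 0, p_ba <= 1,
            n_replicas >= 1, n_per_replica >= 1)
  if (is.null(emissions)) {
    emissions <- tibble::tibble(
      state = c("a", "b"),
      dist_mean = c(3.5, 5.5), dist_sd = c(0.4, 0.5),
      dihedral_mean = c(-55, 110), dihedral_sd = c(20, 7),
      hbond_mean = c(5.0, 2.9), hbond_sd = c(0.6, 0.3)
    )
  }
  emissions <- tibble::as_tibble(emissions)
  need <- c("state", "dist_mean", "dist_sd", "dihedral_mean", "dihedral_sd")
  miss <- setdiff(need, names(emissions))
  if (length(miss) > 0) stop("emissions missing columns: ", paste(miss, collapse = ", "))
  sd_cols <- intersect(c("dist_sd", "dihedral_sd", "hbond_sd"), names(emissions))
  if (any(unlist(emissions[sd_cols]) <= 0)) stop("emission SDs must be > 0")
  stopifnot(setequal(emissions$state, c("a", "b")))
  structure(list(p_ab = p_ab, p_ba = p_ba, emissions = emissions,
                 n_replicas = n_replicas, n_per_replica = n_per_replica,
                 dt_ps = dt_ps),
            class = "two_state_model")
}

#' Stationary occupancy of state a
#'
#' @param model A [two_state_model()].
#' @return `p_ba / (p_ab + p_ba)`; 1 when both switch probabilities are 0
#'   (the chain never leaves its start state, taken as `a`).
#' @export
stationary_occupancy <- function(model) {
  stopifnot(inherits(model, "two_state_model"))
  if (model$p_ab + model$p_ba == 0) return(1)
  model$p_ba / (model$p_ab + model$p_ba)
}

# wrap angles into (-180, 180]; the +180 boundary maps to +180
wrap_angle <- function(theta) {
  w <- theta - 360 * ceiling((theta - 180) / 360)
  w[w == -180] <- 180
  w
}

#' Simulate feature-series trajectories from a two-state model
#'
#' Advances the hidden Markov chain one step per snapshot and draws
#' Gaussian emissions conditional on the state. The hidden state is kept
#' as a ground-truth column for testing. Dihedral emissions are wrapped
#' into (-180, 180].
#'
#' @param model A [two_state_model()].
#' @param seed Master seed; per-replica seeds derive via [derive_seed()].
#' @param start_state Initial state for every replica; `"stationary"`
#'   (default) draws it from the stationary distribution.
#' @return A tibble with columns `time` (ps), `replica`, `state`, `s_cb`,
#'   `dihedral`, and `hbond` when the model defines hydrogen-bond emissions.
#' @export
make_two_state_trajectory <- function(model, seed, start_state = "stationary") {
  stopifnot(inherits(model, "two_state_model"))
  if (missing(seed)) stop("an explicit seed is required")
  em <- model$emissions[match(c("a", "b"), model$emissions$state), ]
  has_hb <- all(c("hbond_mean", "hbond_sd") %in% names(em))
  pi_a <- stationary_occupancy(model)
  reps <- lapply(seq_len(model$n_replicas), function(r) {
    set.seed(derive_seed(seed, r))
    n <- model$n_per_replica
    s <- integer(n)  # 1 = a, 2 = b
    s[1] <- if (identical(start_state, "stationary")) {
      if (runif(1) < pi_a) 1L else 2L
    } else if (start_state == "a") 1L else 2L
    u <- runif(n - 1)
    for (t in seq_len(n - 1)) {
      s[t + 1] <- if (s[t] == 1L) {
        if (u[t] < model$p_ab) 2L else 1L
      } else {
        if (u[t] < model$p_ba) 1L else 2L
      }
    }
    out <- tibble::tibble(
      time = seq_len(n) * model$dt_ps,
      replica = r,
      state = c("a", "b")[s],
      s_cb = rnorm(n, em$dist_mean[s], em$dist_sd[s]),
      dihedral = wrap_angle(rnorm(n, em$dihedral_mean[s], em$dihedral_sd[s]))
    )
    if (has_hb) out$hbond <- rnorm(n, em$hbond_mean[s], em$hbond_sd[s])
    out
  })
  dplyr::bind_rows(reps)
}
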