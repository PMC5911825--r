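#' Boltzmann constant in kcal mol^-1 K^-1
#'
#' Value used throughout for converting probabilities to free energies
#' (A = -kB T ln P) and for Metropolis acceptance.
#'
#' @export
kB <- 0.0019872041

#' Thermal energy kB*T
#'
#' @param temperature Temperature in kelvin.
#' @return kB*T in kcal mol^-1.
#' @export
kT <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  kB * temperature
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-window / per-stage
#' seeds, using two rounds of a Lehmer multiplicative congruential step
#' (multiplier 48271, modulus 2^31 - 1). All intermediates stay below
#' 2^53 so the arithmetic is exact in doubles, and the result fits in a
#' 32-bit integer as required by [set.seed()].
#'
#' @param master Master seed (non-negative integer).
#' @param index Child index (non-negative integer, e.g. window number).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(index))
  m <- 2147483647
  x <- (abs(master) %% m)
  x <- (48271 * x + index + 1) %% m
  x <- (48271 * x) %% m
  as.integer(ifelse(x == 0, 1, x))
}

# left-closed right-open binning: returns bin index in 1..(length(edges)-1),
# NA when out of range (including x == max edge, per the [a, b) rule)
.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = FALSE, all.inside = FALSE)
  i[i < 1 | i >= length(edges) | x >= edges[length(edges)]] <- NA_integer_
  i
}

.edges_from_width <- function(start, stop, width) {
  stopifnot(width > 0, stop > start)
  n <- ceiling(round((stop - start) / width, 9))
  start + width * seq(0L, n)
}

.centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2
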