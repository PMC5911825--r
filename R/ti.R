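#' Lambda schedule for thermodynamic integration
#'
#' Strictly increasing coupling-parameter values in (0, 1). Accepts a
#' numeric vector or a comma/whitespace-separated string (so a schedule
#' printed in a methods section can be pasted verbatim).
#'
#' @param x Numeric vector or a single string such as
#'   `"0.005, 0.071, 0.137"`.
#' @return A `lambda_schedule` (numeric vector subclass).
#' @export
lambda_schedule <- function(x) {
  if (is.character(x)) {
    x <- as.numeric(strsplit(trimws(paste(x, collapse = " ")),
                             "[,;\\s]+")[[1]])
  }
  stopifnot(is.numeric(x), length(x) >= 2, !anyNA(x))
  if (any(x <= 0) || any(x >= 1)) stop("lambda values must lie in (0, 1)")
  if (any(diff(x) <= 0)) stop("lambda values must be strictly increasing")
  structure(as.numeric(x), class = "lambda_schedule")
}

#' The 16-window WaterSwap-style lambda schedule
#'
#' Sixteen evenly spaced windows from 0.005 to 0.995 (spacing 0.066), the
#' schedule commonly used for replica-exchange thermodynamic integration
#' over the WaterSwap reaction coordinate.
#'
#' @return A [lambda_schedule()] of length 16.
#' @export
lambda_schedule_16 <- function() {
  lambda_schedule(0.005 + 0.066 * (0:15))
}

#' Thermodynamic-integration quadrature over a lambda schedule
#'
#' Averages each window's free-energy gradient after discarding an initial
#' burn-in fraction, then integrates the mean gradients over lambda by the
#' trapezoidal rule on the sampled range (no extrapolation beyond
#' `[lambda_1, lambda_n]` unless `extrapolate = TRUE`, which extends the
#' end-point gradients as constants to lambda = 0 and 1).
#'
#' @param gradients A data frame with columns `lambda` and `gradient`
#'   (kcal mol^-1 per unit lambda), one time series per lambda window, or a
#'   list of numeric gradient series ordered as `schedule`.
#' @param schedule A [lambda_schedule()]; required when `gradients` is a
#'   list, otherwise inferred (and checked) from the data.
#' @param burn_in_fraction Fraction of each series discarded from the
#'   front; default 1/3 (e.g. discarding the first 10 of 30 million Monte
#'   Carlo moves).
#' @param extrapolate Extend to the full [0, 1] range by constant
#'   end-point gradients (default FALSE).
#' @return A one-row tibble: `delta_A`, `n_lambda`, `lambda_min`,
#'   `lambda_max`; attribute `per_lambda` holds the per-window mean
#'   gradients.
#' @export
ti_integrate <- function(gradients, schedule = NULL, burn_in_fraction = 1/3,
                         extrapolate = FALSE) {
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  if (is.data.frame(gradients)) {
    stopifnot(all(c("lambda", "gradient") %in% names(gradients)))
    split_g <- split(gradients$gradient, gradients$lambda)
    lam <- as.numeric(names(split_g))
    series <- split_g
    if (!is.null(schedule)) {
      if (length(schedule) != length(lam) ||
          any(abs(sort(as.numeric(schedule)) - lam) > 1e-12))
        stop("schedule does not match the lambda values present in gradients")
    }
  } else {
    if (is.null(schedule)) stop("a schedule is required for list input")
    if (length(gradients) != length(schedule))
      stop("schedule/gradient length mismatch: ", length(schedule), " vs ",
           length(gradients))
    lam <- as.numeric(schedule)
    series <- gradients
  }
  means <- vapply(series, function(g) {
    g <- as.numeric(g)
    drop <- floor(burn_in_fraction * length(g))
    mean(g[(drop + 1):length(g)])
  }, 1)
  ord <- order(lam)
  lam <- lam[ord]; means <- means[ord]
  if (extrapolate) {
    lam <- c(0, lam, 1)
    means <- c(means[1], means, means[length(means)])
  }
  dA <- sum(diff(lam) * (head(means, -1) + tail(means, -1)) / 2)
  out <- tibble::tibble(delta_A = dA, n_lambda = length(series),
                        lambda_min = min(lam), lambda_max = max(lam))
  attr(out, "per_lambda") <- tibble::tibble(lambda = lam, mean_gradient = means)
  out
}

#' Aggregate replicate free-energy (or pKa-shift) estimates
#'
#' Mean, standard deviation (n - 1 denominator) and standard error of the
#' mean over independent replicate values, the convention for reporting
#' repeated binding-free-energy runs or per-snapshot pKa shifts.
#'
#' @param values Numeric vector of replicate estimates (n >= 1).
#' @param mode Which spread to treat as the headline uncertainty: `"sem"`
#'   (default) or `"sd"`.
#' @return A one-row tibble (`mean`, `sd`, `sem`, `n`, `uncertainty`,
#'   `mode`); with n = 1 the spread is 0 and the result carries a
#'   `single_replicate` attribute flag.
#' @export
aggregate_replicates <- function(values, mode = c("sem", "sd")) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty input: no replicate values")
  n <- length(values)
  s <- if (n > 1) sd(values) else 0
  sem <- s / sqrt(n)
  out <- tibble::tibble(mean = mean(values), sd = s, sem = sem, n = n,
                        uncertainty = if (mode == "sem") sem else s,
                        mode = mode)
  attr(out, "single_replicate") <- n == 1
  out
}
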