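#' Harmonic umbrella bias
#'
#' Restraint of the form \eqn{U_{bias} = \sum_j k_j (\xi_j - \xi_{0,j})^2}.
#' Note the convention: no 1/2 factor, matching the AMBER restraint
#' definition (a spring constant of 100 kcal mol^-1 A^-2 contributes
#' 1 kcal mol^-1 at 0.1 A displacement).
#'
#' @param center Bias centre(s), one value per biased coordinate.
#' @param k Spring constant(s) in kcal mol^-1 per unit^2 (recycled).
#' @param coord Coordinate id(s); defaults to `"x"` (and `"y"`).
#' @return A `harmonic_bias` object.
#' @export
harmonic_bias <- function(center, k, coord = NULL) {
  stopifnot(is.numeric(center), is.numeric(k), all(k >= 0))
  k <- rep_len(k, length(center))
  if (is.null(coord)) coord <- c("x", "y")[seq_along(center)]
  structure(list(center = center, k = k, coord = coord),
            class = "harmonic_bias")
}

#' Bias energy of a harmonic restraint
#'
#' @param bias A [harmonic_bias()].
#' @param xi A numeric vector (one point) or matrix with one column per
#'   biased coordinate.
#' @return Bias energies in kcal mol^-1, zero at the centre and symmetric
#'   about it.
#' @export
bias_energy <- function(bias, xi) {
  stopifnot(inherits(bias, "harmonic_bias"))
  if (is.null(dim(xi))) xi <- matrix(xi, ncol = length(bias$center))
  dev <- sweep(xi, 2, bias$center)
  as.numeric(dev^2 %*% bias$k)
}

#' Sample a biased umbrella window by Metropolis Monte Carlo
#'
#' Draws from the density proportional to
#' \eqn{\exp(-[U(\xi) + U_{bias}(\xi)] / k_B T)} with a symmetric uniform
#' proposal. During burn-in the step size is tuned to a 30-60% acceptance
#' band (adjusted every 50 steps), then frozen; burn-in samples are
#' discarded. With an identical seed the returned series is identical.
#'
#' @param potential An [analytic_surface()] (fast compiled path) or an R
#'   function taking a numeric vector of length equal to the number of
#'   biased coordinates and returning the potential in kcal mol^-1.
#' @param bias A [harmonic_bias()].
#' @param n_samples Number of retained samples (> 0).
#' @param burn_in Number of discarded equilibration steps; default 10% of
#'   `n_samples`.
#' @param step Initial proposal half-width; the default `NULL` starts from
#'   the random-walk-optimal scale for the bias alone,
#'   `2.4 sqrt(kB T / (2 k)) / sqrt(d)`, before tuning.
#' @param seed Integer seed (required; sampling is never silently seeded).
#' @param temperature Temperature in kelvin.
#' @param start Start point; defaults to the bias centre.
#' @return A tibble with columns `step` and `value_x` (and `value_y`),
#'   carrying attributes `acceptance`, `step_size`, `seed`, `temperature`.
#' @export
sample_biased_window <- function(potential, bias, n_samples,
                                 burn_in = ceiling(0.1 * n_samples),
                                 step = NULL, seed, temperature = 300,
                                 start = NULL) {
  stopifnot(inherits(bias, "harmonic_bias"), n_samples > 0)
  if (missing(seed)) stop("an explicit seed is required")
  d <- length(bias$center)
  if (is.null(start)) start <- bias$center
  kt <- kT(temperature)
  if (is.null(step))
    step <- 2.4 * sqrt(kt / (2 * max(max(bias$k), 1))) / sqrt(d)
  set.seed(seed)
  if (inherits(potential, "analytic_surface")) {
    stopifnot(potential$dim == d)
    w <- potential$wells
    wc <- rbind(w$center_x, if (d == 2L) w$center_y)
    wd <- rbind(w$width_x, if (d == 2L) w$width_y)
    res <- cpp_sample_surface(wc, w$depth, wd, potential$conf_center,
                              potential$conf_k, bias$center, bias$k,
                              as.integer(n_samples), as.integer(burn_in),
                              step, kt, start)
    samples <- res$samples
    acc <- res$acceptance
    step_final <- res$step_size
  } else {
    stopifnot(is.function(potential))
    u0 <- potential(start) + bias_energy(bias, start)
    if (!is.finite(u0)) stop("non-finite potential at start point")
    total <- burn_in + n_samples
    samples <- matrix(NA_real_, n_samples, d)
    x <- start; u <- u0
    acc_post <- 0L; acc_win <- 0L; win <- 0L
    for (t in seq_len(total)) {
      xp <- x + (runif(d) * 2 - 1) * step
      up <- potential(xp) + bias_energy(bias, xp)
      accept <- is.finite(up) && (up <= u || runif(1) < exp(-(up - u) / kt))
      if (accept) { x <- xp; u <- up }
      if (t <= burn_in) {
        acc_win <- acc_win + accept; win <- win + 1L
        if (win == 50L) {
          rate <- acc_win / 50
          if (rate > 0.60) step <- step * 1.2
          else if (rate < 0.30) step <- step * 0.8
          acc_win <- 0L; win <- 0L
        }
      } else {
        acc_post <- acc_post + accept
        samples[t - burn_in, ] <- x
      }
    }
    acc <- acc_post / n_samples
    step_final <- step
  }
  out <- tibble::tibble(step = seq_len(n_samples))
  out$value_x <- samples[, 1]
  if (d == 2L) out$value_y <- samples[, 2]
  attr(out, "acceptance") <- acc
  attr(out, "step_size") <- step_final
  attr(out, "seed") <- seed
  attr(out, "temperature") <- temperature
  out
}

#' Construct an umbrella window
#'
#' Couples a harmonic bias with its sampled series, plus metadata needed to
#' replay or document the window.
#'
#' @param bias A [harmonic_bias()].
#' @param samples A data frame with columns `step`, `value_x` (and `value_y`).
#' @param metadata Optional named list (seed, temperature, acceptance, ...).
#' @return An `umbrella_window` object.
#' @export
umbrella_window <- function(bias, samples, metadata = list()) {
  stopifnot(inherits(bias, "harmonic_bias"))
  samples <- tibble::as_tibble(samples)
  need <- c("value_x", if (length(bias$center) == 2L) "value_y")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) stop("samples missing columns: ", paste(miss, collapse = ", "))
  structure(list(bias = bias, samples = samples, metadata = metadata),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> center (%s), k (%s), %d samples\n",
              paste(signif(x$bias$center, 4), collapse = ", "),
              paste(x$bias$k, collapse = ", "), nrow(x$samples)))
  invisible(x)
}

.window_values <- function(w) {
  d <- length(w$bias$center)
  as.matrix(w$samples[, c("value_x", if (d == 2L) "value_y")])
}

#' Generate a full umbrella-sampling dataset from an analytic surface
#'
#' One Metropolis-sampled window per grid point, with per-window seeds
#' derived deterministically from the master seed via [derive_seed()].
#' Optionally writes one plain-text series file per window plus a YAML
#' manifest (see [read_us_dataset()]).
#'
#' @param surface An [analytic_surface()] (1D or 2D).
#' @param spec_x,spec_y Window [grid_spec()]s; `spec_y` only for 2D.
#' @param k Spring constant (kcal mol^-1 per unit^2), applied to every
#'   biased coordinate.
#' @param n_per_window Retained samples per window.
#' @param seed Master seed.
#' @param temperature Temperature (K).
#' @param burn_in Discarded steps per window; default 10% of `n_per_window`.
#' @param dir Optional output directory for window files + `manifest.yml`.
#' @return A list of [umbrella_window()] objects (invisibly carries the
#'   manifest path as attribute `manifest` when `dir` is given).
#' @export
generate_us_dataset <- function(surface, spec_x, spec_y = NULL, k = 100,
                                n_per_window = 2000, seed,
                                temperature = 300,
                                burn_in = ceiling(0.1 * n_per_window),
                                dir = NULL) {
  stopifnot(inherits(surface, "analytic_surface"))
  if (missing(seed)) stop("an explicit master seed is required")
  grid <- build_window_grid(spec_x, spec_y)
  d <- if (is.null(spec_y)) 1L else 2L
  stopifnot(surface$dim == d)
  windows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    center <- c(grid$center_x[i], if (d == 2L) grid$center_y[i])
    b <- harmonic_bias(center, k)
    s_i <- derive_seed(seed, i)
    ser <- sample_biased_window(surface, b, n_per_window, burn_in = burn_in,
                                seed = s_i, temperature = temperature)
    windows[[i]] <- umbrella_window(b, ser, metadata = list(
      window = i, seed = s_i, temperature = temperature,
      burn_in = burn_in, acceptance = attr(ser, "acceptance"),
      step_size = attr(ser, "step_size")))
  }
  if (!is.null(dir)) {
    manifest <- write_us_dataset(windows, dir)
    attr(windows, "manifest") <- manifest
  }
  windows
}

#' Write umbrella windows to plain-text series files plus a YAML manifest
#'
#' @param windows A list of [umbrella_window()] objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file.
#' @export
write_us_dataset <- function(windows, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  entries <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    file <- file.path(dir, sprintf("window_%04d.dat", i))
    .write_window_series(w, file)
    entries[[i]] <- list(
      file = basename(file),
      coordinate = as.list(w$bias$coord),
      center = as.list(w$bias$center),
      k = as.list(w$bias$k),
      temperature = w$metadata$temperature %||% 300,
      seed = w$metadata$seed %||% NA,
      n = nrow(w$samples)
    )
  }
  manifest <- file.path(dir, "manifest.yml")
  yaml::write_yaml(list(windows = entries), manifest)
  manifest
}

.write_window_series <- function(w, file) {
  d <- length(w$bias$center)
  hdr <- c(
    paste("# coordinate:", paste(w$bias$coord, collapse = " ")),
    paste("# center:", paste(format(w$bias$center, digits = 12), collapse = " ")),
    paste("# k:", paste(format(w$bias$k, digits = 12), collapse = " ")),
    paste("# temperature:", w$metadata$temperature %||% 300),
    paste("# seed:", w$metadata$seed %||% NA),
    paste("# step", paste0("value_", w$bias$coord, collapse = " "))
  )
  vals <- .window_values(w)
  body <- paste(w$samples$step,
                apply(format(vals, digits = 12, trim = TRUE), 1, paste,
                      collapse = " "))
  con <- file(file, "w")
  on.exit(close(con))
  ok <- tryCatch({ writeLines(c(hdr, body), con); TRUE },
                 error = function(e) stop("I/O failure writing ", file, ": ",
                                          conditionMessage(e)))
  invisible(file)
}

#' Read one umbrella-window series file
#'
#' Whitespace-delimited `step value` (1D) or `step value_x value_y` (2D)
#' with a `#` comment header carrying coordinate ids, centre(s), spring
#' constant(s), temperature and seed.
#'
#' @param file Path to a window series file.
#' @return An [umbrella_window()].
#' @export
read_window_series <- function(file) {
  if (!file.exists(file)) stop("no such window file: ", file)
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# *", key, ":"), hdr)]
    if (length(ln) == 0) return(NULL)
    strsplit(trimws(sub(paste0("^# *", key, ":"), "", ln[1])), "\\s+")[[1]]
  }
  coord <- get("coordinate")
  center <- as.numeric(get("center"))
  k <- as.numeric(get("k"))
  temperature <- as.numeric(get("temperature") %||% "300")
  seed <- suppressWarnings(as.numeric(get("seed") %||% NA))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  d <- length(center)
  samples <- tibble::tibble(step = mat[, 1], value_x = mat[, 2])
  if (d == 2L) samples$value_y <- mat[, 3]
  umbrella_window(harmonic_bias(center, k, coord), samples,
                  metadata = list(temperature = temperature, seed = seed,
                                  file = file))
}

#' Read an umbrella-sampling dataset from a YAML manifest
#'
#' @param manifest Path to a `manifest.yml` written by [write_us_dataset()].
#' @return A list of [umbrella_window()] objects.
#' @export
read_us_dataset <- function(manifest) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  m <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  lapply(m$windows, function(e) read_window_series(file.path(dir, e$file)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
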