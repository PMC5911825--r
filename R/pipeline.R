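# End-to-end orchestration: simulate -> wham -> analyze -> conffes -> report.
# One declarative config, one master seed fanned out per stage through
# derive_seed() with fixed stage indices (documented in validate_config).

.stage_seeds <- c(us_2d = 101L, us_1d = 102L, trajectories = 103L)

#' Validate and complete a pipeline run configuration
#'
#' Fills defaults, checks types and ranges, and returns the completed
#' config; all problems are reported together in one error. The master
#' `seed` is required, and a `us` block must state its spring constant `k`
#' explicitly (a restraint strength is a physical choice, never defaulted).
#'
#' @param config A named list, or the path to a YAML file.
#' @return The validated config (class `run_config`) with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errors <- character()
  err <- function(...) errors <<- c(errors, sprintf(...))

  if (is.null(config$seed)) err("missing required field 'seed'")
  else if (!is.numeric(config$seed)) err("'seed' must be numeric")
  config$temperature <- config$temperature %||% 300
  if (config$temperature <= 0) err("'temperature' must be > 0")

  config$surface <- utils::modifyList(
    list(barrier = 7.8, reaction_free_energy = -10.3,
         reactant_center = c(3.4, 2.0), product_center = c(1.9, -1.5),
         width = 0.35, conf_k = 1.0),
    config$surface %||% list())

  if (!is.null(config$us)) {
    if (is.null(config$us$k)) err("us: missing spring constant 'k'")
    else if (config$us$k < 0) err("us: spring constant 'k' must be >= 0")
    config$us <- utils::modifyList(
      list(spec_x = list(start = 3.6, stop = 1.8, step = -0.1),
           spec_y = list(start = 2.8, stop = -2.2, step = -0.2),
           n_per_window = 2000),
      config$us)
  }
  if (!is.null(config$us_1d)) {
    if (is.null(config$us_1d$k)) err("us_1d: missing spring constant 'k'")
    config$us_1d <- utils::modifyList(
      list(spec = list(start = 1, stop = -1, step = -0.1),
           n_per_window = 2000,
           surface = list(barrier = 2.5, reaction_free_energy = 0.5,
                          reactant_center = -0.5, product_center = 0.5,
                          width = 0.15, conf_k = 2)),
      config$us_1d)
  }
  config$wham <- utils::modifyList(
    list(tolerance = 1e-7, max_iter = 1e5), config$wham %||% list())
  if (config$wham$tolerance < 0) err("wham: 'tolerance' must be >= 0")

  if (!is.null(config$conformational)) {
    config$conformational <- utils::modifyList(
      list(p_ab = 0.002, p_ba = 0.002, n_replicas = 4,
           n_per_replica = 30000, cutoff = 3.9, hbond_cutoff = 3.5),
      config$conformational)
    with(config$conformational, {
      if (p_ab < 0 || p_ab > 1) err("conformational: 'p_ab' not in [0, 1]")
      if (p_ba < 0 || p_ba > 1) err("conformational: 'p_ba' not in [0, 1]")
      if (cutoff <= 0) err("conformational: 'cutoff' must be > 0")
    })
  }
  if (length(errors) > 0)
    stop("invalid config:\n  - ", paste(errors, collapse = "\n  - "))
  class(config) <- c("run_config", "list")
  config
}

.as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) x else grid_spec(x$start, x$stop, x$step)
}

#' Run the full free-energy pipeline from one configuration
#'
#' Executes the configured stages in dependency order: surface calibration
#' and umbrella-sampling simulation, WHAM, basin/path analysis, and
#' conformational analysis of two-state trajectories. Identical config and
#' seed reproduce identical artifacts. A stage failure stops the run with
#' a stage-named error; upstream results computed so far are attached to
#' the error condition.
#'
#' @param config A validated (or validatable) config; see
#'   [validate_config()].
#' @param out_dir Optional directory: writes `report.json` plus
#'   tab-separated FES/path tables.
#' @return A `run_report` list: `config`, per-stage `results`, `warnings`,
#'   `ok` flag and package `version`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  seed <- config$seed
  temp <- config$temperature
  warnings <- character()
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial_results <- results
      stop(cond)
    })
  }

  if (!is.null(config$us)) {
    run_stage("simulate", {
      surf <- do.call(make_reaction_surface, c(
        config$surface[c("barrier", "reaction_free_energy", "reactant_center",
                         "product_center", "width", "conf_k")],
        list(temperature = temp)))
      results$surface_ground_truth <- attr(surf, "ground_truth")
      results$us_windows <- generate_us_dataset(
        surf, .as_grid_spec(config$us$spec_x), .as_grid_spec(config$us$spec_y),
        k = config$us$k, n_per_window = config$us$n_per_window,
        seed = derive_seed(seed, .stage_seeds[["us_2d"]]),
        temperature = temp)
    })
    run_stage("wham", {
      results$wham <- wham(results$us_windows, temperature = temp,
                           tolerance = config$wham$tolerance,
                           max_iter = config$wham$max_iter)
      if (!results$wham$converged)
        warnings <- c(warnings, "2D WHAM did not converge")
    })
    run_stage("analyze", {
      fes <- results$wham$fes
      minima <- find_minima(fes)
      rc <- config$surface$reactant_center
      dists <- (minima$center_x - rc[1])^2 + (minima$center_y - rc[2])^2
      from <- minima$basin[which.min(dists)]
      to <- minima$basin[which.max(dists)]
      path <- minimax_path(fes, from, to, minima = minima)
      results$minima <- minima
      results$path <- path
      results$energetics <- activation_reaction_energies(path)
    })
  }

  if (!is.null(config$us_1d)) {
    run_stage("simulate_1d", {
      s1 <- config$us_1d$surface
      surf1 <- make_reaction_surface(
        s1$barrier, s1$reaction_free_energy,
        reactant_center = s1$reactant_center,
        product_center = s1$product_center,
        width = s1$width, conf_k = s1$conf_k, temperature = temp)
      results$us1d_ground_truth <- attr(surf1, "ground_truth")
      results$us1d_windows <- generate_us_dataset(
        surf1, .as_grid_spec(config$us_1d$spec),
        k = config$us_1d$k, n_per_window = config$us_1d$n_per_window,
        seed = derive_seed(seed, .stage_seeds[["us_1d"]]),
        temperature = temp)
    })
    run_stage("wham_1d", {
      results$wham_1d <- wham(results$us1d_windows, temperature = temp,
                              tolerance = config$wham$tolerance,
                              max_iter = config$wham$max_iter)
      if (!results$wham_1d$converged)
        warnings <- c(warnings, "1D WHAM did not converge")
      results$profile_delta <- profile_delta(results$wham_1d$fes)
    })
  }

  if (!is.null(config$conformational)) {
    run_stage("conffes", {
      cf <- config$conformational
      model <- two_state_model(p_ab = cf$p_ab, p_ba = cf$p_ba,
                               n_replicas = cf$n_replicas,
                               n_per_replica = cf$n_per_replica)
      traj <- make_two_state_trajectory(
        model, seed = derive_seed(seed, .stage_seeds[["trajectories"]]))
      pooled <- pool_features(traj)
      results$conf_fes <- boltzmann_fes(pooled, temperature = temp)
      oor <- attr(results$conf_fes, "out_of_range")
      if (oor > 0)
        warnings <- c(warnings, sprintf(
          "conformational FES: %d snapshots out of binning range", oor))
      results$reactive <- reactive_fraction(pooled, cutoff = cf$cutoff)
      assigned <- assign_states(pooled)
      results$basin_delta <- basin_delta(assigned, temperature = temp)
      results$coupling <- coupling_report(
        assigned, seed = derive_seed(seed, 104L))
      if ("hbond" %in% names(pooled))
        results$hbond <- hbond_occupancy(pooled, cutoff = cf$hbond_cutoff)
    })
  }

  report <- structure(list(
    config = config,
    results = results,
    warnings = warnings,
    ok = length(warnings) == 0,
    version = as.character(utils::packageVersion("covfes"))
  ), class = "run_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> covfes %s, %s\n", x$version,
              if (x$ok) "ok" else "with warnings"))
  for (w in x$warnings) cat("  warning:", w, "\n")
  s <- glance(x)
  print(as.data.frame(s))
  invisible(x)
}

#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    delta_A_act = r$energetics$delta_A_act %||% NA_real_,
    delta_A_reac = r$energetics$delta_A_reac %||% NA_real_,
    profile_delta = r$profile_delta %||% NA_real_,
    basin_delta = r$basin_delta %||% NA_real_,
    reactive_fraction = if (!is.null(r$reactive))
      r$reactive$pooled$fraction else NA_real_,
    ok = x$ok
  )
}

.write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  r <- report$results
  if (!is.null(r$wham)) tsv(tidy(r$wham$fes), "fes_2d.tsv")
  if (!is.null(r$wham_1d)) tsv(tidy(r$wham_1d$fes), "fes_1d.tsv")
  if (!is.null(r$path)) tsv(as.data.frame(r$path), "path.tsv")
  if (!is.null(r$conf_fes)) tsv(tidy(r$conf_fes), "conf_fes.tsv")
  summary <- c(
    list(version = report$version, ok = report$ok,
         warnings = report$warnings,
         seed = report$config$seed, temperature = report$config$temperature),
    lapply(r[intersect(names(r), c("surface_ground_truth", "energetics",
                                   "profile_delta", "basin_delta"))],
           function(z) if (is.data.frame(z)) as.list(z) else z),
    if (!is.null(r$reactive)) list(reactive = as.list(r$reactive$pooled))
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
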