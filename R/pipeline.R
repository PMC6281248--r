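#' Read and write the pipeline's tidy CSV tables
#'
#' All tables use SI units embedded in the column names (`..._m`, `..._s`);
#' times are seconds from recording start and abscissae increase in the
#' direction of collective travel.
#'
#' @param x data frame to write.
#' @param path CSV file path.
#' @return `write_table_csv()` returns `path` invisibly;
#'   `read_table_csv()` returns a data frame.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) utils::read.csv(path)

stage_specs <- list(
  synth = c("group_sizes", "n_replicates", "duration", "sample_period",
            "grazing_speed", "noise_sd", "heading_range", "out"),
  simulate = c("N", "t_max", "record_interval", "out"),
  estimate = c("tracks", "threshold", "min_run", "min_cell_count",
               "n_boot", "out"),
  fit_rates = c("latencies", "min_cell_count", "n_boot", "out"),
  solve_pde = c("N", "t_end", "dt", "dx", "domain", "record_every",
                "moving_fraction0", "sd0", "out"),
  analytic = c("N_range", "alpha", "mu_A", "mu_I", "v", "variant", "out")
)

#' Run a configured chain of pipeline stages
#'
#' Executes any sequence of `synth`, `simulate`, `estimate`, `fit_rates`,
#' `solve_pde` and `analytic` stages described by a config (an R list or a
#' YAML/JSON file path), writes each stage's artifacts under `out_dir`,
#' and finishes with a JSON run manifest recording the command, the fully
#' resolved parameter set, seeds, every input/output path, timestamps and
#' the package version — re-running the manifest's config with its seed
#' byte-reproduces all stochastic outputs.
#'
#' @param config list or path to a YAML/JSON config with optional fields
#'   `seed`, `params` (a [behavioural_params()] mapping) and `stages` (a
#'   list of mappings each carrying a `stage` key plus stage arguments).
#'   Unknown stage names or keys are rejected with the offending name.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) {
    cfg_path <- config
    config <- if (grepl("\\.json$", cfg_path)) {
      jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    } else yaml::read_yaml(cfg_path)
  }
  allowed_top <- c("seed", "params", "stages")
  extra <- setdiff(names(config), allowed_top)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  params <- if (!is.null(config$params))
    do.call(behavioural_params, config$params) else behavioural_params()
  stages <- config$stages %||% list()
  manifest <- list(command = "run_pipeline", seed = seed,
                   params = unclass(params),
                   package_version = as.character(packageVersion("sheeppulse")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  set.seed(seed)
  for (k in seq_along(stages)) {
    st <- stages[[k]]
    name <- st$stage
    if (is.null(name) || !name %in% names(stage_specs))
      stop("stage ", k, ": unknown or missing stage name '",
           name %||% "<none>", "'")
    extra <- setdiff(names(st), c("stage", stage_specs[[name]]))
    if (length(extra))
      stop("stage '", name, "': unknown key(s): ",
           paste(extra, collapse = ", "))
    out_file <- file.path(out_dir,
                          st$out %||% paste0(name, "_", k, ".csv"))
    res <- run_stage(name, st, params, seed + k, out_file)
    manifest$stages[[k]] <- c(list(stage = name, out = out_file,
                                   seed = seed + k),
                              st[setdiff(names(st), c("stage", "out"))])
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, st, params, seed, out_file) {
  switch(name,
    synth = {
      spec <- field_track_spec(
        group_sizes = st$group_sizes %||% c(2L, 3L, 4L, 8L),
        n_replicates = st$n_replicates %||% 8L,
        duration = st$duration %||% 1800,
        sample_period = st$sample_period %||% 1,
        grazing_speed = st$grazing_speed %||% 0.1,
        noise_sd = st$noise_sd %||% 0.05,
        heading_range = st$heading_range %||% (pi / 3),
        params = params, seed = seed)
      write_table_csv(generate_field_tracks(spec), out_file)
    },
    simulate = {
      p <- params
      if (!is.null(st$N)) p$N <- as.integer(st$N)
      traj <- run_gillespie(p, t_max = st$t_max %||% 1800,
                            record_interval = st$record_interval %||% 1,
                            seed = seed)
      write_table_csv(as.data.frame(traj), out_file)
    },
    estimate = {
      tracks <- read_table_csv(st$tracks)
      fit <- estimate_parameters(tracks,
                                 threshold = st$threshold %||% 0.3,
                                 min_run = st$min_run %||% 2L,
                                 min_cell_count = st$min_cell_count %||% 3L,
                                 n_boot = st$n_boot %||% 1000L,
                                 seed = seed)
      out_file <- sub("\\.csv$", ".json", out_file)
      jsonlite::write_json(serialize_fits(fit), out_file,
                           auto_unbox = TRUE, digits = NA, null = "null")
      invisible(out_file)
    },
    fit_rates = {
      lat <- read_table_csv(st$latencies)
      fit <- fit_mimetic_params(lat,
                                min_cell_count = st$min_cell_count %||% 3L,
                                n_boot = st$n_boot %||% 1000L, seed = seed)
      out_file <- sub("\\.csv$", ".json", out_file)
      jsonlite::write_json(serialize_fit(fit), out_file,
                           auto_unbox = TRUE, digits = NA)
      invisible(out_file)
    },
    solve_pde = {
      p <- params
      if (!is.null(st$N)) p$N <- as.integer(st$N)
      dx <- st$dx %||% 0.05
      dom <- st$domain %||% c(-20, 20 + p$v * (st$t_end %||% 600))
      x <- seq(dom[1], dom[2], by = dx)
      f0 <- gaussian_field(p$N, x, center = 0, sd = st$sd0 %||% 2,
                           moving_fraction0 = st$moving_fraction0 %||% 0)
      sol <- kinetic_solve(f0, p, t_end = st$t_end %||% 600,
                           dt = st$dt %||% 1e-2,
                           record_every = st$record_every %||% 50)
      last <- nrow(sol$A)
      write_table_csv(data.frame(x_m = sol$x, A = sol$A[last, ],
                                 I = sol$I[last, ]), out_file)
    },
    analytic = {
      scan <- sensitivity_scan(st$N_range %||% 2^(0:8),
                               alpha = st$alpha %||% 0.5,
                               mu_A = st$mu_A %||% 0.02,
                               mu_I = st$mu_I %||% 0.08,
                               v = st$v %||% 1,
                               variant = isTRUE(st$variant))
      write_table_csv(scan, out_file)
    })
}

serialize_fit <- function(fit) {
  list(alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
       ci = as.data.frame(fit$ci), r_squared = fit$r_squared,
       n_boot = fit$n_boot, table = fit$table)
}

serialize_fits <- function(est) {
  list(departure = serialize_fit(est$departure_fit),
       stop = serialize_fit(est$stop_fit),
       mu_I_star = if (!is.null(est$mu_I)) est$mu_I$mu_I_star else NULL)
}
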