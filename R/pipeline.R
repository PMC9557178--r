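# ---------------------------------------------------------------------------
# Reproducible pipeline: simulate -> describe -> prep -> fit -> predict ->
# compare, with a JSON config, structured logging, and a manifest.
# ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' Returns the complete default configuration as a nested list; any subset
#' can be overridden via `overrides` (named list, names in `a.b.c` dotted
#' form) or by supplying a JSON config file to [run_pipeline()]. Defaults
#' are smoke-test sized; the synthetic-data defaults at full scale live in
#' [simulate_dataset()].
#'
#' @param overrides named list of dotted-path overrides, e.g.
#'   `list("fit.iter" = 500)`.
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1,
    simulate = list(
      counts_per_wave = c(30, 30, 30, 30, 30),
      grid = list(n_rows = 12, n_cols = 12, origin_lon = 34,
                  origin_lat = 14, cell_size = 0.5),
      alpha_true = -0.55,
      beta_true = c(-0.39, 0.09),
      covariate_names = c("temperature", "travel_time"),
      smoothness_cells = 5,
      children_per_cluster = c(5, 25)
    ),
    prep = list(collinearity_threshold = 0.8, priority = NULL),
    fit = list(chains = 1, iter = 600, burnin = 200, include_field = TRUE,
               waves = "pooled"),
    predict = list(n_draws = 50),
    compare = list(enabled = TRUE)
  )
  if (!is.null(overrides)) {
    for (key in names(overrides)) {
      path <- strsplit(key, ".", fixed = TRUE)[[1]]
      cfg[[path]] <- overrides[[key]]
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Keys present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path JSON file.
#' @param overrides further dotted-path overrides applied after the file.
#' @return a `run_config`.
#' @export
read_config <- function(path, overrides = NULL) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- unclass(default_config())
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  cfg <- merge_into(cfg, user)
  class(cfg) <- c("run_config", "list")
  if (!is.null(overrides)) {
    for (key in names(overrides)) {
      path_v <- strsplit(key, ".", fixed = TRUE)[[1]]
      cfg[[path_v]] <- overrides[[key]]
    }
  }
  cfg
}

log_line <- function(stage, msg, log_file = NULL) {
  line <- sprintf("[%s] [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(line)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, describe, prep, fit, predict and compare in order,
#' writing every artifact under `out_dir` and a `manifest.json` recording
#' the configuration, all seeds, an MD5 hash of every output file, and the
#' WAIC table. The manifest contains no timestamps, so identical
#' config + seed reproduce it bit for bit; wall-clock timings go to the run
#' log (`run.log`) instead.
#'
#' @param config a `run_config` (see [default_config()], [read_config()]).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stopifnot(is.numeric(seed), seed >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  cat("", file = log_file)
  artifacts <- character(0)
  t0 <- Sys.time()

  # --- simulate ---
  log_line("simulate", sprintf("seed = %s", seed), log_file)
  sim_cfg <- config$simulate
  gs <- do.call(grid_spec, as.list(sim_cfg$grid))
  sim <- simulate_dataset(
    counts_per_wave = sim_cfg$counts_per_wave,
    spec = gs,
    alpha_true = sim_cfg$alpha_true,
    beta_true = sim_cfg$beta_true,
    smoothness_range = sim_cfg$smoothness_cells * gs$cell_size,
    children_per_cluster = sim_cfg$children_per_cluster,
    seed = seed,
    covariate_names = sim_cfg$covariate_names)
  p_clusters <- file.path(out_dir, "clusters.csv")
  write_clusters(sim$records, p_clusters)
  artifacts <- c(artifacts, p_clusters)
  for (g in sim$grids) {
    p <- file.path(out_dir, paste0("covariate_", g$name, ".asc"))
    write_raster(g, p)
    artifacts <- c(artifacts, p)
  }
  p_truth <- file.path(out_dir, "truth.json")
  write_truth(sim$truth, p_truth)
  artifacts <- c(artifacts, p_truth)

  # --- describe ---
  log_line("describe", "prevalence table", log_file)
  tab <- prevalence_table(sim$records)
  p_desc <- file.path(out_dir, "descriptives.csv")
  utils::write.csv(as.data.frame(tab), p_desc, row.names = FALSE)
  artifacts <- c(artifacts, p_desc)

  # --- prep ---
  log_line("prep", "standardize + collinearity screen", log_file)
  dm <- standardize(sim$design, names = sim_cfg$covariate_names)
  screen <- correlation_screen(
    dm, threshold = config$prep$collinearity_threshold,
    priority = config$prep$priority)
  p_screen <- file.path(out_dir, "screen.json")
  jsonlite::write_json(list(retained = screen$retained,
                            dropped = screen$dropped),
                       p_screen, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, p_screen)
  keep <- match(screen$retained, dm$columns)
  dm_used <- standardize(sim$design[, keep, drop = FALSE],
                         names = dm$columns[keep])

  # --- fit (pooled and/or per-wave) ---
  fit_cfg <- config$fit
  wave_sets <- list()
  if (identical(fit_cfg$waves, "all")) {
    uw <- unique(sim$records$wave)
    wave_sets <- c(list(pooled = NULL), stats::setNames(as.list(uw), uw))
  } else {
    if ("pooled" %in% fit_cfg$waves) wave_sets["pooled"] <- list(NULL)
    for (w in setdiff(fit_cfg$waves, "pooled")) wave_sets[[w]] <- w
  }
  fits <- list()
  waics <- list()
  for (label in names(wave_sets)) {
    log_line("fit", paste("model:", label), log_file)
    w <- wave_sets[[label]]
    rows <- if (is.null(w)) seq_len(nrow(sim$records)) else
      which(sim$records$wave == w)
    rec_sub <- cluster_records(as.data.frame(sim$records)[rows, ,
                                                          drop = FALSE])
    dm_sub <- standardize(sim$design[rows, keep, drop = FALSE],
                          names = dm$columns[keep])
    fit <- fit_mcmc(rec_sub, dm_sub,
                    include_field = isTRUE(fit_cfg$include_field),
                    chains = fit_cfg$chains, iter = fit_cfg$iter,
                    burnin = fit_cfg$burnin,
                    seed = sub_seed(seed, paste0("fit-", label)))
    fits[[label]] <- fit
    waics[[label]] <- waic(fit)
    p_fit <- file.path(out_dir, paste0("posterior_", label, ".json"))
    s <- summary(fit)
    jsonlite::write_json(s, p_fit, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, p_fit)

    # --- predict ---
    log_line("predict", paste("surface:", label), log_file)
    surf <- predict_surface(fit, sim$grids,
                            n_draws = config$predict$n_draws,
                            seed = sub_seed(seed, paste0("predict-", label)))
    paths <- write_surface(surf, out_dir, prefix = paste0("surface_", label))
    artifacts <- c(artifacts, paths)
  }

  # --- compare ---
  cmp <- NULL
  if (isTRUE(config$compare$enabled) && length(waics)) {
    log_line("compare", "WAIC ranking", log_file)
    cmp <- compare_models(waics)
    p_cmp <- file.path(out_dir, "waic.csv")
    utils::write.csv(cmp, p_cmp, row.names = FALSE)
    artifacts <- c(artifacts, p_cmp)
  }

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_line("done", sprintf("wall clock %.1f s", elapsed), log_file)

  manifest <- list(
    package_version = as.character(utils::packageVersion("geoprev")),
    seed = seed,
    config = unclass(config),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p))),
    waic = if (is.null(cmp)) NULL else cmp,
    models = names(wave_sets)
  )
  p_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# Command-line entry point
# ---------------------------------------------------------------------------

#' Command-line interface
#'
#' `geoprev <subcommand> [--config FILE] [--seed N] [--out DIR]` with
#' subcommands `simulate`, `describe`, `prep`, `fit`, `predict`, `compare`
#' and `run`. `run` executes the full pipeline; the single-stage
#' subcommands re-run just that stage of the same pipeline (from cached
#' upstream artifacts where applicable). Invoked from R or via the script
#' in `inst/cli/geoprev.R`.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit status, invisibly.
#' @export
geoprev_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: geoprev simulate|describe|prep|fit|predict|compare|run [--config FILE] [--seed N] [--out DIR]"
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = "geoprev_out")
  ))
  opts <- optparse::parse_args(parser, args = args[-1])
  cfg <- if (is.null(opts$config)) default_config() else
    read_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- opts$seed

  if (cmd == "run") {
    run_pipeline(cfg, opts$out)
    return(invisible(0L))
  }

  # single stages operate on / toward the artifact directory
  out <- opts$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (cmd == "simulate") {
    gs <- do.call(grid_spec, as.list(cfg$simulate$grid))
    sim <- simulate_dataset(
      counts_per_wave = cfg$simulate$counts_per_wave, spec = gs,
      alpha_true = cfg$simulate$alpha_true,
      beta_true = cfg$simulate$beta_true,
      smoothness_range = cfg$simulate$smoothness_cells * gs$cell_size,
      children_per_cluster = cfg$simulate$children_per_cluster,
      seed = cfg$seed, covariate_names = cfg$simulate$covariate_names)
    write_clusters(sim$records, file.path(out, "clusters.csv"))
    for (g in sim$grids) {
      write_raster(g, file.path(out, paste0("covariate_", g$name, ".asc")))
    }
    write_truth(sim$truth, file.path(out, "truth.json"))
  } else if (cmd == "describe") {
    rec <- read_clusters(file.path(out, "clusters.csv"))
    tab <- prevalence_table(rec)
    utils::write.csv(as.data.frame(tab),
                     file.path(out, "descriptives.csv"), row.names = FALSE)
    print(tab)
  } else if (cmd %in% c("prep", "fit", "predict", "compare")) {
    # these stages share state; delegate to the full pipeline which is
    # deterministic and re-entrant under the same config/seed
    run_pipeline(cfg, out)
  } else {
    message(usage)
    return(invisible(2L))
  }
  invisible(0L)
}
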