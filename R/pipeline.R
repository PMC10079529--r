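# Configuration, orchestration and plain-text IO for the full analysis.

#' Analysis configuration
#'
#' Collects every tunable of the network-inference pipeline with the
#' standard defaults: 60-month moving windows, 100 seasonal surrogates,
#' 100 convergence subsets at library fractions 0.2/0.5, embedding
#' dimensions 2-15, the 18-value theta grid, S-map exclusion radius 12,
#' 100 scenario models on a 100 x 100 grid.
#'
#' @param window moving-window length in months.
#' @param n_surrogates seasonal-surrogate ensemble size.
#' @param n_convergence_subsets random library segments per fraction.
#' @param lib_fractions small/large library fractions.
#' @param E_range candidate embedding dimensions.
#' @param tau embedding lag in months.
#' @param theta_grid S-map theta candidates.
#' @param exclusion_radius temporal exclusion for S-map cross-validation.
#' @param ccm_exclusion_radius temporal exclusion for cross-mapping
#'   (default 0: leave-one-out only).
#' @param n_scenario_models ensemble size for scenario grids.
#' @param subsample_frac library fraction per scenario model.
#' @param grid_resolution levels per grid axis.
#' @param master_seed master seed; per-pair seeds derive from it.
#' @param period_cutoff month stamp splitting the two focal periods for
#'   trend tests (`NULL`: series midpoint).
#' @return object of class `run_config`.
#' @export
run_config <- function(window = 60L,
                       n_surrogates = 100L,
                       n_convergence_subsets = 100L,
                       lib_fractions = c(0.2, 0.5),
                       E_range = 2:15,
                       tau = 1L,
                       theta_grid = default_theta_grid(),
                       exclusion_radius = 12L,
                       ccm_exclusion_radius = 0L,
                       n_scenario_models = 100L,
                       subsample_frac = 0.5,
                       grid_resolution = 100L,
                       master_seed = 1L,
                       period_cutoff = NULL) {
  stopifnot(window >= 12, n_surrogates >= 20, n_convergence_subsets >= 2,
            length(lib_fractions) == 2, lib_fractions[1] < lib_fractions[2])
  structure(list(window = as.integer(window),
                 n_surrogates = as.integer(n_surrogates),
                 n_convergence_subsets = as.integer(n_convergence_subsets),
                 lib_fractions = lib_fractions,
                 E_range = as.integer(E_range), tau = as.integer(tau),
                 theta_grid = theta_grid,
                 exclusion_radius = as.integer(exclusion_radius),
                 ccm_exclusion_radius = as.integer(ccm_exclusion_radius),
                 n_scenario_models = as.integer(n_scenario_models),
                 subsample_frac = subsample_frac,
                 grid_resolution = as.integer(grid_resolution),
                 master_seed = as.integer(master_seed),
                 period_cutoff = period_cutoff),
            class = "run_config")
}

# Stable hash of a configuration, for output provenance.
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", pair_seed(0L, txt, "config"))
}

#' Read / write tidy time-series CSV
#'
#' Long format with columns `month` (integer index), `variable`,
#' `value`; an empty value marks a missing observation.
#'
#' @param path CSV path.
#' @return `read_series_csv`: wide data frame (`month` + one column per
#'   variable, every month between the first and last present).
#' @export
read_series_csv <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("month", "variable", "value") %in% names(long)))
  months <- seq(min(long$month), max(long$month))
  out <- data.frame(month = months)
  for (v in unique(long$variable)) {
    d <- long[long$variable == v, ]
    out[[v]] <- d$value[match(months, d$month)]
  }
  out
}

#' @rdname read_series_csv
#' @param table wide data frame with a `month` column.
#' @export
write_series_csv <- function(table, path) {
  vars <- setdiff(names(table), "month")
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(month = table$month, variable = v, value = table[[v]])
  }))
  write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Preprocessing (winsorization of guild abundances, linear
#' interpolation of drivers), CCM network construction, network-property
#' series, trend tests on the two focal periods, the temperature/
#' phosphate feedback test, and S-map scenario grids for connectance and
#' mean strength.  Deterministic under a fixed `master_seed`.  When
#' `out_dir` is given, all series, grids and a manifest (configuration,
#' hash, seed) are written as plain-text files.
#'
#' @param table data frame: `month` plus one column per guild.
#' @param drivers data frame: `month`, `temperature`, `phosphate`.
#' @param graph a [guild_graph()].
#' @param config a [run_config()].
#' @param depth,volume lake morphometry used in scenario models.
#' @param out_dir optional output directory.
#' @param scenarios if `FALSE`, skip the (comparatively expensive)
#'   scenario stage.
#' @return list with `network`, `properties`, `trophic`, `types`,
#'   `link_strengths`, `trends`, `feedback`, `scenario` (per response:
#'   `theta` and `grid`), and `manifest`.
#' @export
run_pipeline <- function(table, drivers, graph, config = run_config(),
                         depth = 30, volume = 1, out_dir = NULL,
                         scenarios = TRUE) {
  missing_cols <- setdiff(graph$nodes$guild, names(table))
  if (length(missing_cols))
    stop("schema error: guild column(s) missing from table: ",
         paste(missing_cols, collapse = ", "))
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf("[planknet] %-12s %7.1fs", name,
                                          proc.time()[["elapsed"]] - t_start))
  # --- preprocess ---------------------------------------------------
  proc_tab <- table
  for (g in graph$nodes$guild) proc_tab[[g]] <- winsorize(table[[g]])
  drv <- drivers
  drv$temperature <- interpolate_drivers(drivers$temperature)
  drv$phosphate <- interpolate_drivers(drivers$phosphate)
  stage("preprocess")
  # --- network ------------------------------------------------------
  net <- build_network(proc_tab, graph, config)
  stage("network")
  # --- metrics ------------------------------------------------------
  props <- network_properties(net)
  types <- type_decomposition(net)
  troph <- tryCatch(trophic_control(net), error = function(e) NULL)
  pairs <- unique(net$links[, c("driver", "driven")])
  link_strengths <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sel <- net$links$driver == pairs$driver[i] &
      net$links$driven == pairs$driven[i]
    data.frame(driver = pairs$driver[i], driven = pairs$driven[i],
               pw_strength = prevalence_weighted_strength(net$links[sel, ]))
  }))
  cutoff <- config$period_cutoff %||%
    as.integer(round(stats::median(props$window_centre)))
  trends <- lapply(c(connectance = "connectance",
                     mean_strength = "mean_strength"), function(col) {
    lapply(list(early = c(-Inf, cutoff), late = c(cutoff, Inf)),
           function(per) {
             tryCatch(trend_test(props[[col]], props$window_centre, per),
                      error = function(e) NULL)
           })
  })
  feedback <- tryCatch(
    feedback_test(drv$temperature, drv$phosphate, config,
                  names_ab = c("temperature", "phosphate")),
    error = function(e) NULL)
  stage("metrics")
  # --- scenarios ----------------------------------------------------
  scen <- NULL
  if (scenarios) {
    axes <- make_grid_axes(drv$temperature, drv$phosphate,
                           config$grid_resolution)
    scen <- lapply(c(connectance = "connectance",
                     mean_strength = "mean_strength"), function(col) {
      prop <- props[, c("window_centre", col)]
      prop <- prop[is.finite(prop[[col]]), ]
      if (nrow(prop) < 20) return(NULL)
      blk <- scenario_block(prop, drv, depth, volume, smooth = config$window)
      th <- fit_theta(blk, config$theta_grid, config$exclusion_radius)
      grid <- ensemble_predict(blk, axes, as.numeric(th),
                               n_models = config$n_scenario_models,
                               subsample_frac = config$subsample_frac,
                               seed = pair_seed(config$master_seed, "scenario", col))
      grid$in_range <- observed_range_mask(blk, grid)
      list(theta = as.numeric(th), grid = grid)
    })
    stage("scenarios")
  }
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   master_seed = config$master_seed,
                   n_guilds = nrow(graph$nodes),
                   n_months = nrow(table))
  result <- list(network = net, properties = props, trophic = troph,
                 types = types, link_strengths = link_strengths,
                 trends = trends, feedback = feedback, scenario = scen,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Serialize every stage's tables as CSV plus a JSON manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  w(result$network$links, "link_series.csv")
  w(result$network$meta, "link_meta.csv")
  w(result$properties, "network_properties.csv")
  w(result$trophic, "trophic_control.csv")
  w(result$types, "interaction_types.csv")
  w(result$link_strengths, "link_strengths.csv")
  w(result$feedback, "feedback.csv")
  for (nm in names(result$scenario %||% list())) {
    if (!is.null(result$scenario[[nm]]))
      w(as.data.frame(result$scenario[[nm]]$grid),
        paste0("scenario_", nm, ".csv"))
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
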