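# End-to-end replications of the two experiments from a single config.

#' Build a pipeline run configuration
#'
#' All defaults are loadable without any external file; [read_run_config()]
#' overlays values from a YAML file onto these defaults.
#'
#' @param seed Integer master seed for the whole run.
#' @param experiment `"artificial"` (taped-out random designs on open
#'   grassland) or `"field"` (simulated beetle radio-tracking in forest).
#' @param n_designs_10,n_designs_20 Numbers of 10- and 20-step designs for
#'   the artificial experiment (defaults 3 and 3).
#' @param n_gps_repeats GPS re-recordings per design (default 3).
#' @param start `c(lon, lat)` reference/release point (WGS84).
#' @param declination Magnetic declination in degrees east-positive
#'   (default 0; e.g. +5.133 at a Budapest site in 2020).
#' @param sigma,canopy_factor,rain_factor GPS error model; see
#'   [gps_error_model()]. Field runs default both factors to 1.5.
#' @param passive_threshold Passive-fix cutoff in meters (default 0.5).
#' @param n_tracks,n_fixes Field-experiment scale (default 6 animals x 27
#'   fixes per method).
#' @param hmm_init HMM starting values; default [default_hmm_init()] with
#'   zero inflation 0 (artificial) or 0.5 (field).
#' @param hmm_starts Optimizer starts per HMM fit (default 3).
#' @param emulate_min_dist If `TRUE`, floors GPS-derived step lengths at
#'   1.6 m, emulating legacy trajectory software that rounds shorter steps up
#'   to a preset minimum. Default `FALSE`.
#' @param out_dir Optional output directory for CSV/GeoJSON artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, experiment = c("artificial", "field"),
                       n_designs_10 = 3, n_designs_20 = 3, n_gps_repeats = 3,
                       start = c(19.0609, 47.4724), declination = 0,
                       sigma = 3, canopy_factor = NULL, rain_factor = NULL,
                       passive_threshold = 0.5, n_tracks = 6, n_fixes = 27,
                       hmm_init = NULL, hmm_starts = 3,
                       emulate_min_dist = FALSE, out_dir = NULL) {
  experiment <- match.arg(experiment)
  field <- experiment == "field"
  if (is.null(canopy_factor)) canopy_factor <- if (field) 1.5 else 1
  if (is.null(rain_factor)) rain_factor <- if (field) 1.5 else 1
  if (is.null(hmm_init))
    hmm_init <- default_hmm_init(zero_mass = if (field) c(0.5, 0.5) else c(0, 0))
  structure(list(seed = seed, experiment = experiment,
                 n_designs_10 = n_designs_10, n_designs_20 = n_designs_20,
                 n_gps_repeats = n_gps_repeats, start = start,
                 declination = declination,
                 gps = gps_error_model(sigma, canopy_factor, rain_factor),
                 passive_threshold = passive_threshold,
                 n_tracks = n_tracks, n_fixes = n_fixes,
                 hmm_init = hmm_init, hmm_starts = hmm_starts,
                 emulate_min_dist = emulate_min_dist, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys matching the arguments of [run_config()]; every value has a
#' default, so an empty file is valid.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  keep <- intersect(names(vals), names(formals(run_config)))
  do.call(run_config, vals[keep])
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the artificial-trajectory experiment
#'
#' Generates the random designs (default three 10-step and three 20-step),
#' dead-reckons each into a DB-measured trajectory from the reference point,
#' simulates the configured number of GPS re-recordings per design, computes
#' per-fix error records and coordinate correlations, fits the error mixed
#' models, fits the two-state HMM separately to the DB- and GPS-measured
#' series and Viterbi-decodes every track, and compares the decoded state
#' proportions between methods.
#'
#' @param config A [run_config()] with `experiment = "artificial"`.
#' @return A `run_report` list; see the `counts`, `error_summary`,
#'   `correlations`, `models`, `hmm`, `state_comparison` elements. When
#'   `config$out_dir` is set, CSV outputs and a hashed manifest are written.
#' @export
run_experiment1 <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  n_per <- c(rep(10, config$n_designs_10), rep(20, config$n_designs_20))
  designs <- lapply(seq_along(n_per), function(i)
    generate_design(n_per[i], seed = NULL, design_id = paste0("D", i)))
  names(designs) <- vapply(designs, `[[`, "", "design_id")
  stage_log("generate", "%d designs (%s steps)", length(designs),
            paste(n_per, collapse = "/"))

  db_fixes <- list(); gps_fixes <- list()
  for (d in designs) {
    coords <- db_to_coords(config$start, d$steps, config$declination)
    db <- data.frame(track_id = d$design_id,
                     order = 0:(nrow(coords) - 1), method = "DB",
                     lon = coords$lon, lat = coords$lat, active = TRUE,
                     stringsAsFactors = FALSE)
    sim <- simulate_gps(db, config$gps, n_repeats = config$n_gps_repeats)
    db$design_id <- d$design_id
    db_fixes[[d$design_id]] <- db
    gps <- do.call(rbind, sim$gps_repeats)
    gps$design_id <- d$design_id
    gps_fixes[[d$design_id]] <- gps
  }
  db_fixes <- do.call(rbind, db_fixes); rownames(db_fixes) <- NULL
  gps_fixes <- do.call(rbind, gps_fixes); rownames(gps_fixes) <- NULL
  n_traj <- length(unique(db_fixes$track_id)) +
    length(unique(gps_fixes$track_id))
  n_fix <- nrow(db_fixes) + nrow(gps_fixes)
  stage_log("measure", "%d trajectories, %d fixes", n_traj, n_fix)

  analysis <- analyse_paired(db_fixes, gps_fixes, config,
                             passive_threshold = 0)
  report <- c(list(experiment = "artificial", seed = config$seed,
                   n_trajectories = n_traj, n_fixes = n_fix,
                   designs = designs, db_fixes = db_fixes,
                   gps_fixes = gps_fixes),
              analysis)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Run the simulated beetle radio-tracking experiment
#'
#' Simulates HMM-driven beetle tracks with passive fixes (zero-inflation 0.5)
#' recorded by both methods under a forest-grade GPS error model, then runs
#' the same analysis chain as [run_experiment1()] with passive fixes excluded
#' from the error models.
#'
#' @param config A [run_config()] with `experiment = "field"`.
#' @return A `run_report` list.
#' @export
run_experiment2 <- function(config = run_config(experiment = "field")) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  sim <- simulate_beetle_tracks(
    n_tracks = config$n_tracks, n_fixes = config$n_fixes,
    params = config$hmm_init, error_model = config$gps,
    passive_threshold = config$passive_threshold,
    start = config$start, n_repeats = 1, seed = NULL)
  db_fixes <- sim$db; gps_fixes <- sim$gps
  db_fixes$design_id <- db_fixes$track_id
  gps_fixes$design_id <- sub("_r[0-9]+$", "", gps_fixes$track_id)
  n_traj <- length(unique(db_fixes$track_id)) +
    length(unique(gps_fixes$track_id))
  n_fix <- nrow(db_fixes) + nrow(gps_fixes)
  stage_log("simulate", "%d trajectories, %d fixes (%d animals)",
            n_traj, n_fix, config$n_tracks)
  analysis <- analyse_paired(db_fixes, gps_fixes, config,
                             passive_threshold = config$passive_threshold)
  report <- c(list(experiment = "field", seed = config$seed,
                   n_trajectories = n_traj, n_fixes = n_fix,
                   true_states = sim$states, db_fixes = db_fixes,
                   gps_fixes = gps_fixes),
              analysis)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Shared analysis chain: error records -> summaries -> LMMs -> HMM fits ->
# Viterbi decoding -> state-proportion GLMM.
analyse_paired <- function(db_fixes, gps_fixes, config, passive_threshold) {
  gps_ids <- unique(gps_fixes$track_id)
  records <- do.call(rbind, lapply(gps_ids, function(gid) {
    did <- gps_fixes$design_id[match(gid, gps_fixes$track_id)]
    r <- pair_and_score(db_fixes[db_fixes$track_id == did, ],
                        gps_fixes[gps_fixes$track_id == gid, ],
                        passive_threshold = passive_threshold)
    if (nrow(r)) r$design_id <- did
    r
  }))
  rownames(records) <- NULL
  err <- summarize_errors(records)
  stage_log("errors", "%d active records: distance %.3f m, bearing %.3f deg",
            err$n, err$mean_distance_error, err$mean_bearing_error)

  # pair every GPS fix with its DB counterpart, active arrivals only
  db_paired <- do.call(rbind, lapply(gps_ids, function(gid) {
    did <- gps_fixes$design_id[match(gid, gps_fixes$track_id)]
    db <- db_fixes[db_fixes$track_id == did, ]
    db[db$active & db$order > 0, ]
  }))
  gps_paired <- do.call(rbind, lapply(gps_ids, function(gid) {
    did <- gps_fixes$design_id[match(gid, gps_fixes$track_id)]
    db <- db_fixes[db_fixes$track_id == did, ]
    gp <- gps_fixes[gps_fixes$track_id == gid, ]
    gp[db$active & db$order > 0, ]
  }))
  correlations <- coordinate_correlation(db_paired, gps_paired)

  models <- list(
    distance_error_vs_distance =
      fit_error_lmm(records, "distance_error", "db_distance", "track_id"),
    bearing_error_vs_bearing =
      fit_error_lmm(transform(records,
                              bearing_cat = round(db_bearing / 30) %% 12),
                    "bearing_error", "bearing_cat", "track_id",
                    categorical = TRUE),
    bearing_error_vs_distance =
      fit_error_lmm(records, "bearing_error", "db_distance", "track_id"),
    distance_error_vs_order =
      fit_error_lmm(records, "distance_error", "fix_order", "track_id"),
    bearing_error_vs_order =
      fit_error_lmm(records, "bearing_error", "fix_order", "track_id"),
    total_length_vs_method = total_length_comparison(db_fixes, gps_fixes))
  stage_log("models", "%d mixed models fitted", length(models))

  min_dist <- if (isTRUE(config$emulate_min_dist)) 1.6 else 0
  db_series <- fixes_to_series(db_fixes)
  gps_series <- fixes_to_series(gps_fixes, min_distance = min_dist)
  fit_db <- fit_hmm(db_series, init = config$hmm_init,
                    n_starts = config$hmm_starts, seed = config$seed)
  fit_gps <- fit_hmm(gps_series, init = config$hmm_init,
                     n_starts = config$hmm_starts, seed = config$seed + 1)
  stage_log("hmm", "logLik DB %.2f, GPS %.2f", fit_db$log_likelihood,
            fit_gps$log_likelihood)

  counts <- rbind(count_states(fit_db$decoded_states, method = "DB"),
                  count_states(fit_gps$decoded_states, method = "GPS"))
  counts$design <- sub("_r[0-9]+$", "", counts$track_id)
  comparison <- compare_proportions(counts)
  stage_log("compare", "random walk DB %.1f%% vs GPS %.1f%%",
            100 * comparison$prop_db, 100 * comparison$prop_gps)

  list(error_records = records, error_summary = err,
       correlations = correlations, models = models,
       model_table = model_table(models, comparison),
       hmm = list(DB = fit_db, GPS = fit_gps), state_counts = counts,
       state_comparison = comparison)
}

# One row per fitted model, mirroring the published results-table layout.
model_table <- function(models, comparison) {
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    data.frame(model = nm, chi_sq = m$chi_sq, df = m$df, p = m$p_value,
               marginal_R2 = m$marginal_R2, conditional_R2 = m$conditional_R2,
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1]] <-
    data.frame(model = "prop_random_walk_vs_method", chi_sq = comparison$chi_sq,
               df = comparison$df, p = comparison$p_value,
               marginal_R2 = comparison$marginal_R2,
               conditional_R2 = comparison$conditional_R2,
               stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report (%s experiment, seed %d)\n", x$experiment, x$seed))
  cat(sprintf("  %d trajectories, %d fixes\n", x$n_trajectories, x$n_fixes))
  cat(sprintf("  distance error: %.3f m (SEM %.3f), bearing error: %.3f deg (SEM %.3f)\n",
              x$error_summary$mean_distance_error,
              x$error_summary$sem_distance_error,
              x$error_summary$mean_bearing_error,
              x$error_summary$sem_bearing_error))
  cat("  model table:\n")
  print(x$model_table, row.names = FALSE, digits = 3)
  print(x$state_comparison)
  invisible(x)
}

# Write CSV artifacts plus a manifest with md5 hashes.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$db_fixes, "db_fixes.csv")
  wr(report$gps_fixes, "gps_fixes.csv")
  wr(report$error_records, "error_records.csv")
  wr(report$model_table, "model_results.csv")
  wr(report$state_counts, "state_counts.csv")
  wr(rbind(cbind(method = "DB", hmm_report(report$hmm$DB)),
           cbind(method = "GPS", hmm_report(report$hmm$GPS))),
     "hmm_report.csv")
  cmp <- report$state_comparison
  wr(data.frame(estimate = cmp$estimate, chi_sq = cmp$chi_sq, df = cmp$df,
                p = cmp$p_value, prop_db = cmp$prop_db,
                prop_gps = cmp$prop_gps, prop_diff_pp = cmp$prop_diff_pp),
     "comparison_results.csv")
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = report$seed, experiment = report$experiment,
                            files = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
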