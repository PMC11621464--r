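# polynomial rolling hash of a character scalar, reported as 8 hex digits;
# used to stamp outputs with the configuration they came from
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end study: where the recordings come
#' from (a synthetic study or CSV + Newick files), the rhythm settings, and
#' the comparative settings.
#'
#' @param mode `"synthetic"` (generate recordings with
#'   [simulate_study_dataset()]) or `"csv"` (read `series_csv` and
#'   `tree_file`).
#' @param study a [study_config()] (synthetic mode). Its seed is overridden
#'   by the pipeline master seed so one seed reproduces the whole run.
#' @param series_csv path to a long-format series CSV (csv mode).
#' @param tree_file path to a Newick chronogram (csv mode).
#' @param window Gaussian smoothing window (points).
#' @param voices wavelet voices per octave.
#' @param truncate_frames length colony series are truncated to before metric
#'   computation; `NULL` uses the shortest individual series.
#' @param n_boot bootstrap replicates for rate and disparity comparisons
#'   (>= 100).
#' @param n_sensitivity sampling iterations of the PGLS sensitivity analysis.
#' @param seed master seed; per-stage child seeds are derived from it
#'   deterministically so stages can be rerun in isolation.
#' @param out_dir optional output directory for report.json, metrics.csv and
#'   tip_values.csv.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "csv"),
                            study = study_config(), series_csv = NULL,
                            tree_file = NULL, window = 15L, voices = 12L,
                            truncate_frames = NULL, n_boot = 10000L,
                            n_sensitivity = 10000L, seed = 1L,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv") {
    if (is.null(series_csv) || is.null(tree_file))
      stop("csv mode needs series_csv and tree_file", call. = FALSE)
  }
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  structure(list(mode = mode, study = study, series_csv = series_csv,
                 tree_file = tree_file, window = as.integer(window),
                 voices = as.integer(voices),
                 truncate_frames = truncate_frames,
                 n_boot = as.integer(n_boot),
                 n_sensitivity = as.integer(n_sensitivity),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.load_inputs <- function(config, study_seed) {
  if (config$mode == "synthetic") {
    st <- config$study
    st$seed <- study_seed
    ds <- simulate_study_dataset(st)
    list(series = ds$series, tree = ds$tree, provenance = ds$provenance)
  } else {
    list(series = read_series_csv(config$series_csv),
         tree = ape::read.tree(config$tree_file), provenance = NULL)
  }
}

# per-species SD of a per-recording metric column at one level (intraspecific
# spread used by the sensitivity PGLS); species with one record get 0
.intraspecific_sd <- function(metrics, column, level) {
  df <- metrics[metrics$level == level & is.finite(metrics[[column]]), ]
  s <- vapply(split(df[[column]], df$species),
              function(v) if (length(v) > 1) stats::sd(v) else 0, numeric(1))
  s
}

#' Run the full study pipeline
#'
#' Executes the complete analysis chain: obtain recordings (synthetic or from
#' files), compute rhythm metrics per series (colony series truncated to the
#' individual recording length first, so series of equal length are
#' compared), estimate species tip values, and run the evolutionary
#' inference — bootstrap rate comparison for rhythmicity and period, PGLS and
#' sensitivity PGLS for both colony/individual trait pairs, and the
#' phenospace disparity comparison. Interspecific-difference tests for each
#' trait are reported descriptively. The run is fully reproducible from
#' (config, seed).
#'
#' @param config a [pipeline_config()].
#' @return list of class `study_report` with elements `metrics`,
#'   `tip_values` (raw and standardized), `rates` (per trait),
#'   `pgls` / `sensitivity` (per trait pair), `disparity`,
#'   `species_effects`, and `meta` (seed, child seeds, config hash, input
#'   provenance).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  child <- sample.int(.Machine$integer.max - 1L, 6L)
  message("[pipeline] loading inputs (mode = ", config$mode, ")")
  inp <- .load_inputs(config, study_seed = child[1])
  n_series <- length(inp$series)
  message("[pipeline] ", n_series, " series, ",
          length(inp$tree$tip.label), " tree tips")

  lens_ind <- vapply(inp$series, function(s)
    if (s$level == "individual") length(s$values) else NA_integer_,
    integer(1))
  trunc <- config$truncate_frames
  if (is.null(trunc))
    trunc <- if (all(is.na(lens_ind))) NULL else min(lens_ind, na.rm = TRUE)

  message("[pipeline] computing rhythm metrics (truncate colony series to ",
          if (is.null(trunc)) "full length" else trunc, " frames)")
  metrics <- rhythm_metrics_table(inp$series, truncate_frames = trunc,
                                  window = config$window,
                                  voices = config$voices)

  absent <- setdiff(unique(metrics$species), inp$tree$tip.label)
  if (length(absent))
    stop("species present in metrics but absent from tree: ",
         paste(absent, collapse = ", "), call. = FALSE)

  tips <- species_tip_values(metrics)
  tips_std <- standardize_traits(tips)

  message("[pipeline] bootstrap rate comparisons (n_boot = ",
          config$n_boot, ")")
  rates <- list(
    rhythmicity = bootstrap_rate_comparison(metrics, inp$tree, "rhythmicity",
                                            n_boot = config$n_boot,
                                            seed = child[2]),
    period = bootstrap_rate_comparison(metrics, inp$tree, "period",
                                       n_boot = config$n_boot,
                                       seed = child[3]))

  as_named <- function(col) stats::setNames(tips[[col]], tips$species)
  message("[pipeline] PGLS and sensitivity PGLS (n_iter = ",
          config$n_sensitivity, ")")
  pgls_fits <- list(
    rhythmicity = pgls(inp$tree, x = as_named("individual_rhythmicity"),
                       y = as_named("colony_rhythmicity")),
    period = pgls(inp$tree, x = as_named("individual_period_min"),
                  y = as_named("colony_period_min")))
  sens <- list(
    rhythmicity = sensitivity_pgls(
      inp$tree, x = as_named("individual_rhythmicity"),
      y = as_named("colony_rhythmicity"),
      x_sd = .intraspecific_sd(metrics, "beta", "individual"),
      y_sd = .intraspecific_sd(metrics, "beta", "colony"),
      n_iter = config$n_sensitivity, seed = child[4]),
    period = sensitivity_pgls(
      inp$tree, x = as_named("individual_period_min"),
      y = as_named("colony_period_min"),
      x_sd = .intraspecific_sd(metrics, "dominant_period_min", "individual"),
      y_sd = .intraspecific_sd(metrics, "dominant_period_min", "colony"),
      n_iter = config$n_sensitivity, seed = child[5]))

  message("[pipeline] disparity comparison")
  phen <- function(prefix) {
    m <- as.matrix(tips[, paste0(prefix, c("_rhythmicity", "_period_min"))])
    dimnames(m) <- list(tips$species, c("rhythmicity", "period"))
    m
  }
  disparity <- disparity_comparison(phen("colony"), phen("individual"),
                                    n_boot = config$n_boot, seed = child[6])

  eff <- rbind(species_effect_test(metrics, "beta", "colony"),
               species_effect_test(metrics, "beta", "individual"),
               species_effect_test(metrics, "dominant_period_min", "colony"),
               species_effect_test(metrics, "dominant_period_min",
                                   "individual"))

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  report <- structure(list(
    metrics = metrics, tip_values = tips, tip_values_standardized = tips_std,
    rates = rates, pgls = pgls_fits, sensitivity = sens,
    disparity = disparity, species_effects = eff,
    meta = list(seed = config$seed, child_seeds = child,
                config_hash = .config_hash(cfg_for_hash),
                mode = config$mode, n_series = n_series,
                inputs = c(series_csv = config$series_csv,
                           tree_file = config$tree_file))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  %d series, %d species (config %s, seed %d)\n",
              x$meta$n_series, nrow(x$tip_values), x$meta$config_hash,
              x$meta$seed))
  cat(sprintf("  rate comparison: rhythmicity p = %.4g, period p = %.4g\n",
              x$rates$rhythmicity$p_value, x$rates$period$p_value))
  cat(sprintf("  PGLS: rhythmicity t = %.3g (p = %.3g), period t = %.3g (p = %.3g)\n",
              x$pgls$rhythmicity$t_statistic, x$pgls$rhythmicity$p_value,
              x$pgls$period$t_statistic, x$pgls$period$p_value))
  cat(sprintf("  sensitivity PGLS median p: rhythmicity %.3g, period %.3g\n",
              x$sensitivity$rhythmicity$median_p, x$sensitivity$period$median_p))
  cat(sprintf("  disparity: colony %.3g vs individual %.3g (p = %.4g)\n",
              x$disparity$sum_of_variances_colony,
              x$disparity$sum_of_variances_individual,
              x$disparity$p_value))
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `report.json` (all fits, bootstrap distributions summarized by
#' median and 2.5/97.5 percentiles), `tip_values.csv` and `metrics.csv`.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tip_values, file.path(dir, "tip_values.csv"),
                   row.names = FALSE)
  summarize_rate <- function(r)
    list(trait = r$trait, sigma2_colony = r$sigma2_colony,
         sigma2_individual = r$sigma2_individual,
         observed_difference = r$observed_difference, p_value = r$p_value,
         n_boot = r$n_boot, seed = r$seed, summary = r$summary)
  out <- list(
    meta = report$meta,
    rates = lapply(report$rates, summarize_rate),
    pgls = lapply(report$pgls, unclass),
    sensitivity = lapply(report$sensitivity, function(s)
      list(median_p = s$median_p, median_slope = s$median_slope,
           n_iter = s$n_iter, seed = s$seed)),
    disparity = list(
      sum_of_variances_colony = report$disparity$sum_of_variances_colony,
      sum_of_variances_individual = report$disparity$sum_of_variances_individual,
      p_value = report$disparity$p_value, n_boot = report$disparity$n_boot,
      summary = report$disparity$summary),
    species_effects = report$species_effects)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Validate pipeline inputs
#'
#' Runs structural checks on the configured inputs and reports pass/fail per
#' check instead of raising: CSV schema, tree/series species concordance,
#' series length vs the truncation setting, and frame-index continuity.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  checks <- list()
  add <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail)
  if (config$mode == "synthetic") {
    add("config", inherits(config$study, "study_config"),
        "synthetic mode with a study_config")
    return(do.call(rbind, checks))
  }
  df <- tryCatch(utils::read.csv(config$series_csv), error = function(e) NULL)
  need <- c("series_id", "species", "colony_id", "individual_id", "level",
            "frame_index", "time_s", "activity")
  schema_ok <- !is.null(df) && all(need %in% names(df))
  add("csv_schema", schema_ok,
      if (schema_ok) "" else paste("missing columns:",
                                   paste(setdiff(need, names(df)),
                                         collapse = ", ")))
  tree <- tryCatch(ape::read.tree(config$tree_file), error = function(e) NULL)
  add("tree_readable", !is.null(tree), config$tree_file)
  if (schema_ok && !is.null(tree)) {
    absent <- setdiff(unique(df$species), tree$tip.label)
    add("species_concordance", length(absent) == 0L,
        if (length(absent)) paste("missing from tree:",
                                  paste(absent, collapse = ", ")) else "")
    gaps <- vapply(split(df$frame_index, df$series_id),
                   function(fi) any(diff(sort(fi)) != 1L), TRUE)
    add("frame_continuity", !any(gaps),
        if (any(gaps)) paste("gaps in:",
                             paste(names(gaps)[gaps], collapse = ", ")) else "")
    if (!is.null(config$truncate_frames)) {
      lens <- vapply(split(df, df$series_id),
                     function(d) nrow(d), integer(1))
      lv <- vapply(split(df, df$series_id),
                   function(d) d$level[1], "")
      short <- names(lens)[lv == "colony" & lens < config$truncate_frames]
      add("series_length_vs_truncation", length(short) == 0L,
          if (length(short)) paste("colony series shorter than truncation:",
                                   paste(short, collapse = ", ")) else "")
    }
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
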