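#' Construct an activity time series
#'
#' The basic record of the package: one recording's per-frame activity values
#' at a fixed sampling interval, tagged with the biological unit it came from.
#' Colony-level series hold the proportion (or flow magnitude) of movement in
#' the nest per 30 s frame transition; individual-level series hold the
#' centroid displacement of a single isolated worker.
#'
#' @param values numeric vector of finite, non-negative activity values,
#'   length >= 2.
#' @param sample_interval_s sampling interval in seconds (30 for study-shaped
#'   recordings).
#' @param level `"colony"` or `"individual"`.
#' @param species species name.
#' @param colony_id colony identifier (colony of origin for individuals).
#' @param individual_id individual identifier, or `NA` for colony series.
#' @param source how the values were obtained: one of `"pixel_change"`,
#'   `"optical_flow"`, `"centroid_displacement"`, `"synthetic"`.
#' @param series_id unique identifier for the recording.
#' @return an object of class `activity_series`.
#' @export
activity_series <- function(values, sample_interval_s = 30,
                            level = c("colony", "individual"),
                            species = NA_character_, colony_id = NA_character_,
                            individual_id = NA_character_,
                            source = c("synthetic", "pixel_change",
                                       "optical_flow", "centroid_displacement"),
                            series_id = NA_character_) {
  level <- match.arg(level)
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("an activity series needs at least 1 value", call. = FALSE)
  if (!all(is.finite(values)))
    stop("activity values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("activity values must be >= 0", call. = FALSE)
  if (!is.numeric(sample_interval_s) || sample_interval_s <= 0)
    stop("sample_interval_s must be > 0", call. = FALSE)
  structure(
    list(values = values, sample_interval_s = as.numeric(sample_interval_s),
         level = level, species = as.character(species),
         colony_id = as.character(colony_id),
         individual_id = as.character(individual_id),
         source = source, series_id = as.character(series_id)),
    class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf(
    "<activity_series> %s: %d frames @ %gs (%s, %s, source=%s)\n",
    x$series_id, length(x$values), x$sample_interval_s, x$level,
    x$species, x$source))
  invisible(x)
}

#' @export
length.activity_series <- function(x) length(x$values)

#' @export
as.data.frame.activity_series <- function(x, ...) {
  n <- length(x$values)
  data.frame(series_id = x$series_id, species = x$species,
             colony_id = x$colony_id, individual_id = x$individual_id,
             level = x$level, frame_index = seq_len(n) - 1L,
             time_s = (seq_len(n) - 1L) * x$sample_interval_s,
             activity = x$values, stringsAsFactors = FALSE)
}

#' Write a collection of activity series to long-format CSV
#'
#' Columns: series_id, species, colony_id, individual_id, level, frame_index,
#' time_s, activity.
#'
#' @param series list of [activity_series] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "activity_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read activity series from long-format CSV
#'
#' Inverse of [write_series_csv()]. The `sample_interval_s` of each series is
#' inferred from consecutive `time_s` values.
#'
#' @param path CSV path with the long-format schema of [write_series_csv()].
#' @return list of [activity_series] objects, one per unique `series_id`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "species", "colony_id", "individual_id", "level",
            "frame_index", "time_s", "activity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("series CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$series_id), function(d) {
    d <- d[order(d$frame_index), ]
    dt <- diff(d$time_s)
    activity_series(d$activity, sample_interval_s = dt[1],
                    level = d$level[1], species = d$species[1],
                    colony_id = as.character(d$colony_id[1]),
                    individual_id = as.character(d$individual_id[1]),
                    source = "synthetic", series_id = d$series_id[1])
  })
  out[order(names(out))]
}
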