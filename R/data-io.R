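#' Read a turbine detection-parameter table
#'
#' The detection table holds one row per turbine and year with the carcass
#' totals and the independently estimated detection parameters: `C` (total
#' carcasses found), `T` (number of searches), `a` (fall-in proportion,
#' treated as known), `s` (daily persistence probability) with `s_lwr` /
#' `s_upr` 95% confidence limits, `f` (searcher efficiency) with limits,
#' and `p` (overall carcass detection probability) with limits.
#'
#' @param path Path to a CSV file with a header row and the columns listed
#'   above (comma-separated, `.` decimal separator, UTF-8).
#' @return A tibble with one row per turbine, columns as in the file.
#' @examples
#' det <- read_detection_table(collmix_extdata("table2_detection.csv"))
#' dplyr::count(det, year)
#' @export
read_detection_table <- function(path) {
  df <- read_csv_checked(path, detection_table_columns())
  num_cols <- setdiff(detection_table_columns(), "turbine")
  for (col in num_cols) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop_validation(sprintf("non-numeric value in column '%s' at data row %d", col, bad[1]))
    }
  }
  for (col in c("a", "s", "s_lwr", "s_upr", "f", "f_lwr", "f_upr", "p", "p_lwr", "p_upr")) {
    bad <- which(df[[col]] < 0 | df[[col]] > 1)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "probability column '%s' outside [0, 1] at data row %d (value %g)",
        col, bad[1], df[[col]][bad[1]]
      ))
    }
  }
  for (par in c("s", "f", "p")) {
    lwr <- df[[paste0(par, "_lwr")]]
    upr <- df[[paste0(par, "_upr")]]
    bad <- which(lwr > upr)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "confidence limits for '%s' have lower > upper at data row %d", par, bad[1]
      ))
    }
  }
  if (!is_count(df$C)) stop_validation("column 'C' must hold non-negative integers")
  if (!is_count(df$`T`) || any(df$`T` < 1)) {
    stop_validation("column 'T' must hold positive integers")
  }
  for (col in c("turbine", "year", "C", "T")) df[[col]] <- as_whole(df[[col]])
  df
}

# Store integer-valued columns as integers so write/read cycles are exact.
as_whole <- function(x) {
  if (is.numeric(x) && all(is.finite(x)) && all(x == floor(x))) as.integer(x) else x
}

detection_table_columns <- function() {
  c(
    "turbine", "year", "C", "T", "a",
    "s", "s_lwr", "s_upr", "f", "f_lwr", "f_upr", "p", "p_lwr", "p_upr"
  )
}

night_table_columns <- function() {
  c("turbine", "night", "c", "activity", "wind", "searched")
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop_format(sprintf("empty file: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE, comment = "#")
  if (nrow(df) == 0) stop_format(sprintf("no data rows in %s", path))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  as_tibble(df[required])
}

#' Read a nightly carcass-search record table
#'
#' One row per turbine-night: `turbine`, `night` (1-based index of the 24-h
#' interval ending at the search), `c` (carcasses found, 0 when not
#' searched), `activity` (echolocation recordings that night), `wind`
#' (nightly median wind speed, m/s) and `searched` (logical).  Rows are
#' returned sorted by turbine and night; night indices must be consecutive
#' within each turbine.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble sorted by `(turbine, night)`.
#' @export
read_night_table <- function(path) {
  df <- read_csv_checked(path, night_table_columns())
  df$searched <- as.logical(df$searched)
  for (col in c("night", "c", "activity", "wind")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop_validation(sprintf("non-numeric value in column '%s' at data row %d", col, bad[1]))
    }
  }
  bad <- which(df$c < 0 | df$c != floor(df$c))
  if (length(bad) > 0) {
    stop_validation(sprintf("negative or non-integer carcass count at data row %d", bad[1]))
  }
  bad <- which(df$activity < 0 | df$activity != floor(df$activity))
  if (length(bad) > 0) {
    stop_validation(sprintf("negative or non-integer activity at data row %d", bad[1]))
  }
  bad <- which(df$wind < 0)
  if (length(bad) > 0) {
    stop_validation(sprintf("negative wind speed at data row %d", bad[1]))
  }
  bad <- which(df$c > 0 & !df$searched)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "carcass count > 0 on an unsearched night at data row %d", bad[1]
    ))
  }
  for (col in c("turbine", "night", "c", "activity")) df[[col]] <- as_whole(df[[col]])
  df <- arrange(df, .data$turbine, .data$night)
  check_night_index(df)
  df
}

check_night_index <- function(nights) {
  by_turbine <- split(nights$night, nights$turbine)
  for (id in names(by_turbine)) {
    idx <- by_turbine[[id]]
    if (idx[1] != 1 || any(diff(idx) != 1)) {
      stop_validation(sprintf(
        "night index for turbine %s must start at 1 and increase without gaps", id
      ))
    }
  }
  invisible(nights)
}

#' Write the detection / night tables
#'
#' Inverse of [read_detection_table()] and [read_night_table()]; numeric
#' values are written at full precision so that a write/read cycle is an
#' identity.
#'
#' @param x Tibble as returned by the corresponding reader.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(x, path) {
  readr::write_csv(x[detection_table_columns()], path)
  invisible(path)
}

#' @rdname write_detection_table
#' @export
write_night_table <- function(x, path) {
  readr::write_csv(x[night_table_columns()], path)
  invisible(path)
}

#' Bundle night and detection tables into one dataset object
#'
#' @param nights Night table (see [read_night_table()]).
#' @param detections Detection table (see [read_detection_table()]).
#' @return A list of class `collision_data` with elements `nights` and
#'   `detections`.
#' @export
collision_data <- function(nights, detections) {
  missing <- setdiff(unique(nights$turbine), detections$turbine)
  if (length(missing) > 0) {
    stop_validation(sprintf(
      "turbine(s) %s appear in the night table but not in the detection table",
      paste(missing, collapse = ", ")
    ))
  }
  check_night_index(arrange(nights, .data$turbine, .data$night))
  structure(
    list(nights = as_tibble(nights), detections = as_tibble(detections)),
    class = "collision_data"
  )
}

#' @export
print.collision_data <- function(x, ...) {
  cat(sprintf(
    "<collision_data> %d turbine-nights at %d turbines (%d searched, %d carcasses found)\n",
    nrow(x$nights), length(unique(x$nights$turbine)),
    sum(x$nights$searched), sum(x$nights$c)
  ))
  invisible(x)
}

#' Per-year summary of a carcass-search dataset
#'
#' Sums carcasses and turbine-nights (search effort `T`) per year and
#' reports the unweighted mean of the per-turbine detection probabilities.
#'
#' @param detections Detection table, or a `collision_data` object.
#' @return A tibble with one row per year: `year`, `n_turbines`,
#'   `total_carcasses`, `turbine_nights`, `mean_detection`.
#' @examples
#' summarize_dataset(example_detection_table())
#' @export
summarize_dataset <- function(detections) {
  if (inherits(detections, "collision_data")) detections <- detections$detections
  if (nrow(detections) == 0) stop_validation("empty detection table")
  detections %>%
    group_by(.data$year) %>%
    summarise(
      n_turbines = dplyr::n(),
      total_carcasses = sum(.data$C),
      turbine_nights = sum(.data$`T`),
      mean_detection = mean(.data$p),
      .groups = "drop"
    )
}

#' Paths to bundled example data
#'
#' The package ships the published per-turbine detection table and season
#' summaries from a two-year carcass-search study at 30 German wind
#' turbines (12 sampled in 2007, 18 in 2008), together with the fitted
#' collision-model coefficient summaries reported for those data.
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or vector of file names).
#' @export
collmix_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "collmix")))
  }
  path <- system.file("extdata", file, package = "collmix")
  if (path == "") stop_format(sprintf("no bundled file '%s'", file))
  path
}

#' @rdname collmix_extdata
#' @export
example_detection_table <- function() {
  read_detection_table(collmix_extdata("table2_detection.csv"))
}

#' @rdname collmix_extdata
#' @export
example_season_summary <- function() {
  readr::read_csv(collmix_extdata("table1_summary.csv"), show_col_types = FALSE)
}

#' @rdname collmix_extdata
#' @export
reported_coefficients <- function() {
  readr::read_csv(collmix_extdata("table4_coefficients.csv"), show_col_types = FALSE)
}
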