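#' Read a trend dataset from a CSV file
#'
#' Reads a delimited table with a header and assembles a [trend_data()]
#' object from named columns. Rows with missing values in the selected
#' columns are rejected with their row numbers. Two coordinate columns
#' named (case-insensitively) `lon`/`lat` (or `longitude`/`latitude`)
#' switch the distance metric to great-circle automatically.
#'
#' @param path CSV file path.
#' @param response Response column name (string).
#' @param time Optional time column name.
#' @param coords Optional character vector of coordinate column names.
#' @param group Optional grouping column name.
#' @param metric `"euclidean"`, `"greatcircle"`, or `NULL` to auto-detect
#'   from the coordinate names.
#' @return A `"trend_data"` tibble.
#' @export
read_trend_data <- function(path, response, time = NULL, coords = NULL,
                            group = NULL, metric = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(metric)) {
    lonlat <- length(coords) == 2L &&
      all(tolower(coords) %in% c("lon", "long", "longitude", "lat", "latitude"))
    metric <- if (lonlat) "greatcircle" else "euclidean"
  }
  trend_data(raw,
    response = !!response, time = !!time, coords = coords,
    group = !!group, metric = metric
  )
}

#' Write an analysis report
#'
#' Writes a human-readable text summary of a [analyze_trend()] result plus
#' machine-readable twins: a coefficients CSV and, when jsonlite is
#' available, a JSON file with the full decision path. Re-running the same
#' analysis with the same seed yields byte-identical machine-readable
#' output.
#'
#' @param analysis A `"trend_analysis"` object.
#' @param path Output path stem; `.txt`, `.csv` and `.json` files are
#'   written next to it.
#' @param seed Seed used for any stochastic part of the analysis, echoed
#'   into the report.
#' @return Invisibly, the paths written.
#' @export
write_trend_report <- function(analysis, path, seed = NULL) {
  if (!inherits(analysis, "trend_analysis")) abort("`analysis` must come from analyze_trend().")
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("output directory does not exist: ", dir))
  if (file.access(dir, 2L) != 0L) abort(paste0("output directory is not writable: ", dir))
  stem <- sub("\\.(txt|csv|json)$", "", path)
  txt <- paste0(stem, ".txt")
  csv <- paste0(stem, ".csv")
  cmp <- dplyr::left_join(
    dplyr::select(tidy(analysis$fit_ols), "term", t_ols = "statistic"),
    dplyr::select(tidy(analysis), "term", t_final = "statistic"),
    by = "term"
  )
  lines <- c(
    utils::capture.output(print(analysis)),
    "", "OLS vs corrected slope t-values:",
    utils::capture.output(print(as.data.frame(cmp), digits = 4)),
    if (!is.null(seed)) c("", paste("seed:", seed))
  )
  writeLines(lines, txt)
  readr::write_csv(tidy(analysis), csv)
  written <- c(txt, csv)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    json <- paste0(stem, ".json")
    payload <- list(
      branch = analysis$branch,
      dw_ols = unclass(tidy(analysis$dw_ols)),
      candidates = analysis$candidates,
      coefficients = tidy(analysis),
      messages = analysis$messages,
      seed = seed
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, json)
  }
  invisible(written)
}
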