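#' Run configuration for the identification workflow
#'
#' Collects the tunable parameters of [identify_file()]: the window function,
#' optional background removal, the presence threshold, and report depth.
#'
#' @param window Window kind, `"gaussian"` (default) or `"rectangular"`.
#' @param sigma Window width in m/z (default 0.5).
#' @param clean Run background removal on grid (profile) input (default
#'   `FALSE`).
#' @param q,p Background-removal selectivity and iteration cap (defaults 1.5
#'   and 3).
#' @param c Presence threshold (default 1e-15).
#' @param top Number of candidates in the report (default 10).
#' @param format Input interpretation: `"auto"` (uniform-grid heuristic),
#'   `"grid"`, or `"peaks"`.
#' @param cutoff Gaussian window evaluation cutoff in sigmas (default `Inf`:
#'   full evaluation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(window = c("gaussian", "rectangular"), sigma = 0.5,
                       clean = FALSE, q = 1.5, p = 3, c = 1e-15, top = 10,
                       format = c("auto", "grid", "peaks"), cutoff = Inf) {
  window <- match.arg(window)
  format <- match.arg(format)
  stopifnot(top >= 1)
  structure(list(window = window, sigma = sigma, clean = isTRUE(clean),
                 q = q, p = p, c = c, top = as.integer(top),
                 format = format, cutoff = cutoff),
            class = "run_config")
}

#' Read a query spectrum, auto-detecting grid vs peak-list form
#'
#' A file whose m/z column is uniformly spaced (within 1e-6 relative) and has
#' at least 8 rows is read as a grid (profile) spectrum; anything else is
#' read as a discrete peak list. Set `format` to override the heuristic.
#'
#' @param path Path to a two-column spectrum file.
#' @param format `"auto"`, `"grid"`, or `"peaks"`.
#' @return A `grid_spectrum` or `peak_list`.
#' @export
read_spectrum <- function(path, format = c("auto", "grid", "peaks")) {
  format <- match.arg(format)
  if (format == "grid") return(read_grid_spectrum(path))
  if (format == "peaks") return(read_peak_list(path))
  xy <- parse_xy(path)
  if (length(xy$x) >= 8L && all(diff(xy$x) > 0)) {
    dx <- diff(xy$x)
    if (max(abs(dx - mean(dx))) <= 1e-6 * mean(dx))
      return(read_grid_spectrum(path))
  }
  read_peak_list(path)
}

#' Identify a spectrum against a spectral library
#'
#' The end-to-end workflow: read the query (grid or peak list), optionally
#' strip the background (grid input only), rank every library entry by the
#' metametric, and report the best candidates. The report is preliminary
#' evidence only: identification is always biased toward the library's
#' contents and must be confirmed by expert inspection and independent
#' methods.
#'
#' @param spectrum_path Path to the query spectrum file.
#' @param db_path Path to the library root directory (ignored when `db` is
#'   given).
#' @param config A `run_config`.
#' @param db Optionally, an already loaded `ms_database`.
#' @return An object of class `identification_report`: list with `results`
#'   (the top `config$top` rows of the ranking), `full` (all entries),
#'   `threshold` (background threshold applied, or `NA`), `n_entries`,
#'   `query`, `config`, and `note` (the expert-confirmation caveat).
#' @export
identify_file <- function(spectrum_path, db_path = NULL,
                          config = run_config(), db = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(db)) {
    if (is.null(db_path)) stop("supply 'db_path' or a loaded 'db'")
    db <- load_database(db_path)
  }
  query <- read_spectrum(spectrum_path, config$format)
  threshold <- NA_real_
  if (config$clean && inherits(query, "grid_spectrum")) {
    cleaned <- remove_background(query, q = config$q, p = config$p)
    query <- cleaned$cleaned
    threshold <- cleaned$threshold
  }
  w <- window_spec(config$window, config$sigma)
  tab <- rank_against_database(query, db, w, config$c, config$cutoff)
  structure(list(results = utils::head(tab, config$top),
                 full = tab,
                 threshold = threshold,
                 n_entries = nrow(tab),
                 query = spectrum_path,
                 config = config,
                 note = paste("Preliminary identification only: results are",
                              "biased toward the library contents and require",
                              "expert confirmation by independent methods.")),
            class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("Query: %s  (library: %d entries)\n", x$query, x$n_entries))
  if (!is.na(x$threshold))
    cat(sprintf("Background removed at threshold %.6g\n", x$threshold))
  df <- x$results[, c("rank", "class", "formula", "name", "n_matched",
                      "p_matched", "d_kl", "d_b", "d_h", "d_c", "d_meta")]
  print(format(df, digits = 4), row.names = FALSE)
  cat("NOTE:", x$note, "\n")
  invisible(x)
}

#' Serialize an identification report to JSON
#'
#' The JSON layout follows the schema shipped at
#' `system.file("extdata", "report-schema.json", package = "specmatch")`.
#'
#' @param report An `identification_report`.
#' @param path Optional output path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "identification_report"))
  obj <- list(query = report$query,
              n_entries = report$n_entries,
              threshold = if (is.na(report$threshold)) NULL else report$threshold,
              parameters = unclass(report$config),
              note = report$note,
              results = report$results)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
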