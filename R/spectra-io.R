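#' Construct a peak list
#'
#' A peak list is a discrete mass spectrum: ordered (m/z, intensity) pairs.
#' Reference spectra in a library and centroided query spectra are both peak
#' lists. m/z values must be strictly increasing and intensities strictly
#' positive; use [as_peak_list()] to coerce unsorted or duplicated raw pairs.
#'
#' @param mz Numeric vector of m/z positions, strictly increasing.
#' @param intensity Numeric vector of intensities, same length, all > 0.
#'   Intensities are in arbitrary units (ion counts); see
#'   [normalize_intensities()] for the percent normalization used in matching.
#' @param label Free-text label for the spectrum.
#' @return An object of class `peak_list` with fields `mz`, `intensity`,
#'   `label`.
#' @seealso [read_peak_list()], [normalize_intensities()]
#' @export
peak_list <- function(mz, intensity, label = "") {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have the same length")
  if (length(mz) < 1L) stop("a peak list needs at least one peak")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("peak list values must be finite")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("m/z values must be strictly increasing")
  if (any(intensity <= 0)) stop("intensities must be strictly positive")
  structure(list(mz = mz, intensity = intensity,
                 label = as.character(label)[1L]),
            class = "peak_list")
}

#' Coerce raw (m/z, intensity) pairs to a peak list
#'
#' Sorts by m/z, merges duplicate m/z rows by summing their intensities
#' (intensity is an ion count, so co-located signal adds), and drops rows with
#' non-positive intensity (with a warning).
#'
#' @param mz,intensity Numeric vectors of equal length (unsorted allowed).
#' @param label Free-text label.
#' @return A `peak_list`.
#' @export
as_peak_list <- function(mz, intensity, label = "") {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have the same length")
  bad <- !is.finite(mz) | !is.finite(intensity)
  if (any(bad)) stop("peak list values must be finite")
  drop <- intensity <= 0
  if (any(drop)) {
    warning(sprintf("dropped %d peak(s) with non-positive intensity",
                    sum(drop)))
    mz <- mz[!drop]
    intensity <- intensity[!drop]
  }
  if (!length(mz)) stop("no peaks with positive intensity remain")
  o <- order(mz, method = "radix")
  mz <- mz[o]
  intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    f <- factor(mz, levels = unique(mz))
    intensity <- as.vector(rowsum(intensity, f))
    mz <- unique(mz)
  }
  peak_list(mz, intensity, label)
}

# Parse a two-column numeric text file. Lines starting with '#' or ';' and
# blank lines are comments; columns may be separated by whitespace or commas.
parse_xy <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  data_idx <- which(!grepl("^\\s*($|[#;])", lines))
  if (!length(data_idx))
    stop(sprintf("'%s' contains no data lines", path))
  toks <- strsplit(trimws(lines[data_idx]), "[,[:space:]]+")
  n_tok <- lengths(toks)
  if (any(n_tok != 2L)) {
    bad <- data_idx[which(n_tok != 2L)[1L]]
    stop(sprintf("'%s' line %d: expected two numeric columns", path, bad))
  }
  x <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 2L)))
  nonnum <- is.na(x) | is.na(y)
  if (any(nonnum)) {
    bad <- data_idx[which(nonnum)[1L]]
    stop(sprintf("'%s' line %d: non-numeric value", path, bad))
  }
  list(x = x, y = y)
}

#' Read a discrete spectrum (peak list) from a two-column text file
#'
#' The file holds one (m/z, intensity) pair per line (`.xy` / `ref.ms`
#' convention). `#`- or `;`-prefixed lines and blank lines are skipped;
#' whitespace or comma delimiters are accepted. Pairs are sorted by m/z,
#' duplicate m/z rows are merged by summing intensities, and rows with
#' intensity <= 0 are dropped with a warning. Intensities are returned as
#' read (not normalized).
#'
#' @param path Path to the text file.
#' @param label Label for the spectrum; defaults to the file name.
#' @return A `peak_list`.
#' @export
read_peak_list <- function(path, label = basename(path)) {
  xy <- parse_xy(path)
  as_peak_list(xy$x, xy$y, label = label)
}

#' Write a peak list to a two-column text file
#'
#' @param pl A `peak_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  writeLines(sprintf("%.12g %.12g", pl$mz, pl$intensity), path)
  invisible(path)
}

#' Normalize peak intensities to percent
#'
#' Rescales intensities so they sum to 100 (percent of total ion signal),
#' the normalization under which all library comparisons are made.
#'
#' @param pl A `peak_list` with at least one positive intensity.
#' @return The `peak_list` with intensities summing to 100.
#' @export
normalize_intensities <- function(pl) {
  stopifnot(inherits(pl, "peak_list"))
  s <- sum(pl$intensity)
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize: total intensity is not positive")
  pl$intensity <- pl$intensity * (100 / s)
  pl
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Peak list '%s': %d peaks, m/z %.4g-%.4g, total intensity %.6g\n",
              x$label, length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Construct a grid (profile) spectrum
#'
#' A grid spectrum is a continuous mass spectrum sampled at M uniformly
#' spaced m/z points between `mz_start` and `mz_end`.
#'
#' @param mz_start,mz_end m/z bounds, `mz_end > mz_start`.
#' @param intensities Numeric vector of M >= 2 finite, non-negative
#'   intensities.
#' @param label Free-text label.
#' @return An object of class `grid_spectrum`.
#' @export
grid_spectrum <- function(mz_start, mz_end, intensities, label = "") {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 2L) stop("a grid spectrum needs at least 2 points")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  mz_start <- as.numeric(mz_start)[1L]
  mz_end <- as.numeric(mz_end)[1L]
  if (!is.finite(mz_start) || !is.finite(mz_end) || mz_end <= mz_start)
    stop("need finite m/z bounds with mz_end > mz_start")
  structure(list(mz_start = mz_start, mz_end = mz_end,
                 intensities = intensities, label = as.character(label)[1L]),
            class = "grid_spectrum")
}

#' m/z axis of a grid spectrum
#'
#' @param g A `grid_spectrum`.
#' @return Numeric vector of the M uniformly spaced m/z grid points.
#' @export
grid_mz <- function(g) {
  stopifnot(inherits(g, "grid_spectrum"))
  seq(g$mz_start, g$mz_end, length.out = length(g$intensities))
}

# grid spacing Delta x
grid_dx <- function(g) {
  (g$mz_end - g$mz_start) / (length(g$intensities) - 1L)
}

#' Read a grid (profile) spectrum from a two-column text file
#'
#' The m/z column must be strictly increasing and uniformly spaced (within a
#' relative spacing tolerance of 1e-6). Negative intensities, which can arise
#' from upstream baseline subtraction, are clipped to 0 with a warning so
#' that the downstream distance metrics stay well-defined.
#'
#' @param path Path to the text file.
#' @param label Label for the spectrum; defaults to the file name.
#' @return A `grid_spectrum`.
#' @export
read_grid_spectrum <- function(path, label = basename(path)) {
  xy <- parse_xy(path)
  if (length(xy$x) < 2L)
    stop(sprintf("'%s': a grid spectrum needs at least 2 points", path))
  dx <- diff(xy$x)
  if (any(dx <= 0))
    stop(sprintf("'%s': m/z values must be strictly increasing", path))
  mdx <- mean(dx)
  if (max(abs(dx - mdx)) > 1e-6 * mdx)
    stop(sprintf(
      "'%s': m/z grid is not uniform; read it as a peak list instead", path))
  y <- xy$y
  if (any(y < 0)) {
    warning(sprintf("clipped %d negative intensity value(s) to 0",
                    sum(y < 0)))
    y <- pmax(y, 0)
  }
  grid_spectrum(xy$x[1L], xy$x[length(xy$x)], y, label = label)
}

#' Write a grid spectrum to a two-column text file
#'
#' @param g A `grid_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_spectrum <- function(g, path) {
  stopifnot(inherits(g, "grid_spectrum"))
  writeLines(sprintf("%.12g %.12g", grid_mz(g), g$intensities), path)
  invisible(path)
}

#' @export
print.grid_spectrum <- function(x, ...) {
  cat(sprintf("Grid spectrum '%s': %d points, m/z %.4g-%.4g (dx = %.4g)\n",
              x$label, length(x$intensities), x$mz_start, x$mz_end,
              grid_dx(x)))
  invisible(x)
}

#' Construct a library entry
#'
#' @param class_label Substance class (parent directory name in the on-disk
#'   layout).
#' @param formula Chemical formula in Hill notation (may be `""`).
#' @param name Common substance name.
#' @param peaks A `peak_list`; normalized to 100 percent on construction.
#' @param info Optional free-text annotation (contents of `INFO.txt`).
#' @return An object of class `database_entry` with a unique `id` of the form
#'   `class/formula_name`.
#' @export
database_entry <- function(class_label, formula, name, peaks, info = NULL) {
  stopifnot(inherits(peaks, "peak_list"))
  folder <- if (nzchar(formula)) paste(formula, name, sep = "_") else name
  structure(list(id = paste(class_label, folder, sep = "/"),
                 class_label = as.character(class_label)[1L],
                 formula = as.character(formula)[1L],
                 name = as.character(name)[1L],
                 peaks = normalize_intensities(peaks),
                 info = info),
            class = "database_entry")
}

#' Construct an in-memory spectral library
#'
#' Entries are stored in a deterministic order (lexicographic by entry id,
#' byte-wise) so that rankings and tie-breaks are reproducible across
#' platforms.
#'
#' @param entries List of `database_entry` objects with unique ids.
#' @return An object of class `ms_database`.
#' @export
ms_database <- function(entries) {
  if (!length(entries)) stop("a database needs at least one entry")
  ok <- vapply(entries, inherits, TRUE, "database_entry")
  if (!all(ok)) stop("all entries must be 'database_entry' objects")
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entry id: '%s'", ids[duplicated(ids)][1L]))
  entries <- entries[order(ids, method = "radix")]
  structure(list(entries = entries), class = "ms_database")
}

#' @export
print.ms_database <- function(x, ...) {
  cat(sprintf("Spectral library: %d entries, %d classes\n",
              length(x$entries),
              length(unique(vapply(x$entries, `[[`, "", "class_label")))))
  invisible(x)
}

#' @export
length.ms_database <- function(x) length(x$entries)

#' Entry ids of a library
#'
#' @param db An `ms_database`.
#' @return Character vector of entry ids, in library order.
#' @export
db_ids <- function(db) {
  stopifnot(inherits(db, "ms_database"))
  vapply(db$entries, `[[`, "", "id")
}

#' Per-class entry counts of a library
#'
#' @param db An `ms_database`.
#' @return A data frame with columns `class` and `n`, sorted by class.
#' @export
db_class_counts <- function(db) {
  stopifnot(inherits(db, "ms_database"))
  cls <- vapply(db$entries, `[[`, "", "class_label")
  tab <- table(cls)
  data.frame(class = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Load a spectral library from its directory layout
#'
#' The library lives in a two-level directory tree:
#' `root/<class>/<Formula>_<Name>/ref.ms`, where `ref.ms` is a two-column
#' peak list (required) and `INFO.txt` is an optional free-text annotation.
#' The substance folder name is split at the first underscore into the Hill
#' formula and the common name; folders without an underscore load with an
#' empty formula. `ref.ms` intensities are treated as unnormalized and
#' normalized to 100 percent at load time. Substance folders without a
#' `ref.ms` are skipped with a warning.
#'
#' @param root Path to the library root directory.
#' @return An `ms_database`.
#' @export
load_database <- function(root) {
  if (!dir.exists(root)) stop(sprintf("database root '%s' not found", root))
  class_dirs <- list.dirs(root, recursive = FALSE)
  class_dirs <- class_dirs[order(basename(class_dirs), method = "radix")]
  entries <- list()
  for (cd in class_dirs) {
    sub_dirs <- list.dirs(cd, recursive = FALSE)
    sub_dirs <- sub_dirs[order(basename(sub_dirs), method = "radix")]
    for (sd in sub_dirs) {
      ref <- file.path(sd, "ref.ms")
      if (!file.exists(ref)) {
        warning(sprintf("skipping '%s': no ref.ms", sd))
        next
      }
      pl <- read_peak_list(ref, label = basename(sd))
      nm <- basename(sd)
      us <- regexpr("_", nm, fixed = TRUE)
      if (us > 0L) {
        formula <- substr(nm, 1L, us - 1L)
        name <- substr(nm, us + 1L, nchar(nm))
      } else {
        formula <- ""
        name <- nm
      }
      info_path <- file.path(sd, "INFO.txt")
      info <- if (file.exists(info_path)) {
        paste(readLines(info_path, warn = FALSE, encoding = "UTF-8"),
              collapse = "\n")
      }
      entries[[length(entries) + 1L]] <-
        database_entry(basename(cd), formula, name, pl, info)
    }
  }
  if (!length(entries))
    stop(sprintf("no loadable entries under '%s'", root))
  ms_database(entries)
}

#' Write a library to the on-disk directory layout
#'
#' Creates `dir/<class>/<Formula>_<Name>/ref.ms` (plus `INFO.txt` where an
#' entry carries an annotation). The written tree round-trips through
#' [load_database()].
#'
#' @param db An `ms_database`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "ms_database"))
  for (e in db$entries) {
    folder <- if (nzchar(e$formula)) paste(e$formula, e$name, sep = "_") else e$name
    d <- file.path(dir, e$class_label, folder)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_peak_list(e$peaks, file.path(d, "ref.ms"))
    if (!is.null(e$info)) writeLines(e$info, file.path(d, "INFO.txt"))
  }
  invisible(dir)
}
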