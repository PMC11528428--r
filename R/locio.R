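#' Read a localization table
#'
#' Reads single-molecule localizations into a tibble with the package's
#' canonical columns: `x`, `y` (nm), `frame` (0-based integer) and, when
#' present, `precision` (nm) and `species`.  Two dialects are supported: a
#' configurable CSV (any delimited text readable by [readr::read_delim()])
#' and Picasso-style HDF5 files carrying a `locs` compound dataset with
#' camera-pixel coordinates.
#'
#' All coordinates are normalized to nanometres on read; unit conversion
#' happens only at this boundary.  Row order is preserved.
#'
#' @param path Path to the localization file.
#' @param dialect `"csv"` or `"picasso_hdf5"`.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(x = "x [nm]", y = "y [nm]")`.  Unmapped
#'   canonical columns are looked up under their own names.
#' @param unit Unit of the coordinate columns in the file: `"nm"`, `"um"`
#'   or `"px"` (the latter requires `pixel_size_nm`).  HDF5 localizations
#'   are always pixel-valued.
#' @param pixel_size_nm Camera pixel size in nm, used when `unit = "px"`
#'   or for the HDF5 dialect.
#' @param frame_interval_s Frame interval in seconds, stored as table-level
#'   metadata (attribute `frame_interval_s`).
#' @param frame_count Total number of frames; defaults to `max(frame) + 1`.
#' @param delim Field delimiter for the CSV dialect.
#'
#' @return A tibble of localizations (class `smlmeq_locs`) with attributes
#'   `frame_interval_s` and `frame_count`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x_nm = c(0, 10), y_nm = c(0, 5), frame = 0:1), f,
#'           row.names = FALSE)
#' read_localizations(f, column_map = c(x = "x_nm", y = "y_nm"))
read_localizations <- function(path,
                               dialect = c("csv", "picasso_hdf5"),
                               column_map = NULL,
                               unit = c("nm", "um", "px"),
                               pixel_size_nm = NULL,
                               frame_interval_s = 0.1,
                               frame_count = NULL,
                               delim = ",") {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (!file.exists(path)) abort(sprintf("Localization file not found: %s", path))

  if (dialect == "picasso_hdf5") {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      abort("The 'rhdf5' package is required for the picasso_hdf5 dialect.")
    }
    if (is.null(pixel_size_nm)) {
      abort("`pixel_size_nm` is required for the picasso_hdf5 dialect (coordinates are camera pixels).")
    }
    raw <- as_tibble(as.data.frame(rhdf5::h5read(path, "locs")))
    unit <- "px"
  } else {
    raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  }

  resolve <- function(canonical, required) {
    file_col <- if (!is.null(column_map) && canonical %in% names(column_map)) {
      unname(column_map[[canonical]])
    } else {
      canonical
    }
    if (!file_col %in% names(raw)) {
      if (required) {
        abort(sprintf("Required column '%s' (for '%s') is missing from %s.",
                      file_col, canonical, path))
      }
      return(NULL)
    }
    v <- raw[[file_col]]
    if (!is.numeric(v) && canonical != "species") {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      abort(sprintf("Column '%s' is not numeric (first offending row: %d).",
                    file_col, if (is.na(bad)) 1L else bad))
    }
    v
  }

  scale <- switch(unit, nm = 1, um = 1000, px = pixel_size_nm)
  if (is.null(scale)) abort("`pixel_size_nm` must be supplied when unit = 'px'.")

  out <- tibble(
    x = as.numeric(resolve("x", TRUE)) * scale,
    y = as.numeric(resolve("y", TRUE)) * scale,
    frame = as.integer(resolve("frame", TRUE))
  )
  prec <- resolve("precision", FALSE)
  if (!is.null(prec)) out$precision <- as.numeric(prec) * scale
  sp <- resolve("species", FALSE)
  if (!is.null(sp)) out$species <- as.character(sp)

  validate_localizations(out, frame_count = frame_count)
  frame_count <- frame_count %||% (max(out$frame) + 1L)
  structure(out,
            frame_interval_s = frame_interval_s,
            frame_count = as.integer(frame_count),
            class = c("smlmeq_locs", class(out)))
}

validate_localizations <- function(tbl, frame_count = NULL) {
  if (!all(is.finite(tbl$x)) || !all(is.finite(tbl$y))) {
    abort("Localization coordinates must be finite.")
  }
  if (any(tbl$frame < 0L)) abort("Frame indices must be >= 0.")
  if (!is.null(frame_count) && any(tbl$frame >= frame_count)) {
    abort("Frame indices must be < frame_count.")
  }
  if ("precision" %in% names(tbl) && any(tbl$precision <= 0, na.rm = TRUE)) {
    abort("Localization precision must be positive.")
  }
  if ("species" %in% names(tbl)) check_species(tbl$species)
  invisible(tbl)
}

check_species <- function(species) {
  n <- length(unique(species[!is.na(species)]))
  if (n > 2L) {
    abort(sprintf(
      "At most 2 species are supported per analysis; found %d labels.", n))
  }
  invisible(species)
}

#' Write and read molecule maps
#'
#' A molecule map holds the positions of counted protein molecules (one row
#' per molecule, after qPAINT counting or from simulation ground truth) with
#' a species label and a positive integer `count_weight`.  The on-disk format
#' is CSV with columns `x_nm`, `y_nm`, `species`, `count_weight`; a write
#' followed by a read is the identity.
#'
#' @param map Tibble with columns `x`, `y` (nm) and optionally `species`
#'   (default `"A"`) and `count_weight` (default 1).
#' @param path Output (or input) CSV path.
#' @return `write_molecule_map()` returns `path` invisibly;
#'   `read_molecule_map()` returns the molecule-map tibble.
#' @export
write_molecule_map <- function(map, path) {
  if (!is.data.frame(map) || nrow(map) == 0L) {
    abort("Cannot write an empty molecule map.")
  }
  map <- as_molecule_map(map)
  out <- tibble(x_nm = map$x, y_nm = map$y,
                species = map$species, count_weight = map$count_weight)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_molecule_map
#' @export
read_molecule_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("Molecule map not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("x_nm", "y_nm", "species", "count_weight")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("Molecule map is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  as_molecule_map(tibble(x = raw$x_nm, y = raw$y_nm, species = raw$species,
                         count_weight = raw$count_weight))
}

#' Coerce to a molecule map
#'
#' @param points Data frame with at least `x` and `y` columns (nm).
#' @return Tibble with columns `x`, `y`, `species`, `count_weight`.
#' @export
as_molecule_map <- function(points) {
  xy <- as_xy(points)
  out <- tibble(x = xy[, 1L], y = xy[, 2L])
  out$species <- if ("species" %in% names(points)) as.character(points$species) else "A"
  out$count_weight <- if ("count_weight" %in% names(points)) {
    as.integer(points$count_weight)
  } else {
    1L
  }
  if (any(out$count_weight < 1L)) abort("count_weight must be >= 1.")
  check_species(out$species)
  out
}
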