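#' Column dialect for delimited localization tables
#'
#' A dialect maps the columns of an exported localization table onto the
#' fields used throughout the package (`frame`, `x`, `y`, `photons`) and
#' declares the coordinate unit. The default matches a minimal
#' `frame,x_nm,y_nm,photons` header in nanometres.
#'
#' @param frame_col,x_col,y_col,photons_col Column names in the file.
#' @param unit Coordinate unit in the file: `"nm"` or `"px"` (camera pixels;
#'   converted with the table's camera pixel size, default 100 nm/px).
#' @param delimiter Field delimiter.
#' @return A list of class `loc_dialect`.
#' @export
loc_dialect <- function(frame_col = "frame", x_col = "x_nm", y_col = "y_nm",
                        photons_col = "photons", unit = c("nm", "px"),
                        delimiter = ",") {
  unit <- arg_match(unit)
  structure(
    list(frame_col = frame_col, x_col = x_col, y_col = y_col,
         photons_col = photons_col, unit = unit, delimiter = delimiter),
    class = "loc_dialect"
  )
}

#' Read or write a dialect specification as YAML
#'
#' @param path YAML file with fields `frame_col`, `x_col`, `y_col`,
#'   `photons_col`, `unit`, `delimiter`.
#' @return `read_dialect()` returns a `loc_dialect`; `write_dialect()` is
#'   called for its side effect.
#' @export
read_dialect <- function(path) {
  d <- yaml::read_yaml(path)
  loc_dialect(frame_col = d$frame_col %||% "frame",
              x_col = d$x_col %||% "x_nm",
              y_col = d$y_col %||% "y_nm",
              photons_col = d$photons_col %||% "photons",
              unit = d$unit %||% "nm",
              delimiter = d$delimiter %||% ",")
}

#' @rdname read_dialect
#' @param dialect A [loc_dialect()].
#' @export
write_dialect <- function(dialect, path) {
  yaml::write_yaml(unclass(dialect), path)
  invisible(path)
}

#' Construct a localization table
#'
#' Localization tables are tibbles with at least the columns `frame`
#' (1-based acquisition frame), `x`, `y` (nm) and `photons` (> 0). Rows are
#' kept in frame order (stable within a frame). Field-of-view bounds, the
#' source channel tag and the camera pixel size are carried as attributes.
#'
#' @param records Data frame with columns `frame`, `x`, `y`, `photons`
#'   (extra columns are preserved).
#' @param bounds Field-of-view rectangle `c(xmin, xmax, ymin, ymax)` in nm;
#'   defaults to the coordinate range of the data.
#' @param source_channel Channel tag, e.g. `"S"`, `"L"`, `"demixed:red"`.
#' @param pixel_size_camera Camera pixel size in nm (used for px dialects).
#' @return A tibble of class `loc_table`.
#' @export
loc_table <- function(records, bounds = NULL, source_channel = "none",
                      pixel_size_camera = 100) {
  records <- as_tibble(records)
  need <- c("frame", "x", "y", "photons")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort_format(paste0("localization table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records)) {
    bad <- which(!is.finite(records$photons) | records$photons <= 0)
    if (length(bad)) {
      abort_format(paste0("non-positive or non-numeric photon count in row(s): ",
                          paste(head(bad, 5L), collapse = ", ")))
    }
    bad <- which(!is.finite(records$x) | !is.finite(records$y))
    if (length(bad)) {
      abort_format(paste0("non-finite coordinates in row(s): ",
                          paste(head(bad, 5L), collapse = ", ")))
    }
    bad <- which(!is.finite(records$frame) | records$frame < 1)
    if (length(bad)) {
      abort_format(paste0("frame index < 1 in row(s): ",
                          paste(head(bad, 5L), collapse = ", ")))
    }
    records <- records[order(records$frame), , drop = FALSE]
  }
  if (is.null(bounds)) {
    bounds <- if (nrow(records)) {
      c(min(records$x), max(records$x), min(records$y), max(records$y))
    } else {
      c(0, 0, 0, 0)
    }
  }
  structure(records,
            class = c("loc_table", class(records)),
            bounds = as.numeric(bounds),
            source_channel = source_channel,
            pixel_size_camera = pixel_size_camera)
}

#' @rdname loc_table
#' @param table A localization table.
#' @export
loc_bounds <- function(table) {
  attr(table, "bounds") %||%
    c(min(table$x), max(table$x), min(table$y), max(table$y))
}

#' Read a delimited localization table
#'
#' Reads an exported single-molecule localization table, maps columns
#' through a dialect, converts coordinates to nm and returns rows in frame
#' order.
#'
#' @param path File path.
#' @param dialect A [loc_dialect()] (or path semantics via
#'   [read_dialect()]).
#' @param pixel_size_camera nm per camera pixel, used when
#'   `dialect$unit == "px"`.
#' @param source_channel Channel tag attached to the result.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               pixel_size_camera = 100,
                               source_channel = "none") {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  df <- tryCatch(
    readr::read_delim(path, delim = dialect$delimiter, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) abort_format(paste0("cannot parse '", path, "': ",
                                            conditionMessage(e)))
  )
  if (ncol(df) == 0) abort_format(paste0("empty input file: ", path))
  cols <- c(frame = dialect$frame_col, x = dialect$x_col,
            y = dialect$y_col, photons = dialect$photons_col)
  missing_cols <- setdiff(unname(cols), names(df))
  if (length(missing_cols)) {
    abort_format(paste0("missing column(s) in '", path, "': ",
                        paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    frame = suppressWarnings(as.numeric(df[[cols["frame"]]])),
    x = suppressWarnings(as.numeric(df[[cols["x"]]])),
    y = suppressWarnings(as.numeric(df[[cols["y"]]])),
    photons = suppressWarnings(as.numeric(df[[cols["photons"]]]))
  )
  extra <- setdiff(names(df), unname(cols))
  for (nm in extra) out[[nm]] <- df[[nm]]
  if (dialect$unit == "px") {
    out$x <- out$x * pixel_size_camera
    out$y <- out$y * pixel_size_camera
  }
  loc_table(out, source_channel = source_channel,
            pixel_size_camera = pixel_size_camera)
}

#' Write a localization table as delimited text
#'
#' Inverse of [read_localizations()]: coordinates are converted from nm to
#' the dialect's unit and columns renamed to the dialect's names, so a
#' read/write round trip reproduces the table.
#'
#' @inheritParams read_localizations
#' @param table A localization table.
#' @export
write_localizations <- function(table, path, dialect = loc_dialect()) {
  px <- attr(table, "pixel_size_camera") %||% 100
  out <- as_tibble(table)
  if (!is.null(dialect$unit) && dialect$unit == "px") {
    out$x <- out$x / px
    out$y <- out$y / px
  }
  names(out)[match(c("frame", "x", "y", "photons"), names(out))] <-
    c(dialect$frame_col, dialect$x_col, dialect$y_col, dialect$photons_col)
  readr::write_delim(out, path, delim = dialect$delimiter, progress = FALSE)
  invisible(path)
}

#' Crop a localization table to a rectangle
#'
#' Keeps records with `xmin <= x < xmax` and `ymin <= y < ymax` (half-open,
#' so adjacent crops partition the plane) and sets the table bounds to the
#' rectangle. An empty intersection yields an empty table, not an error.
#'
#' @param table A localization table.
#' @param rect `c(xmin, xmax, ymin, ymax)` in nm.
#' @return A [loc_table()] bounded by `rect`.
#' @export
crop_region <- function(table, rect) {
  stopifnot(length(rect) == 4, rect[1] < rect[2], rect[3] < rect[4])
  keep <- table$x >= rect[1] & table$x < rect[2] &
    table$y >= rect[3] & table$y < rect[4]
  loc_table(as_tibble(table)[keep, , drop = FALSE],
            bounds = rect,
            source_channel = attr(table, "source_channel") %||% "none",
            pixel_size_camera = attr(table, "pixel_size_camera") %||% 100)
}
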