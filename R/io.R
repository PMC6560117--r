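#' Tabular and raster I/O
#'
#' CSV readers validate their schema and fail listing the offending columns;
#' timestamps are parsed timezone-aware (UTC). Rasters use the plain-text
#' ASCII grid dialect of [write_grid_ascii()].
#'
#' @name interface_io
NULL

track_columns <- c("individual_id", "species", "colony_id", "timestamp",
                   "x_km", "y_km", "source")
colony_columns <- c("id", "species", "x", "y", "population_size")

#' Write / read tracks as CSV
#'
#' Columns: `individual_id`, `species`, `colony_id`, `timestamp` (ISO-8601
#' UTC), `x_km`, `y_km`, `source` (argos/gps/fastloc), `quality_class`,
#' `n_satellites`.
#'
#' @param tracks List of track data.frames (or one bound data.frame).
#' @param path CSV path.
#' @return `read_tracks` returns a list of track data.frames split by
#'   individual.
#' @export
write_tracks <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) as.data.frame(tracks) else bind_tracks(tracks)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$date <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(track_columns, names(df))
  if (length(missing)) {
    stop("track CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(df$timestamp)) stop("unparseable ISO-8601 timestamps in track CSV")
  if (!"quality_class" %in% names(df)) df$quality_class <- NA_character_
  if (!"n_satellites" %in% names(df)) df$n_satellites <- NA_integer_
  df$quality_class <- as.character(df$quality_class)
  df$date <- as.Date(df$timestamp, tz = "UTC")
  bad_src <- setdiff(unique(df$source), c("argos", "gps", "fastloc"))
  if (length(bad_src)) stop("unknown source value(s): ", paste(bad_src, collapse = ", "))
  split_df <- split(df, df$individual_id)
  lapply(split_df, function(t) {
    t <- t[order(t$timestamp), , drop = FALSE]
    rownames(t) <- NULL
    class(t) <- c("cpf_track", "data.frame")
    t
  })
}

#' Write / read the colony registry as CSV
#'
#' Columns: `id`, `species`, `x`, `y`, `population_size` (needed by the null
#' density covariate), and optionally `row`, `col`.
#'
#' @param colonies Colony data.frame.
#' @param path CSV path.
#' @return `read_colonies` returns the colony data.frame.
#' @export
write_colonies <- function(colonies, path) {
  utils::write.csv(colonies, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_colonies
#' @export
read_colonies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(colony_columns, names(df))
  if (length(missing)) {
    stop("colony CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$population_size <= 0)) stop("population_size must be positive")
  df
}

#' Read a stack of ASCII-grid rasters sharing one grid
#'
#' @param paths Named character vector of file paths.
#' @return Named list of [grid_raster()]s; fails naming the first layer whose
#'   grid differs from the others.
#' @export
read_raster_stack <- function(paths) {
  out <- lapply(paths, read_grid_ascii)
  g <- out[[1]]$grid
  for (i in seq_along(out)[-1]) {
    if (!same_grid(g, out[[i]]$grid)) {
      stop("raster '", names(paths)[i] %||% paths[i],
           "' does not share the stack's grid")
    }
  }
  out
}

#' Write an isopleth cell set as CSV
#'
#' @param iso An `isopleth_set`.
#' @param path CSV path (columns `row`, `col`, `x`, `y`).
#' @export
write_isopleth_csv <- function(iso, path) {
  xy <- rc_to_xy(iso$grid, iso$cells[, 1], iso$cells[, 2])
  utils::write.csv(
    data.frame(row = iso$cells[, 1], col = iso$cells[, 2],
               x = xy[, "x"], y = xy[, "y"]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a raster to PNG
#'
#' Quick-look rendering: values are scaled to [0, 1] over the finite range
#' and written as a grayscale PNG (north up); NA cells are transparent.
#'
#' @param raster A [grid_raster()].
#' @param path PNG path.
#' @export
write_raster_png <- function(raster, path) {
  v <- raster$values
  rng <- range(v, finite = TRUE)
  scaled <- (v - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  scaled[!is.finite(scaled)] <- 0
  alpha <- ifelse(is.na(v), 0, 1)
  img <- array(0, c(nrow(v), ncol(v), 4))
  img[, , 1] <- img[, , 2] <- img[, , 3] <- scaled
  img[, , 4] <- alpha
  png::writePNG(img[rev(seq_len(nrow(v))), , , drop = FALSE], path)
  invisible(path)
}

#' Write an isopleth cell set as GeoJSON polygons
#'
#' Each member cell becomes one square polygon feature in planar km
#' coordinates, with the isopleth level as a property.
#'
#' @param iso An `isopleth_set`.
#' @param path GeoJSON path.
#' @export
write_isopleth_geojson <- function(iso, path) {
  g <- iso$grid
  half <- g$cell_size / 2
  xy <- rc_to_xy(g, iso$cells[, 1], iso$cells[, 2])
  features <- lapply(seq_len(nrow(xy)), function(i) {
    x <- xy[i, "x"]; y <- xy[i, "y"]
    ring <- list(c(x - half, y - half), c(x + half, y - half),
                 c(x + half, y + half), c(x - half, y + half),
                 c(x - half, y - half))
    list(type = "Feature",
         properties = list(level = iso$level,
                           row = unname(iso$cells[i, 1]),
                           col = unname(iso$cells[i, 2])),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
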