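#' Track cleaning and trip delineation
#'
#' Raw fixes pass through a satellite-count filter (Fastloc GPS), an iterative
#' speed filter, trip delineation by distance to the colony/land, an optional
#' gap-splitting rule for gap-prone taxa, and regularization to a fixed
#' (default hourly) interval by linear interpolation or a continuous-time
#' correlated random walk smoother.
#'
#' @name track_processing
NULL

#' Remove Fastloc GPS fixes with too few satellites
#'
#' Fastloc fixes with fewer than `min_satellites` (default 4) are removed;
#' fixes from other sources pass through untouched. A Fastloc fix with a
#' missing satellite count is an error, never silently kept.
#'
#' @param fixes data.frame with `source` and `n_satellites` columns.
#' @param min_satellites Minimum satellite count to retain (default 4).
#' @return The filtered data.frame.
#' @export
filter_fastloc <- function(fixes, min_satellites = 4L) {
  is_fl <- fixes$source == "fastloc"
  if (any(is_fl & is.na(fixes$n_satellites))) {
    stop("fastloc fix(es) missing n_satellites; cannot apply the satellite filter")
  }
  keep <- !is_fl | fixes$n_satellites >= min_satellites
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  keep_attrs(out, fixes)
}

implied_speeds_kmh <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2) return(numeric(0))
  dt_h <- as.numeric(difftime(fixes$timestamp[-1], fixes$timestamp[-n], units = "hours"))
  dd <- sqrt(diff(fixes$x_km)^2 + diff(fixes$y_km)^2)
  dd / dt_h
}

#' Iterative speed filter
#'
#' Removes location outliers implying impossible travel speeds: while any
#' consecutive pair implies a speed above `vmax`, the later fix of the
#' worst-violating pair is removed (keeping the earlier fix) and speeds are
#' recomputed. Deterministic and idempotent.
#'
#' @param fixes data.frame with `timestamp` (POSIXct), `x_km`, `y_km`;
#'   at least 2 rows.
#' @param vmax Maximum plausible speed in m/s (3 for swimmers, 20 for flying
#'   seabirds).
#' @return The filtered data.frame in original order.
#' @export
speed_filter <- function(fixes, vmax) {
  stopifnot(vmax > 0)
  if (nrow(fixes) < 2) stop("speed_filter needs at least 2 fixes")
  vmax_kmh <- vmax * 3.6
  out <- fixes
  repeat {
    sp <- implied_speeds_kmh(out)
    bad <- which(sp > vmax_kmh)
    if (length(bad) == 0) break
    worst <- bad[which.max(sp[bad])]
    out <- out[-(worst + 1L), , drop = FALSE]
    if (nrow(out) == 0) stop("speed filter removed all fixes; track unusable")
  }
  rownames(out) <- NULL
  keep_attrs(out, fixes)
}

keep_attrs <- function(new, old) {
  for (a in c("true_positions", "colony", "individual_id", "colony_id")) {
    if (!is.null(attr(old, a))) attr(new, a) <- attr(old, a)
  }
  if (inherits(old, "cpf_track")) class(new) <- class(old)
  new
}

#' Split a track into foraging trips
#'
#' A fix is "home" when it lies within `return_radius` km of the colony or on
#' a land cell. Each maximal run of at-sea (non-home) fixes with at least
#' `min_trip_fixes` members, bounded on both sides by home fixes, becomes one
#' trip; the bounding home fixes are included so trips start and end at the
#' colony. Runs truncated by the start or end of the track are discarded as
#' incomplete. A track that never leaves `return_radius` yields zero trips.
#'
#' @param track data.frame of cleaned fixes (`timestamp`, `x_km`, `y_km`).
#' @param mask Land mask [grid_raster()].
#' @param colony One-row colony data.frame (`x`, `y`).
#' @param return_radius Colony-return threshold in km (default 2).
#' @param min_trip_fixes Minimum at-sea fixes per trip (default 3).
#' @return List of trip data.frames, each with attributes `colony`,
#'   `individual_id`, `departure`, `return`.
#' @export
delineate_trips <- function(track, mask, colony, return_radius = 2, min_trip_fixes = 3) {
  stopifnot(return_radius > 0, min_trip_fixes >= 1)
  d_col <- sqrt((track$x_km - colony$x[1])^2 + (track$y_km - colony$y[1])^2)
  rc <- xy_to_rc(mask$grid, track$x_km, track$y_km)
  on_land <- rep(FALSE, nrow(track))
  ok <- !is.na(rc[, "row"])
  on_land[ok] <- mask$values[rc[ok, , drop = FALSE]]
  home <- d_col <= return_radius | on_land
  r <- rle(home)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  trips <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k]) next                       # a home run, not a trip
    if (r$lengths[k] < min_trip_fixes) next     # excursion too short
    if (starts[k] == 1L || ends[k] == nrow(track)) next  # truncated trip
    idx <- (starts[k] - 1L):(ends[k] + 1L)      # include bounding home fixes
    tr <- track[idx, , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "colony") <- colony
    attr(tr, "individual_id") <- if ("individual_id" %in% names(tr)) tr$individual_id[1] else NA
    attr(tr, "departure") <- tr$timestamp[1]
    attr(tr, "return") <- tr$timestamp[nrow(tr)]
    class(tr) <- c("cpf_trip", "data.frame")
    trips[[length(trips) + 1]] <- tr
  }
  trips
}

#' Distance to the nearest coast
#'
#' Chamfer distance (km) from each point's cell to the nearest land cell.
#'
#' @param mask Land mask [grid_raster()].
#' @param x,y Point coordinates (km).
#' @return Numeric vector of distances.
#' @export
nearest_coast_distance <- function(mask, x, y) {
  d <- chamfer_distance(mask$values, mask$grid$cell_size)
  rc <- xy_to_rc(mask$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, "row"])
  out[ok] <- d[rc[ok, , drop = FALSE]]
  out
}

#' Split trips at gaps long enough for an unobserved return to land
#'
#' For gap-prone taxa, a long gap between consecutive fixes may hide a return
#' to the colony, merging what were really separate trips. A trip is split at
#' a gap when the gap duration exceeds the time to swim to the nearest coast
#' from the fix before the gap and back out to the fix after it at
#' `mean_speed`: `(d_coast(before) + d_coast(after)) / mean_speed` hours
#' (equal to `2 d / mean_speed` when the two coast distances agree). Split
#' pieces with fewer than `min_trip_fixes` at-sea fixes are dropped.
#'
#' @param trips List of trip data.frames from [delineate_trips()].
#' @param mask Land mask [grid_raster()].
#' @param mean_speed Sustained swim speed in km/h (default 6).
#' @param min_trip_fixes Minimum at-sea fixes per retained piece (default 3).
#' @return List of trip data.frames.
#' @export
split_gappy_trips <- function(trips, mask, mean_speed = 6, min_trip_fixes = 3) {
  stopifnot(mean_speed > 0)
  coast <- chamfer_distance(mask$values, mask$grid$cell_size)
  out <- list()
  for (tr in trips) {
    n <- nrow(tr)
    if (n < 2) { out[[length(out) + 1]] <- tr; next }
    rc <- xy_to_rc(mask$grid, tr$x_km, tr$y_km)
    dc <- coast[rc]
    dt_h <- as.numeric(difftime(tr$timestamp[-1], tr$timestamp[-n], units = "hours"))
    feasible_h <- (dc[-n] + dc[-1]) / mean_speed
    cut_after <- which(dt_h > feasible_h)
    bounds <- c(0L, cut_after, n)
    for (b in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[b] + 1L):bounds[b + 1L]
      if (length(idx) < min_trip_fixes) next
      piece <- tr[idx, , drop = FALSE]
      rownames(piece) <- NULL
      for (a in c("colony", "individual_id")) attr(piece, a) <- attr(tr, a)
      attr(piece, "departure") <- piece$timestamp[1]
      attr(piece, "return") <- piece$timestamp[nrow(piece)]
      class(piece) <- class(tr)
      out[[length(out) + 1]] <- piece
    }
  }
  out
}

#' Regularize a trip to a fixed time interval
#'
#' `linear` interpolates x and y piecewise-linearly in time (the conventional
#' treatment for low-error GPS fixes); `ctcrw` fits a continuous-time
#' correlated random walk (integrated Ornstein-Uhlenbeck velocity) by maximum
#' likelihood with isotropic, source-dependent observation noise and returns
#' the smoothed mean positions (see [ctcrw_smooth()]). Output positions sit on
#' the exact interval grid from the first fix to the last.
#'
#' @param trip Trip data.frame (`timestamp`, `x_km`, `y_km`, optionally
#'   `source`).
#' @param interval Output interval in hours (default 1).
#' @param method `"linear"` or `"ctcrw"`.
#' @param obs_sd Named per-source observation SD in km for the ctcrw method.
#' @return A regularized trip data.frame (`timestamp`, `x_km`, `y_km`) with
#'   the parent trip's attributes and `h_interval` set.
#' @export
regularize <- function(trip, interval = 1, method = c("linear", "ctcrw"),
                       obs_sd = c(gps = 0, argos = 0.5, fastloc = 0.1)) {
  method <- match.arg(method)
  n <- nrow(trip)
  if (n < 2) stop("regularize needs at least 2 fixes")
  t_h <- as.numeric(difftime(trip$timestamp, trip$timestamp[1], units = "hours"))
  if (max(t_h) < interval) stop("trip span (", max(t_h), " h) shorter than the interval")
  grid_t <- seq(0, max(t_h), by = interval)
  if (method == "linear") {
    x <- stats::approx(t_h, trip$x_km, xout = grid_t)$y
    y <- stats::approx(t_h, trip$y_km, xout = grid_t)$y
  } else {
    src <- if ("source" %in% names(trip)) trip$source else rep("gps", n)
    sd_obs <- unname(obs_sd[src])
    sd_obs[is.na(sd_obs)] <- max(obs_sd)
    fit <- ctcrw_fit(t_h, trip$x_km, trip$y_km, sd_obs^2)
    x <- ctcrw_smooth(t_h, trip$x_km, sd_obs^2, grid_t, fit$beta, fit$sigma)
    y <- ctcrw_smooth(t_h, trip$y_km, sd_obs^2, grid_t, fit$beta, fit$sigma)
  }
  out <- data.frame(timestamp = trip$timestamp[1] + grid_t * 3600, x_km = x, y_km = y)
  for (a in c("colony", "individual_id", "departure", "return")) {
    attr(out, a) <- attr(trip, a)
  }
  attr(out, "h_interval") <- interval
  class(out) <- c("cpf_trip", "data.frame")
  out
}

#' Maximum displacement of a trip from its colony
#'
#' Straight-line planar distance (km) from the colony, maximized over all
#' positions.
#'
#' @param trip Trip data.frame.
#' @param colony One-row colony data.frame (defaults to the trip's `colony`
#'   attribute).
#' @return Maximum distance in km.
#' @export
trip_max_distance <- function(trip, colony = attr(trip, "colony")) {
  if (is.null(trip) || nrow(trip) == 0) stop("empty trip")
  stopifnot(!is.null(colony))
  max(sqrt((trip$x_km - colony$x[1])^2 + (trip$y_km - colony$y[1])^2))
}

#' Cumulative along-path length of a trip
#'
#' @param trip Trip data.frame.
#' @return Path length in km.
#' @export
trip_path_length <- function(trip) {
  if (is.null(trip) || nrow(trip) == 0) stop("empty trip")
  sum(sqrt(diff(trip$x_km)^2 + diff(trip$y_km)^2))
}

#' Summary table for a list of trips
#'
#' @param trips List of trip data.frames.
#' @return data.frame with one row per trip: identifiers, start/end, fix
#'   count, maximum and mean displacement from the colony (km), and cumulative
#'   path length (km).
#' @export
trip_summary <- function(trips) {
  rows <- lapply(seq_along(trips), function(i) {
    tr <- trips[[i]]; colony <- attr(tr, "colony")
    d <- sqrt((tr$x_km - colony$x[1])^2 + (tr$y_km - colony$y[1])^2)
    data.frame(
      trip_id = i,
      individual_id = as.character(attr(tr, "individual_id")),
      colony_id = if ("id" %in% names(colony)) colony$id else NA_character_,
      start = tr$timestamp[1], end = tr$timestamp[nrow(tr)],
      n_fixes = nrow(tr),
      max_distance_km = max(d), mean_distance_km = mean(d),
      path_length_km = trip_path_length(tr),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
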