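#' Synthetic archipelago worlds with known habitat preference
#'
#' The synthetic-world generator produces the inputs the analysis pipeline
#' expects from a real study system: an island land mask on a planar equal-area
#' grid, static bathymetry/slope, daily dynamic fields (SST, sea level anomaly,
#' geostrophic currents and their eddy kinetic energy), colonies of varying
#' population size on the coastline, and central-place foraging tracks whose
#' step selection follows a known preference function (distance decay plus a
#' bathymetry response). Because the preference is known, parameter-recovery
#' tests can check that the habitat models recover it.
#'
#' @name synthetic_world
NULL

# bilinear upsample of a coarse matrix to nr x nc (used for smooth random fields)
bilinear_upsample <- function(m, nr, nc) {
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nc)
  r0 <- pmin(floor(ri), nrow(m) - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), ncol(m) - 1L); fc <- ci - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c0 + 1L, drop = FALSE]
  d <- m[r0 + 1L, c0, drop = FALSE]; e <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * d + wc * e)
}

# spatially smooth Gaussian random field via coarse-grid upsampling
smooth_field <- function(grid, coarse = 8L, sd = 1) {
  m <- matrix(stats::rnorm((coarse + 1L)^2, sd = sd), coarse + 1L, coarse + 1L)
  bilinear_upsample(m, grid$n_rows, grid$n_cols)
}

#' Generate a synthetic archipelago and environmental raster stack
#'
#' Islands are irregular blobs; bathymetry (stored as positive depth in metres)
#' deepens with distance from the nearest land at `depth_rate` m/km plus smooth
#' noise; slope (degrees) is derived from bathymetry by central finite
#' differences; daily SST, SLA and geostrophic current (u, v) fields are smooth
#' random fields with a latitudinal and seasonal SST structure, and EKE is
#' computed from u and v as `0.5 * (u^2 + v^2)`.
#'
#' @param grid A [grid_spec()].
#' @param n_islands Number of islands (>= 1).
#' @param seed Integer seed; fixed seed gives a bit-identical world.
#' @param dates Date vector for the dynamic layers (default 30 consecutive
#'   days starting 2015-01-01).
#' @param depth_rate Offshore deepening rate, m per km of distance from land.
#' @param depth_noise_sd SD (m) of the smooth bathymetric noise field.
#' @return A list with `mask` (a logical [grid_raster()], TRUE = land) and
#'   `env` (an `env_stack`: `grid`, `dates`, `static$bathymetry`,
#'   `static$slope`, and `dynamic$sst/sla/u/v/eke` arrays of dimension
#'   `n_rows x n_cols x length(dates)`).
#' @export
make_world <- function(grid, n_islands, seed,
                       dates = seq(as.Date("2015-01-01"), by = "day", length.out = 30),
                       depth_rate = 20, depth_noise_sd = 10) {
  stopifnot(inherits(grid, "grid_spec"), n_islands >= 1)
  if (grid$n_rows * grid$n_cols < 200 * n_islands) {
    stop("grid too small to host ", n_islands, " island(s); need >= ",
         200 * n_islands, " cells")
  }
  with_seed(seed, {
    xs <- cell_x(grid); ys <- cell_y(grid)
    ext_x <- grid$n_cols * grid$cell_size; ext_y <- grid$n_rows * grid$cell_size
    land <- matrix(FALSE, grid$n_rows, grid$n_cols)
    X <- matrix(xs, grid$n_rows, grid$n_cols, byrow = TRUE)
    Y <- matrix(ys, grid$n_rows, grid$n_cols)
    for (k in seq_len(n_islands)) {
      cx <- grid$x_min + stats::runif(1, 0.2, 0.8) * ext_x
      cy <- grid$y_min + stats::runif(1, 0.2, 0.8) * ext_y
      r0 <- stats::runif(1, 0.05, 0.10) * min(ext_x, ext_y)
      ph <- stats::runif(3, 0, 2 * pi)
      am <- stats::runif(3, 0.05, 0.2)
      th <- atan2(Y - cy, X - cx)
      rb <- r0 * (1 + am[1] * sin(th + ph[1]) + am[2] * sin(2 * th + ph[2]) +
                    am[3] * sin(3 * th + ph[3]))
      land <- land | (sqrt((X - cx)^2 + (Y - cy)^2) < rb)
    }
    if (!any(land) || all(land)) {
      stop("grid too small to host ", n_islands, " island(s) with open sea")
    }
    dist_land <- chamfer_distance(land, grid$cell_size)
    depth <- depth_rate * dist_land + smooth_field(grid, sd = depth_noise_sd)
    depth <- pmax(depth, 0)
    depth[land] <- NA_real_

    # slope (deg) by central differences on depth with land treated as 0 m
    dz <- depth; dz[land] <- 0
    m_per_cell <- grid$cell_size * 1000
    gx <- dz; gy <- dz
    gx[, 2:(grid$n_cols - 1)] <- (dz[, 3:grid$n_cols] - dz[, 1:(grid$n_cols - 2)]) / (2 * m_per_cell)
    gx[, c(1, grid$n_cols)] <- 0
    gy[2:(grid$n_rows - 1), ] <- (dz[3:grid$n_rows, ] - dz[1:(grid$n_rows - 2), ]) / (2 * m_per_cell)
    gy[c(1, grid$n_rows), ] <- 0
    slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    slope[land] <- NA_real_

    nd <- length(dates)
    dyn <- function() array(NA_real_, c(grid$n_rows, grid$n_cols, nd))
    sst <- dyn(); sla <- dyn(); u <- dyn(); v <- dyn()
    doy <- as.integer(format(dates, "%j"))
    for (k in seq_len(nd)) {
      base <- 8 + 2 * sin(2 * pi * doy[k] / 365) - 0.01 * (Y - grid$y_min)
      sst[, , k] <- base + smooth_field(grid, sd = 0.5)
      sla[, , k] <- smooth_field(grid, sd = 0.05)
      u[, , k] <- smooth_field(grid, sd = 0.15)
      v[, , k] <- smooth_field(grid, sd = 0.15)
    }
    eke <- 0.5 * (u^2 + v^2)
    for (k in seq_len(nd)) {
      for (nm in c("sst", "sla", "u", "v", "eke")) {
        a <- get(nm); a[, , k][land] <- NA_real_; assign(nm, a)
      }
    }
    env <- structure(
      list(grid = grid, dates = dates,
           static = list(bathymetry = depth, slope = slope),
           dynamic = list(sst = sst, sla = sla, u = u, v = v, eke = eke)),
      class = "env_stack"
    )
    list(mask = grid_raster(grid, land), env = env)
  })
}

#' Eddy kinetic energy from geostrophic current components
#'
#' `EKE = 0.5 * (u^2 + v^2)`, cell-wise, in m^2/s^2.
#'
#' @param u,v [grid_raster()]s of zonal and meridional current (m/s) on one grid.
#' @return A [grid_raster()] of EKE.
#' @export
eke_from_currents <- function(u, v) {
  stopifnot(inherits(u, "grid_raster"), inherits(v, "grid_raster"))
  check_same_grid(u$grid, v$grid, "current rasters")
  grid_raster(u$grid, 0.5 * (u$values^2 + v$values^2))
}

coastal_sea_cells <- function(mask) {
  land <- mask$values
  nr <- nrow(land); nc <- ncol(land)
  near_land <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
    ok_r <- ri >= 1 & ri <= nr; ok_c <- cj >= 1 & cj <= nc
    near_land[ok_r, ok_c] <- near_land[ok_r, ok_c] | land[ri[ok_r], cj[ok_c]]
  }
  which(!land & near_land, arr.ind = TRUE)
}

#' Place breeding colonies on the coastline
#'
#' Colonies occupy distinct sea cells adjacent (8-neighbourhood) to land, with
#' population sizes drawn log-uniformly within `size_range`.
#'
#' @param mask Land mask ([grid_raster()], TRUE = land).
#' @param n Number of colonies.
#' @param size_range Length-2 numeric, min and max population size.
#' @param seed Integer seed.
#' @param species Species label stored on each colony.
#' @return A data.frame with columns `id`, `species`, `x`, `y`, `row`, `col`,
#'   `population_size`.
#' @export
place_colonies <- function(mask, n, size_range = c(500, 50000), seed = 1,
                           species = "synthetic_predator") {
  stopifnot(n >= 1, length(size_range) == 2, all(size_range > 0))
  coast <- coastal_sea_cells(mask)
  if (nrow(coast) < n) {
    stop("only ", nrow(coast), " coastal sea cells available for ", n, " colonies")
  }
  with_seed(seed, {
    pick <- sample.int(nrow(coast), n)
    sizes <- round(exp(stats::runif(n, log(size_range[1]), log(size_range[2]))))
    xy <- rc_to_xy(mask$grid, coast[pick, 1], coast[pick, 2])
    data.frame(
      id = sprintf("C%02d", seq_len(n)), species = species,
      x = xy[, "x"], y = xy[, "y"],
      row = as.integer(coast[pick, 1]), col = as.integer(coast[pick, 2]),
      population_size = pmax(1, sizes),
      stringsAsFactors = FALSE
    )
  })
}

#' Known habitat-preference function for track simulation
#'
#' The linear predictor steering simulated movement is
#' `distance_coef * d + f_bathy(depth)` where `d` is the least-cost at-sea
#' distance from the colony (km) and `f_bathy` linearly interpolates the
#' tabulated response. `distance_coef` must be negative: use must decline with
#' distance from the central place.
#'
#' @param distance_coef Per-km slope, < 0.
#' @param bathy_response data.frame with columns `depth` (m) and `effect`
#'   (dimensionless, on the linear-predictor scale).
#' @param noise_sd SD of the per-step Gaussian noise added to candidate-cell
#'   scores (0 = deterministic preference).
#' @return An object of class `truth_preference`.
#' @export
truth_preference <- function(distance_coef,
                             bathy_response = data.frame(
                               depth = c(0, 100, 300, 600, 2000),
                               effect = c(0.5, 1.5, 0.5, -1.5, -3)),
                             noise_sd = 0.25) {
  stopifnot(distance_coef < 0, all(c("depth", "effect") %in% names(bathy_response)))
  structure(list(distance_coef = distance_coef,
                 bathy_response = bathy_response,
                 noise_sd = noise_sd),
            class = "truth_preference")
}

truth_eta <- function(truth, dist_km, depth_m) {
  fb <- stats::approx(truth$bathy_response$depth, truth$bathy_response$effect,
                      xout = depth_m, rule = 2)$y
  truth$distance_coef * dist_km + fb
}

neighbour_offsets <- cbind(
  di = c(-1, -1, -1, 0, 0, 1, 1, 1),
  dj = c(-1, 0, 1, -1, 1, -1, 0, 1)
)

#' Simulate habitat-biased central-place foraging tracks
#'
#' Movement is a discrete-time biased random walk over sea cells: at each
#' hourly step the animal moves to an 8-neighbour sea cell with probability
#' proportional to `exp(eta_truth + noise)`, where `eta_truth` comes from
#' [truth_preference()]. After a random outbound phase each trip is forced
#' back to the colony by steepest descent on the least-cost distance raster, so
#' every trip starts and ends on the colony cell. Observed fixes are the true
#' cell-centre positions plus isotropic Gaussian error (source-dependent:
#' `argos_sd` for Argos, `argos_sd / 5` for Fastloc GPS, 0 for GPS), with
#' per-fix dropout at `gap_prob`. Argos fixes carry a quality class and
#' Fastloc fixes a satellite count drawn uniformly from `fastloc_sat_range`.
#'
#' @param colonies Colony data.frame from [place_colonies()].
#' @param env An `env_stack` from [make_world()].
#' @param mask Land mask [grid_raster()].
#' @param truth A [truth_preference()].
#' @param n_individuals,trips_per_individual Counts.
#' @param error_model List with `argos_sd` (km), `gap_prob` in [0, 1),
#'   `fastloc_sat_range` (length-2 integer).
#' @param seed Integer seed.
#' @param sources Candidate tag types assigned per individual.
#' @param steps_out Range (length 2) of outbound steps per trip.
#' @param start_time POSIXct start of sampling; defaults to midnight of the
#'   first env date.
#' @return A list of track data.frames (columns `individual_id`, `species`,
#'   `colony_id`, `timestamp`, `x_km`, `y_km`, `source`, `quality_class`,
#'   `n_satellites`, `date`), each with attributes `true_positions` (pre-error,
#'   pre-dropout fixes with a `trip` index) and `colony` (the colony row).
#' @export
simulate_tracks <- function(colonies, env, mask, truth,
                            n_individuals, trips_per_individual,
                            error_model = list(argos_sd = 0.5, gap_prob = 0.1,
                                               fastloc_sat_range = c(3L, 10L)),
                            seed = 1,
                            sources = c("argos", "gps", "fastloc"),
                            steps_out = c(8, 20),
                            start_time = NULL) {
  stopifnot(inherits(truth, "truth_preference"), truth$distance_coef < 0)
  check_same_grid(env$grid, mask$grid, "env stack and land mask")
  if (any(is.na(xy_to_rc(mask$grid, colonies$x, colonies$y)))) {
    stop("colony located outside the mask grid")
  }
  grid <- mask$grid
  land <- mask$values
  if (is.null(start_time)) start_time <- as.POSIXct(paste(env$dates[1], "00:00:00"), tz = "UTC")
  depth <- env$static$bathymetry

  # per-colony least-cost distance raster and truth linear predictor
  by_colony <- lapply(seq_len(nrow(colonies)), function(ci) {
    dr <- distance_raster(colonies[ci, ], mask)
    eta <- truth_eta(truth, dr$values, depth)
    eta[land] <- NA_real_
    list(dist = dr$values, eta = eta)
  })

  with_seed(seed, {
    ind_colony <- rep(seq_len(nrow(colonies)), length.out = n_individuals)
    ind_source <- sample(sources, n_individuals, replace = TRUE)
    tracks <- vector("list", n_individuals)
    argos_classes <- c("3", "2", "1", "0", "A", "B")
    for (ind in seq_len(n_individuals)) {
      ci <- ind_colony[ind]
      col_row <- colonies[ci, ]
      ccell <- c(col_row$row, col_row$col)
      eta <- by_colony[[ci]]$eta
      dist_c <- by_colony[[ci]]$dist
      pos <- list(); trip_id <- integer(0)
      t_hr <- 0
      times <- numeric(0)
      for (trip in seq_len(trips_per_individual)) {
        cur <- ccell
        pos[[length(pos) + 1]] <- cur; trip_id <- c(trip_id, trip); times <- c(times, t_hr)
        n_out <- sample(seq(steps_out[1], steps_out[2]), 1)
        for (s in seq_len(n_out)) {
          cand <- cbind(cur[1] + neighbour_offsets[, 1], cur[2] + neighbour_offsets[, 2])
          ok <- cand[, 1] >= 1 & cand[, 1] <= grid$n_rows &
            cand[, 2] >= 1 & cand[, 2] <= grid$n_cols
          cand <- cand[ok, , drop = FALSE]
          ok2 <- !land[cand] & is.finite(eta[cand]) &
            !(cand[, 1] == ccell[1] & cand[, 2] == ccell[2])  # no mid-trip colony visit
          cand <- cand[ok2, , drop = FALSE]
          if (nrow(cand) == 0) break
          w <- exp(eta[cand] + stats::rnorm(nrow(cand), sd = truth$noise_sd))
          cur <- cand[sample.int(nrow(cand), 1, prob = w), ]
          t_hr <- t_hr + 1
          pos[[length(pos) + 1]] <- cur; trip_id <- c(trip_id, trip); times <- c(times, t_hr)
        }
        # forced return: steepest descent on the least-cost distance raster
        guard <- 0
        while (!all(cur == ccell) && guard < 10000) {
          cand <- cbind(cur[1] + neighbour_offsets[, 1], cur[2] + neighbour_offsets[, 2])
          ok <- cand[, 1] >= 1 & cand[, 1] <= grid$n_rows &
            cand[, 2] >= 1 & cand[, 2] <= grid$n_cols
          cand <- cand[ok, , drop = FALSE]
          cand <- cand[!land[cand] & is.finite(dist_c[cand]), , drop = FALSE]
          cur <- cand[which.min(dist_c[cand]), ]
          t_hr <- t_hr + 1
          pos[[length(pos) + 1]] <- cur; trip_id <- c(trip_id, trip); times <- c(times, t_hr)
          guard <- guard + 1
        }
        t_hr <- t_hr + 6  # rest at the colony between trips
      }
      rc <- do.call(rbind, pos)
      xy <- rc_to_xy(grid, rc[, 1], rc[, 2])
      src <- ind_source[ind]
      obs_sd <- switch(src, argos = error_model$argos_sd,
                       fastloc = error_model$argos_sd / 5, gps = 0)
      n <- nrow(xy)
      true_df <- data.frame(
        timestamp = start_time + times * 3600,
        x_km = xy[, "x"], y_km = xy[, "y"], trip = trip_id
      )
      obs <- data.frame(
        individual_id = sprintf("%s_I%03d", col_row$id, ind),
        species = col_row$species,
        colony_id = col_row$id,
        timestamp = true_df$timestamp,
        x_km = true_df$x_km + stats::rnorm(n, sd = obs_sd),
        y_km = true_df$y_km + stats::rnorm(n, sd = obs_sd),
        source = src,
        quality_class = if (src == "argos") sample(argos_classes, n, replace = TRUE) else NA_character_,
        n_satellites = if (src == "fastloc")
          sample(seq(error_model$fastloc_sat_range[1], error_model$fastloc_sat_range[2]),
                 n, replace = TRUE) else NA_integer_,
        stringsAsFactors = FALSE
      )
      keep <- stats::runif(n) >= error_model$gap_prob
      obs <- obs[keep, , drop = FALSE]
      obs$date <- as.Date(obs$timestamp, tz = "UTC")
      attr(obs, "true_positions") <- true_df
      attr(obs, "colony") <- col_row
      class(obs) <- c("cpf_track", "data.frame")
      tracks[[ind]] <- obs
    }
    tracks
  })
}

#' Bind a list of tracks into one data.frame
#'
#' @param tracks List of track data.frames.
#' @return A single data.frame.
#' @export
bind_tracks <- function(tracks) {
  out <- do.call(rbind, lapply(tracks, function(t) {
    t <- as.data.frame(t); rownames(t) <- NULL; t
  }))
  rownames(out) <- NULL
  out
}
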