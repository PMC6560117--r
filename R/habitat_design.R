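#' Case-control design construction
#'
#' Habitat selection is modelled with a case-control (use/pseudo-absence)
#' design: each observed at-sea location is contrasted with `ratio` random
#' at-sea locations drawn uniformly from the region accessible to animals from
#' that colony (least-cost at-sea distance within `accessibility_factor` times
#' the group's maximum trip distance), temporally matched by drawing dates from
#' the presence set. Covariates: least-cost distance from the colony, a null
#' density competition index (population size / distance^2 summed over the
#' other colonies), bathymetry, slope, SST, SLA and EKE.
#'
#' @name habitat_design
NULL

#' 8-connected sea-cell graph
#'
#' Undirected graph over sea cells with edge weights `cell_size` (orthogonal)
#' and `cell_size * sqrt(2)` (diagonal), used for least-cost at-sea distances.
#'
#' @param mask Land mask [grid_raster()] (TRUE = land).
#' @return A list with `graph` (igraph) and `vid` (matrix mapping cells to
#'   vertex ids, NA on land).
#' @export
sea_graph <- function(mask) {
  land <- mask$values
  nr <- nrow(land); nc <- ncol(land)
  vid <- matrix(NA_integer_, nr, nc)
  vid[!land] <- seq_len(sum(!land))
  o <- mask$grid$cell_size; dg <- o * sqrt(2)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  add_edges <- function(di, dj, wt) {
    i1 <- max(1, 1 - di):min(nr, nr - di)
    j1 <- max(1, 1 - dj):min(nc, nc - dj)
    a <- vid[i1, j1, drop = FALSE]
    b <- vid[i1 + di, j1 + dj, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    from <<- c(from, a[ok]); to <<- c(to, b[ok]); w <<- c(w, rep(wt, sum(ok)))
  }
  add_edges(0L, 1L, o); add_edges(1L, 0L, o)
  add_edges(1L, 1L, dg); add_edges(1L, -1L, dg)
  g <- igraph::make_graph(rbind(from, to), n = sum(!land), directed = FALSE)
  igraph::E(g)$weight <- w
  list(graph = g, vid = vid)
}

#' Least-cost at-sea distance raster from a colony
#'
#' Shortest-path distance (km) over the 8-connected sea-cell graph, the cost
#' surface used both for the distance covariate and for accessibility limits;
#' travel must avoid land. Sea cells unreachable from the colony are `Inf`,
#' land cells `NA`.
#'
#' @param colony One-row colony data.frame (needs `x`, `y` or `row`, `col`).
#' @param mask Land mask [grid_raster()].
#' @param graph Optional precomputed [sea_graph()] for `mask` (reused across
#'   colonies for speed).
#' @return A [grid_raster()]; 0 at the colony cell.
#' @export
distance_raster <- function(colony, mask, graph = NULL) {
  rc <- colony_rc(colony, mask$grid)
  if (mask$values[rc[1], rc[2]]) stop("colony cell is on land")
  if (is.null(graph)) graph <- sea_graph(mask)
  src <- graph$vid[rc[1], rc[2]]
  d <- igraph::distances(graph$graph, v = src)[1, ]
  out <- matrix(NA_real_, mask$grid$n_rows, mask$grid$n_cols)
  out[!mask$values] <- d[graph$vid[!mask$values]]
  r <- grid_raster(mask$grid, out)
  attr(r, "colony_id") <- if ("id" %in% names(colony)) colony$id else NA_character_
  r
}

colony_rc <- function(colony, grid) {
  if (all(c("row", "col") %in% names(colony)) &&
      !is.na(colony$row[1]) && !is.na(colony$col[1])) {
    return(c(colony$row[1], colony$col[1]))
  }
  rc <- xy_to_rc(grid, colony$x[1], colony$y[1])
  if (any(is.na(rc))) stop("colony lies outside the grid")
  c(rc[1, "row"], rc[1, "col"])
}

#' Accessible region around a colony
#'
#' Sea cells whose least-cost distance from the colony does not exceed
#' `accessibility_factor` times the group's maximum trip distance.
#'
#' @param colony One-row colony data.frame.
#' @param max_trip_distance Group maximum trip distance (km), > 0.
#' @param mask Land mask [grid_raster()].
#' @param accessibility_factor Multiplier on the maximum trip distance
#'   (default 1.1).
#' @param dist Optional precomputed [distance_raster()] for this colony.
#' @return An object of class `accessible_region`: `colony_id`, `cells`
#'   (two-column row/col matrix), `radius_used` (km), and `dist` (the distance
#'   raster).
#' @export
accessible_region <- function(colony, max_trip_distance, mask,
                              accessibility_factor = 1.1, dist = NULL) {
  stopifnot(max_trip_distance > 0, accessibility_factor > 0)
  if (is.null(dist)) dist <- distance_raster(colony, mask)
  radius <- accessibility_factor * max_trip_distance
  cells <- which(!is.na(dist$values) & dist$values <= radius, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("accessible region is empty at radius ", radius, " km")
  structure(list(colony_id = if ("id" %in% names(colony)) colony$id else NA_character_,
                 cells = cells, radius_used = radius, dist = dist),
            class = "accessible_region")
}

#' Sample temporally matched pseudo-absences
#'
#' Draws `ratio` pseudo-absence rows per presence, placed uniformly over the
#' accessible region (uniform cell choice, then uniform position within the
#' cell) with dates drawn uniformly from the presence date pool.
#'
#' @param presences data.frame of presence rows (used for its row count and,
#'   by default, its `date` column as the date pool).
#' @param region An [accessible_region()].
#' @param ratio Pseudo-absences per presence (default 3).
#' @param date_pool Dates to draw from; defaults to `presences$date`.
#' @param seed Integer seed.
#' @return data.frame with `label = 0`, `x`, `y`, `date`, `colony_id`.
#' @export
sample_pseudo_absences <- function(presences, region, ratio = 3,
                                   date_pool = presences$date, seed = 1) {
  stopifnot(inherits(region, "accessible_region"), ratio >= 1, length(date_pool) >= 1)
  n <- nrow(presences) * ratio
  grid <- region$dist$grid
  with_seed(seed, {
    pick <- sample.int(nrow(region$cells), n, replace = TRUE)
    rc <- region$cells[pick, , drop = FALSE]
    ctr <- rc_to_xy(grid, rc[, 1], rc[, 2])
    half <- grid$cell_size / 2
    data.frame(
      label = 0L,
      x = ctr[, "x"] + stats::runif(n, -half, half),
      y = ctr[, "y"] + stats::runif(n, -half, half),
      date = sample(date_pool, n, replace = TRUE),
      colony_id = region$colony_id,
      stringsAsFactors = FALSE
    )
  })
}

#' Null-density competition raster
#'
#' Per-colony null density is `population_size / d^2` with `d` the least-cost
#' distance (km) from that colony, floored at half a cell size to keep the
#' colony cell finite. The competition raster for a focal colony is the sum of
#' the null-density rasters of all *other* colonies.
#'
#' @param colonies Colony data.frame (needs `id`, `population_size`).
#' @param distance_rasters Named list of [distance_raster()]s, one per colony id.
#' @param focal_colony Colony id whose competition raster is wanted.
#' @return A [grid_raster()] of summed competition from the other colonies
#'   (all-zero when there is a single colony).
#' @export
null_density <- function(colonies, distance_rasters, focal_colony) {
  missing_ids <- setdiff(colonies$id, names(distance_rasters))
  if (length(missing_ids)) {
    stop("missing distance raster(s) for colony: ", paste(missing_ids, collapse = ", "))
  }
  if (!focal_colony %in% colonies$id) stop("unknown focal colony ", focal_colony)
  grid <- distance_rasters[[1]]$grid
  total <- matrix(0, grid$n_rows, grid$n_cols)
  for (cid in setdiff(colonies$id, focal_colony)) {
    total <- total + single_null_density(
      colonies$population_size[colonies$id == cid],
      distance_rasters[[cid]])$values
  }
  total[is.na(distance_rasters[[focal_colony]]$values)] <- NA_real_
  grid_raster(grid, total)
}

#' @rdname null_density
#' @param population_size Population size of one colony.
#' @param dist Its [distance_raster()].
#' @export
single_null_density <- function(population_size, dist) {
  d <- pmax(dist$values, dist$grid$cell_size / 2)
  grid_raster(dist$grid, population_size / d^2)
}

#' Attach covariates to presence / pseudo-absence rows
#'
#' Static covariates (bathymetry, slope) and the distance and competition
#' rasters are read at each row's cell; dynamic covariates (SST, SLA, EKE) are
#' read from the layer matching the row's date. Rows with any missing
#' covariate (land cell, unreachable cell or date outside the dynamic
#' coverage) are dropped with a warning; the drop count is stored in the
#' `dropped` attribute.
#'
#' @param rows data.frame with `label`, `x`, `y`, `date`, `colony_id`.
#' @param env An `env_stack`.
#' @param distance [distance_raster()] for the rows' colony.
#' @param competition Competition raster from [null_density()].
#' @return A case-control data.frame with covariate columns `distance`,
#'   `density`, `bathymetry`, `slope`, `sst`, `sla`, `eke`.
#' @export
extract_covariates <- function(rows, env, distance, competition) {
  rc <- xy_to_rc(env$grid, rows$x, rows$y)
  idx <- cbind(rc[, "row"], rc[, "col"])
  out <- rows
  out$distance <- distance$values[idx]
  out$density <- competition$values[idx]
  out$bathymetry <- env$static$bathymetry[idx]
  out$slope <- env$static$slope[idx]
  di <- match(as.Date(rows$date), env$dates)
  dyn_at <- function(a) {
    v <- rep(NA_real_, nrow(rows))
    ok <- !is.na(di) & !is.na(idx[, 1])
    v[ok] <- a[cbind(idx[ok, 1], idx[ok, 2], di[ok])]
    v
  }
  out$sst <- dyn_at(env$dynamic$sst)
  out$sla <- dyn_at(env$dynamic$sla)
  out$eke <- dyn_at(env$dynamic$eke)
  out$distance[!is.finite(out$distance)] <- NA_real_
  covars <- c("distance", "density", "bathymetry", "slope", "sst", "sla", "eke")
  bad <- !stats::complete.cases(out[, covars])
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped for missing covariates ",
            "(land, unreachable cell, or date outside dynamic coverage)")
  }
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(bad)
  attr(out, "covariates") <- covars
  out
}

#' Standardize covariates to mean 0, SD 1
#'
#' Sample SD (n - 1 denominator). Adds `<name>_std` columns alongside the raw
#' values and stores the transform in the `standardization` attribute (a
#' data.frame `covariate`, `mean`, `sd`) for reuse when building prediction
#' surfaces. Zero-variance covariates are excluded with a warning.
#'
#' @param table Case-control data.frame.
#' @param covariates Covariate column names (default: the `covariates`
#'   attribute set by [extract_covariates()]).
#' @return The table with standardized columns; attributes `standardization`
#'   and `covariates` (the retained set).
#' @export
standardize_covariates <- function(table, covariates = attr(table, "covariates")) {
  stopifnot(!is.null(covariates))
  keep <- character(0); mus <- numeric(0); sds <- numeric(0)
  for (v in covariates) {
    mu <- mean(table[[v]]); s <- stats::sd(table[[v]])
    if (!is.finite(s) || s == 0) {
      warning("covariate '", v, "' has zero variance and is excluded")
      next
    }
    table[[paste0(v, "_std")]] <- (table[[v]] - mu) / s
    keep <- c(keep, v); mus <- c(mus, mu); sds <- c(sds, s)
  }
  attr(table, "standardization") <- data.frame(covariate = keep, mean = mus, sd = sds,
                                               stringsAsFactors = FALSE)
  attr(table, "covariates") <- keep
  table
}

#' Variance-inflation-factor screen
#'
#' Iteratively removes the covariate with the largest VIF
#' (`1 / (1 - R^2)` from regressing it on the remaining covariates) until all
#' VIFs are at or below `threshold`.
#'
#' @param table Data.frame holding the covariate columns.
#' @param covariates Covariate column names to screen.
#' @param threshold VIF threshold (default 3).
#' @return Character vector of retained covariates, with a `vif` attribute
#'   giving the final VIFs.
#' @export
vif_screen <- function(table, covariates = attr(table, "covariates"), threshold = 3) {
  stopifnot(length(covariates) >= 2, threshold > 1)
  vifs_of <- function(vars) {
    vapply(vars, function(v) {
      fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                       data = table)
      r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits handled below
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vars <- covariates
  repeat {
    if (length(vars) < 2) break
    v <- vifs_of(vars)
    if (max(v) <= threshold) break
    vars <- setdiff(vars, names(which.max(v)))
  }
  out <- vars
  attr(out, "vif") <- if (length(vars) >= 2) vifs_of(vars) else stats::setNames(1, vars)
  out
}
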