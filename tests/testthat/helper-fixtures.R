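# Shared fixtures, built in code. Heavier objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# all-sea mask with a single land cell in the SW corner (masks must hold both)
open_sea_mask <- function(n = 20, cell = 1) {
  g <- grid_spec(0, 0, n, n, cell)
  land <- matrix(FALSE, n, n)
  land[1, 1] <- TRUE
  grid_raster(g, land)
}

# mask with a central land block (an island), for detour / coastline tests
island_mask <- function(n = 21, cell = 1, half = 3) {
  g <- grid_spec(0, 0, n, n, cell)
  land <- matrix(FALSE, n, n)
  mid <- (n + 1) %/% 2
  land[(mid - half):(mid + half), (mid - half):(mid + half)] <- TRUE
  grid_raster(g, land)
}

# straight-line trip at constant speed (km/h), hourly fixes
straight_trip <- function(v = 5, n = 24, t0 = as.POSIXct("2015-01-01", tz = "UTC")) {
  tr <- data.frame(
    timestamp = t0 + 3600 * (seq_len(n) - 1),
    x_km = v * (seq_len(n) - 1),
    y_km = 0
  )
  class(tr) <- c("cpf_trip", "data.frame")
  tr
}

fixes_df <- function(t_hours, x, y, source = "gps", n_satellites = NA_integer_,
                     t0 = as.POSIXct("2015-01-01", tz = "UTC")) {
  data.frame(
    timestamp = t0 + 3600 * t_hours,
    x_km = x, y_km = y,
    source = rep(source, length.out = length(x)),
    quality_class = NA_character_,
    n_satellites = rep(n_satellites, length.out = length(x)),
    stringsAsFactors = FALSE
  )
}

# independent Dijkstra oracle over the 8-connected sea graph (array-scan
# implementation, deliberately unrelated to the igraph route)
dijkstra_oracle <- function(mask, row0, col0) {
  land <- mask$values
  nr <- nrow(land); nc <- ncol(land)
  cell <- mask$grid$cell_size
  d <- matrix(Inf, nr, nc)
  d[land] <- NA_real_
  visited <- matrix(FALSE, nr, nc)
  d[row0, col0] <- 0
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  w <- ifelse(abs(offs[, 1]) + abs(offs[, 2]) == 2, cell * sqrt(2), cell)
  repeat {
    dm <- d; dm[visited] <- Inf
    u <- which.min(dm)
    if (!is.finite(dm[u])) break
    visited[u] <- TRUE
    ui <- (u - 1) %% nr + 1; uj <- (u - 1) %/% nr + 1
    for (k in seq_len(8)) {
      vi <- ui + offs[k, 1]; vj <- uj + offs[k, 2]
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      if (land[vi, vj]) next
      nd <- d[ui, uj] + w[k]
      if (nd < d[vi, vj]) d[vi, vj] <- nd
    }
  }
  d
}

# O(n^2) pairwise Mann-Whitney AUC oracle, ties counted 1/2
auc_pairwise_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sa <- scores[labels == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sa) + 0.5 * sum(p == sa)
  tot / (length(sp) * length(sa))
}

# shared mid-size synthetic study (world + colonies + graph), reused across files
small_study <- function() {
  cached("small_study", function() {
    g <- grid_spec(0, 0, 70, 70, 5)
    w <- make_world(g, 2, seed = 101)
    colonies <- place_colonies(w$mask, 4, size_range = c(1000, 20000), seed = 102)
    graph <- sea_graph(w$mask)
    dists <- lapply(seq_len(nrow(colonies)), function(i) {
      distance_raster(colonies[i, ], w$mask, graph = graph)
    })
    names(dists) <- colonies$id
    list(grid = g, world = w, colonies = colonies, graph = graph, dists = dists)
  })
}

# case-control table built from simulated tracks on the shared study world;
# truth uses distance + bathymetry only, so sst/sla/eke are pure noise
study_table <- function() {
  cached("study_table", function() {
    st <- small_study()
    tracks <- simulate_tracks(
      st$colonies, st$world$env, st$world$mask,
      truth_preference(-0.05, noise_sd = 0.25),
      n_individuals = 12, trips_per_individual = 3,
      error_model = list(argos_sd = 0, gap_prob = 0, fastloc_sat_range = c(4, 10)),
      seed = 103)
    build_case_control(tracks, st, ratio = 3, seed = 104)
  })
}

# assemble a standardized case-control table from raw tracks (used by tests
# and kept close to the pipeline's design stage)
build_case_control <- function(tracks, st, ratio = 3, seed = 1) {
  trips <- list()
  for (tr in tracks) {
    colony <- st$colonies[st$colonies$id == tr$colony_id[1], ]
    trips <- c(trips, delineate_trips(tr, st$world$mask, colony,
                                      return_radius = 8, min_trip_fixes = 3))
  }
  maxd <- max(vapply(trips, trip_max_distance, numeric(1)))
  tabs <- list()
  for (cid in unique(vapply(trips, function(t) attr(t, "colony")$id, character(1)))) {
    ctrips <- Filter(function(t) attr(t, "colony")$id == cid, trips)
    pres <- do.call(rbind, lapply(ctrips, function(t) {
      data.frame(label = 1L, x = t$x_km, y = t$y_km,
                 date = as.Date(t$timestamp, tz = "UTC"), colony_id = cid)
    }))
    region <- accessible_region(st$colonies[st$colonies$id == cid, ], maxd,
                                st$world$mask, 1.1, dist = st$dists[[cid]])
    pseudo <- sample_pseudo_absences(pres, region, ratio = ratio, seed = seed)
    comp <- null_density(st$colonies, st$dists, cid)
    tabs[[cid]] <- extract_covariates(rbind(pres, pseudo), st$world$env,
                                      st$dists[[cid]], comp)
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  attr(tab, "covariates") <- attr(tabs[[1]], "covariates")
  attr(tab, "max_trip_distance") <- maxd
  attr(tab, "trips") <- trips
  standardize_covariates(tab)
}

# trip with transit legs and area-restricted search planted in patches of
# width `patch_width` km (uncorrelated relocation inside the patch disc)
planted_patch_trip <- function(seed, patch_width = 10, n_in = 60, transit = 40,
                               v = 8, npatch = 2) {
  R <- patch_width / 2
  set.seed(seed)
  xs <- c(); ys <- c(); x0 <- 0
  for (p in seq_len(npatch)) {
    tx <- seq(x0, x0 + transit, by = v)
    xs <- c(xs, tx); ys <- c(ys, rep(0, length(tx)))
    cx <- x0 + transit + R
    for (i in seq_len(n_in)) {
      repeat {
        px <- runif(1, -R, R); py <- runif(1, -R, R)
        if (px^2 + py^2 <= R^2) break
      }
      xs <- c(xs, cx + px); ys <- c(ys, py)
    }
    x0 <- cx + R
  }
  tx <- seq(x0, x0 + transit, by = v)
  xs <- c(xs, tx); ys <- c(ys, rep(0, length(tx)))
  fixes_df(seq_along(xs) - 1, x = xs, y = ys)
}

# one end-to-end recovery run: habitat-biased tracks (negative distance
# effect + unimodal bathymetry response, sst/sla/eke pure noise), case-control
# design, VIF screen, forward stepwise with colony folds
recovery_run <- function(seed, st = small_study(), n_individuals = 44,
                         trips_per_individual = 4) {
  tracks <- simulate_tracks(
    st$colonies, st$world$env, st$world$mask,
    truth_preference(-0.05, noise_sd = 0.25),
    n_individuals = n_individuals, trips_per_individual = trips_per_individual,
    error_model = list(argos_sd = 0, gap_prob = 0, fastloc_sat_range = c(4, 10)),
    seed = seed, steps_out = c(15, 30))
  n_fixes <- sum(vapply(tracks, nrow, integer(1)))
  tab <- build_case_control(tracks, st, ratio = 3, seed = seed + 1)
  folds <- fold_scheme(tab, "colony")
  cands <- as.character(vif_screen(tab, threshold = 3))
  model <- forward_stepwise(tab, cands, folds)
  list(model = model, table = tab, n_fixes = n_fixes, candidates = cands)
}
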