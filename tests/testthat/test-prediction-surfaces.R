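test_that("tau closed forms hold to 1e-12", {
  expect_equal(tau_from_eta(0, 0.5, 0.5), 1 / 3, tolerance = 1e-12)
  expect_equal(tau_from_eta(0, 0.75, 0.25), 1 / 13, tolerance = 1e-12)
  expect_equal(case_control_offset(0.75, 0.25), log(1 / 12), tolerance = 1e-15)
  # monotone increasing in eta, saturating at 1
  etas <- seq(-5, 30, by = 0.5)
  taus <- tau_from_eta(etas, 0.75, 0.25)
  expect_true(all(diff(taus) > 0))
  expect_equal(tau_from_eta(50, 0.75, 0.25), 1, tolerance = 1e-9)
  expect_error(tau_from_eta(0, 0.7, 0.2), "P_a")
})

test_that("tau equation matches an independent transcription on random inputs", {
  set.seed(50)
  for (k in 1:20) {
    P_u <- runif(1, 0.1, 0.9); P_a <- 1 - P_u
    eta <- rnorm(7, sd = 3)
    direct <- exp(log((1 - P_a) * P_u / P_a) + eta) /
      (1 + exp(log((1 - P_a) * P_u / P_a) + eta))
    expect_equal(tau_from_eta(eta, P_a, P_u), direct, tolerance = 1e-12)
  }
})

test_that("tau_predict standardizes with stored parameters and flags their absence", {
  tab <- study_table()
  folds <- fold_scheme(tab, "colony")
  m <- forward_stepwise(tab, c("distance", "bathymetry"), folds,
                        tensor_pair = NULL)
  newdata <- tab[1:20, c("distance", "bathymetry")]
  tau <- tau_predict(m, newdata)
  expect_true(all(tau >= 0 & tau <= 1))
  # manual route: standardize, link, offset, logistic
  std <- m$standardization
  nd2 <- newdata
  for (v in c("distance", "bathymetry")) {
    nd2[[paste0(v, "_std")]] <- (nd2[[v]] - std$mean[std$covariate == v]) /
      std$sd[std$covariate == v]
  }
  eta <- predict(m$fit, nd2, type = "link")
  expect_equal(tau, plogis(eta + log((1 - m$P_a) * m$P_u / m$P_a)),
               tolerance = 1e-12)

  m_bare <- m
  m_bare$standardization <- NULL
  expect_error(tau_predict(m_bare, newdata), "standardization")
})

test_that("colony surfaces cover untracked colonies and respect accessibility", {
  st <- small_study()
  tab <- study_table()
  folds <- fold_scheme(tab, "colony")
  m <- forward_stepwise(tab, c("distance", "bathymetry"), folds,
                        tensor_pair = NULL)
  # registry with an extra colony that has no tracking data at all
  extra <- place_colonies(st$world$mask, 6, size_range = c(1000, 5000),
                          seed = 901)
  extra <- extra[!paste(extra$row, extra$col) %in%
                   paste(st$colonies$row, st$colonies$col), ][1, ]
  extra$id <- "UNTRACKED"
  registry <- rbind(st$colonies, extra)
  sf <- colony_surfaces(m, registry, st$world$env, st$world$mask,
                        max_trip_distance = attr(tab, "max_trip_distance"),
                        graph = st$graph)
  expect_length(sf, nrow(registry))
  un <- sf[["UNTRACKED"]]
  expect_false(is.null(un))
  sea_vals <- un$values[!st$world$mask$values]
  expect_true(all(sea_vals >= 0 & sea_vals <= 1, na.rm = TRUE))
  expect_gt(max(sea_vals, na.rm = TRUE), 0)
  # beyond the accessible radius tau is exactly 0
  dr <- distance_raster(extra, st$world$mask, graph = st$graph)
  outside <- which(dr$values > attr(un, "radius_used"))
  expect_true(all(un$values[outside] == 0, na.rm = TRUE))
  # land stays undefined
  expect_true(all(is.na(un$values[st$world$mask$values])))
  expect_error(colony_surfaces(m, registry[0, ], st$world$env, st$world$mask,
                               max_trip_distance = 50), "empty")
})

test_that("species aggregation: max, mean, weights and their limits", {
  g <- grid_spec(0, 0, 6, 6, 1)
  a <- grid_raster(g, matrix(runif(36, 0, 0.5), 6, 6))
  b <- grid_raster(g, matrix(runif(36, 0, 0.5), 6, 6))
  one <- species_surface(list(a))
  expect_equal(one$values, a$values)
  expect_equal(species_surface(list(a), weights = 7)$values, a$values)

  mx <- species_surface(list(a, b))
  expect_equal(mx$values, pmax(a$values, b$values))
  eq <- species_surface(list(a, b), weights = c(3, 3))
  expect_equal(eq$values, (a$values + b$values) / 2, tolerance = 1e-12)
  dom <- species_surface(list(a, b), weights = c(1e12, 1))
  expect_equal(dom$values, a$values, tolerance = 1e-6)
  expect_error(species_surface(list(a, b), weights = 1), "weights")
})

test_that("cumulative surface standardizes by maxima and sums, order-invariant", {
  g <- grid_spec(0, 0, 5, 5, 1)
  mk <- function(mx) grid_raster(g, matrix(runif(25, 0, mx), 5, 5))
  set.seed(51)
  s <- list(mk(0.2), mk(0.6), mk(0.9))
  cum <- cumulative_surface(s)
  brute <- Reduce(`+`, lapply(s, function(r) r$values / max(r$values)))
  expect_equal(cum$values, brute, tolerance = 1e-12)
  expect_equal(max(cumulative_surface(s[1])$values), 1, tolerance = 1e-12)
  nid <- cumulative_surface(list(s[[1]], s[[1]], s[[1]]))
  expect_equal(max(nid$values), 3, tolerance = 1e-12)
  # permutation invariance
  perm <- cumulative_surface(s[c(3, 1, 2)])
  expect_equal(cum$values, perm$values, tolerance = 1e-12)
  # all-zero surface excluded with warning
  zero <- grid_raster(g, matrix(0, 5, 5))
  expect_warning(cz <- cumulative_surface(list(s[[1]], zero)), "excluded")
  expect_equal(cz$values, s[[1]]$values / max(s[[1]]$values), tolerance = 1e-12)
})

test_that("overlap counts match brute force and respect the threshold", {
  g <- grid_spec(0, 0, 10, 10, 1)
  set.seed(52)
  s <- lapply(1:4, function(i) grid_raster(g, matrix(runif(100), 10, 10)))
  ov <- overlap_surface(s, presence_threshold = 0.5)
  brute <- Reduce(`+`, lapply(s, function(r) {
    (r$values / max(r$values) >= 0.5) * 1L
  }))
  expect_equal(ov$count$values, brute)
  expect_lte(max(ov$count$values), 4)
  # permutation invariance
  ov2 <- overlap_surface(s[c(2, 4, 1, 3)], presence_threshold = 0.5)
  expect_equal(ov$count$values, ov2$count$values)

  # disjoint predicted ranges never exceed a count of 1
  left <- matrix(0, 10, 10); left[, 1:4] <- 1
  right <- matrix(0, 10, 10); right[, 7:10] <- 1
  dj <- overlap_surface(list(grid_raster(g, left), grid_raster(g, right)),
                        presence_threshold = 0.5)
  expect_lte(max(dj$count$values), 1)
  # N identical groups count N on the presence set and 0 elsewhere
  idd <- overlap_surface(list(s[[1]], s[[1]], s[[1]]), presence_threshold = 0.5)
  expect_setequal(unique(as.vector(idd$count$values)), c(0, 3))
})

test_that("identical colonies in a symmetric world get translated copies", {
  # two identical square islands 40 cells apart, constant dynamic fields;
  # every covariate field is then translation-symmetric between the islands
  g <- grid_spec(0, 0, 80, 40, 1)
  land <- matrix(FALSE, 40, 80)
  land[18:22, 10:14] <- TRUE
  land[18:22, 50:54] <- TRUE
  mask <- grid_raster(g, land)
  depth_km <- cpfhabitat:::chamfer_distance(land, 1)
  depth <- 20 * depth_km; depth[land] <- NA
  slope <- matrix(1, 40, 80); slope[land] <- NA
  dates <- seq(as.Date("2015-01-01"), by = "day", length.out = 3)
  const_layer <- function(v) {
    a <- array(v, c(40, 80, 3))
    for (k in 1:3) a[, , k][land] <- NA
    a
  }
  env <- structure(list(grid = g, dates = dates,
                        static = list(bathymetry = depth, slope = slope),
                        dynamic = list(sst = const_layer(8),
                                       sla = const_layer(0),
                                       u = const_layer(0.1),
                                       v = const_layer(0.1),
                                       eke = const_layer(0.01))),
                   class = "env_stack")
  registry <- data.frame(id = c("L", "R"), species = "s",
                         x = c(14.5, 54.5), y = c(19.5, 19.5),
                         row = c(20L, 20L), col = c(15L, 55L),
                         population_size = c(5000, 5000))
  tab <- study_table()
  folds <- fold_scheme(tab, "colony")
  m <- forward_stepwise(tab, c("distance", "bathymetry"), folds,
                        tensor_pair = NULL)
  sf <- colony_surfaces(m, registry, env, mask, max_trip_distance = 10,
                        accessibility_factor = 1.1)
  shift <- 40
  lv <- sf[["L"]]$values; rv <- sf[["R"]]$values
  # compare L's accessible neighbourhood with R's, translated by 40 columns
  cols <- 1:40
  expect_equal(lv[, cols], rv[, cols + shift], tolerance = 1e-9)
})
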