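test_that("least-cost distances match straight paths and exceed Euclid behind land", {
  mask <- open_sea_mask(12, cell = 1)
  colony <- data.frame(id = "A", x = 5.5, y = 5.5, row = 6, col = 6)
  dr <- distance_raster(colony, mask)
  expect_equal(dr$values[6, 6], 0)
  expect_equal(dr$values[6, 11], 5)                    # 5 cells straight east
  expect_equal(dr$values[10, 9], 3 * sqrt(2) + 1)      # (3,4) offset: 3 diag + 1 orth
  # never undercuts Euclidean distance
  g <- mask$grid
  idx <- which(!mask$values, arr.ind = TRUE)
  xy <- rc_to_xy(g, idx[, 1], idx[, 2])
  eu <- sqrt((xy[, "x"] - colony$x)^2 + (xy[, "y"] - colony$y)^2)
  expect_true(all(dr$values[idx] >= eu - 1e-9))

  # a wall forces a detour
  wall <- island_mask(21, cell = 1, half = 5)
  cw <- data.frame(id = "B", x = 2.5, y = 10.5, row = 11, col = 3)
  drw <- distance_raster(cw, wall)
  behind <- c(11, 19)   # directly across the island
  eu_b <- sqrt((rc_to_xy(wall$grid, 11, 19)[, "x"] - cw$x)^2)
  expect_gt(drw$values[behind[1], behind[2]], eu_b)

  on_land <- data.frame(id = "C", x = 10.5, y = 10.5, row = 11, col = 11)
  expect_error(distance_raster(on_land, wall), "land")
})

test_that("least-cost raster equals the Dijkstra oracle on random worlds", {
  set.seed(33)
  for (k in 1:100) {
    n <- sample(8:30, 1)
    g <- grid_spec(0, 0, n, n, 1)
    land <- matrix(runif(n * n) < 0.2, n, n)
    sea_idx <- which(!land, arr.ind = TRUE)
    if (nrow(sea_idx) < 5) next
    if (!any(land)) land[1, 1] <- TRUE
    mask <- grid_raster(g, land)
    src <- sea_idx[sample.int(nrow(sea_idx), 1), ]
    colony <- data.frame(id = "X", x = NA, y = NA, row = src[1], col = src[2])
    dr <- distance_raster(colony, mask)
    oracle <- dijkstra_oracle(mask, src[1], src[2])
    expect_equal(dr$values, oracle, tolerance = 1e-9)
  }
})

test_that("accessible region applies the 1.1 factor and rechecks membership", {
  st <- small_study()
  colony <- st$colonies[1, ]
  reg <- accessible_region(colony, 100, st$world$mask, 1.1,
                           dist = st$dists[[colony$id]])
  expect_equal(reg$radius_used, 110)
  dvals <- reg$dist$values[reg$cells]
  expect_true(all(dvals <= reg$radius_used))

  reg1 <- accessible_region(colony, 100, st$world$mask, 1.0,
                            dist = st$dists[[colony$id]])
  expect_equal(reg1$radius_used, 100)
  expect_lte(max(reg1$dist$values[reg1$cells]), 100)
  # a distance raster with no reachable cells leaves the region empty
  unreachable <- st$dists[[colony$id]]
  unreachable$values[] <- Inf
  expect_error(accessible_region(colony, 100, st$world$mask, 1.1,
                                 dist = unreachable),
               "empty")
})

test_that("pseudo-absences honour ratio, region, date pool and uniformity", {
  st <- small_study()
  colony <- st$colonies[2, ]
  reg <- accessible_region(colony, 80, st$world$mask, 1.1,
                           dist = st$dists[[colony$id]])
  pres <- data.frame(label = 1L, x = colony$x, y = colony$y,
                     date = rep(st$world$env$dates[1:5], length.out = 100),
                     colony_id = colony$id)
  pseudo <- sample_pseudo_absences(pres, reg, ratio = 3, seed = 8)
  expect_equal(nrow(pseudo), 300)
  expect_true(all(pseudo$date %in% pres$date))
  rc <- xy_to_rc(st$grid, pseudo$x, pseudo$y)
  expect_false(any(st$world$mask$values[rc]))
  expect_true(all(reg$dist$values[rc] <= reg$radius_used))
  expect_identical(pseudo, sample_pseudo_absences(pres, reg, ratio = 3, seed = 8))

  # exact label proportions downstream: P_a = 3/4, P_u = 1/4
  tab <- rbind(pres[, c("label", "x", "y")], pseudo[, c("label", "x", "y")])
  expect_equal(mean(tab$label == 0), 0.75)

  # chi-square uniformity over region cells (restricted 50-cell subregion)
  reg50 <- reg
  reg50$cells <- reg$cells[seq_len(50), , drop = FALSE]
  many <- sample_pseudo_absences(data.frame(x = numeric(3334)), reg50,
                                 ratio = 3, date_pool = pres$date, seed = 9)
  rc50 <- xy_to_rc(st$grid, many$x, many$y)
  key <- paste(rc50[, 1], rc50[, 2])
  cellkey <- paste(reg50$cells[, 1], reg50$cells[, 2])
  counts <- table(factor(key, levels = cellkey))
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("null density follows N/d^2, is additive and order-invariant", {
  st <- small_study()
  col1 <- st$colonies[1, ]
  nd <- single_null_density(1000, st$dists[[col1$id]])
  cell10 <- which(abs(st$dists[[col1$id]]$values - 10) < 0.26, arr.ind = TRUE)[1, , drop = FALSE]
  d_at <- st$dists[[col1$id]]$values[cell10]
  expect_equal(nd$values[cell10], 1000 / d_at^2, tolerance = 1e-12)
  expect_true(all(nd$values >= 0, na.rm = TRUE))
  # floored at half a cell: finite at the colony cell
  expect_true(is.finite(nd$values[col1$row, col1$col]))

  comp1 <- null_density(st$colonies, st$dists, st$colonies$id[1])
  singles <- lapply(seq_len(nrow(st$colonies)), function(i) {
    single_null_density(st$colonies$population_size[i], st$dists[[st$colonies$id[i]]])$values
  })
  brute <- Reduce(`+`, singles[-1])
  sea <- !st$world$mask$values & !is.na(comp1$values)
  expect_equal(comp1$values[sea], brute[sea], tolerance = 1e-9)

  # permutation invariance and linearity in population size
  shuffled <- st$colonies[c(3, 1, 4, 2), ]
  comp_shuf <- null_density(shuffled, st$dists, st$colonies$id[1])
  expect_equal(comp1$values, comp_shuf$values, tolerance = 1e-12)
  doubled <- st$colonies; doubled$population_size <- 2 * doubled$population_size
  expect_equal(null_density(doubled, st$dists, st$colonies$id[1])$values[sea],
               2 * comp1$values[sea], tolerance = 1e-12)

  expect_error(null_density(st$colonies, st$dists[-1], st$colonies$id[1]), "missing")
})

test_that("covariate extraction reads cells and dates, dropping incomplete rows", {
  st <- small_study()
  colony <- st$colonies[1, ]
  comp <- null_density(st$colonies, st$dists, colony$id)
  sea <- which(!st$world$mask$values &
                 is.finite(st$dists[[colony$id]]$values), arr.ind = TRUE)
  set.seed(10)
  pick <- sea[sample.int(nrow(sea), 50), ]
  xy <- rc_to_xy(st$grid, pick[, 1], pick[, 2])
  rows <- data.frame(label = 1L, x = xy[, "x"], y = xy[, "y"],
                     date = sample(st$world$env$dates, 50, replace = TRUE),
                     colony_id = colony$id)
  tab <- extract_covariates(rows, st$world$env, st$dists[[colony$id]], comp)
  expect_equal(attr(tab, "dropped"), 0)
  i <- 7
  rc <- xy_to_rc(st$grid, tab$x[i], tab$y[i])
  expect_equal(tab$bathymetry[i], st$world$env$static$bathymetry[rc])
  di <- match(tab$date[i], st$world$env$dates)
  expect_equal(tab$sst[i], st$world$env$dynamic$sst[rc[1], rc[2], di])
  expect_equal(tab$distance[i], st$dists[[colony$id]]$values[rc])

  # rows with out-of-window dates are dropped with a warning, count matches
  rows_bad <- rows
  rows_bad$date[1:5] <- max(st$world$env$dates) + 100
  expect_warning(tab2 <- extract_covariates(rows_bad, st$world$env,
                                            st$dists[[colony$id]], comp),
                 "dropped")
  expect_equal(attr(tab2, "dropped"), 5)
  expect_equal(nrow(tab2), 45)
})

test_that("standardization uses sample SD, stores parameters, is idempotent", {
  tab <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40), cns = c(5, 5, 5))
  attr(tab, "covariates") <- c("a", "b", "cns")
  expect_warning(std <- standardize_covariates(tab), "zero variance")
  expect_equal(std$a_std, c(-1, 0, 1))            # sample SD of 1,2,3 is 1
  expect_equal(mean(std$b_std), 0, tolerance = 1e-12)
  expect_equal(stats::sd(std$b_std), 1, tolerance = 1e-12)
  expect_false("cns_std" %in% names(std))
  expect_equal(attr(std, "covariates"), c("a", "b"))
  p <- attr(std, "standardization")
  expect_equal(p$mean[p$covariate == "a"], 2)
  expect_equal(p$sd[p$covariate == "a"], 1)

  # standardizing an already standardized column leaves it unchanged
  tab2 <- data.frame(z = std$b_std)
  attr(tab2, "covariates") <- "z"
  std2 <- standardize_covariates(tab2)
  expect_equal(std2$z_std, tab2$z, tolerance = 1e-12)
})

test_that("VIF screening matches explicit regressions and drops collinear terms", {
  set.seed(20)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.8 * x1 + 0.6 * rnorm(n)
  tab <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  # brute-force VIFs
  brute <- sapply(c("x1", "x2", "x3"), function(v) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(c("x1", "x2", "x3"), v), v),
                            data = tab))$r.squared
    1 / (1 - r2)
  })
  kept <- vif_screen(tab, c("x1", "x2", "x3"), threshold = 10)
  expect_equal(unname(attr(kept, "vif")[names(brute)[names(brute) %in% kept]]),
               unname(brute[names(brute) %in% kept]), tolerance = 1e-9)
  expect_setequal(as.character(kept), c("x1", "x2", "x3"))  # VIFs well below 10

  # perfectly correlated pair: one dropped
  tab$x4 <- 2 * tab$x1
  kept2 <- vif_screen(tab, c("x1", "x4"), threshold = 3)
  expect_length(as.character(kept2), 1)

  # orthogonal zero-mean covariates: all VIF 1, none dropped
  orth <- data.frame(o1 = rep(c(1, -1), 150),
                     o2 = rep(c(1, 1, -1, -1), 75),
                     o3 = rep(c(1, -1, -1, 1), 75))
  kept3 <- vif_screen(orth, c("o1", "o2", "o3"), threshold = 3)
  expect_setequal(as.character(kept3), c("o1", "o2", "o3"))
  expect_equal(unname(attr(kept3, "vif")), rep(1, 3), tolerance = 1e-9)
})
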