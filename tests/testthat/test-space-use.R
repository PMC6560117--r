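test_that("FPT matches the 2r/v closed form for straight-line motion", {
  set.seed(14)
  for (k in 1:20) {
    v <- runif(1, 2, 12)          # km/h
    r <- runif(1, 2, 20)          # km
    tr <- straight_trip(v = v, n = 40)
    fpt <- first_passage_time(tr, r)
    interior <- which(!is.na(fpt))
    expect_gt(length(interior), 0)
    # within one time-step (1 h) of the closed form
    expect_true(all(abs(fpt[interior] - 2 * r / v) <= 1 + 1e-9))
  }
})

test_that("FPT flags undefined positions and bounds tiny radii", {
  tr <- straight_trip(v = 5, n = 10)
  # radius larger than any excursion: never crossed anywhere
  expect_true(all(is.na(first_passage_time(tr, 1000))))
  # consecutive positions 5 km apart, r = 1 km: FPT <= one step at interior points
  fpt <- first_passage_time(tr, 1)
  interior <- 2:9
  expect_true(all(fpt[interior] <= 1 + 1e-9))
})

test_that("ARS scale recovers a planted patch scale and averages across trips", {
  # composite trip: fast straight transit, then a slow walk confined to a
  # 10 km patch, then transit out
  mk_ars_trip <- function(seed) {
    set.seed(seed)
    out_x <- seq(0, 40, by = 8)                    # 8 km/h transit
    cx <- 45; n_in <- 60
    px <- numeric(n_in); py <- numeric(n_in)
    x <- cx; y <- 0
    for (i in seq_len(n_in)) {
      repeat {
        nx <- x + rnorm(1, 0, 1.5); ny <- y + rnorm(1, 0, 1.5)
        if ((nx - cx)^2 + ny^2 <= 10^2) break
      }
      x <- nx; y <- ny; px[i] <- x; py[i] <- y
    }
    back_x <- seq(48, 88, by = 8)
    fixes_df(seq_len(length(out_x) + n_in + length(back_x)) - 1,
             x = c(out_x, px, back_x), y = c(rep(0, length(out_x)), py,
                                             rep(0, length(back_x))))
  }
  radii <- seq(2, 40, by = 2)
  trips <- lapply(1:5, mk_ars_trip)
  res <- ars_scale(trips, radii)
  expect_s3_class(res, "ars_result")
  expect_lte(abs(res$scale - 10), 4 * 2)  # near the planted 10 km patch scale

  # two trips with known per-trip scales average; straight trips are excluded
  expect_equal(mean(res$per_trip, na.rm = TRUE), res$scale)
  expect_error(ars_scale(list(straight_trip(v = 5, n = 30)), radii), "fallback")
})

test_that("kernel UD conserves mass, honours the land mask, is deterministic", {
  mask <- open_sea_mask(60, cell = 1)
  pos <- data.frame(x_km = 30, y_km = 30)
  ud <- kernel_ud(pos, h = 4, mask)
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)
  expect_true(all(ud$density[mask$values] == 0))
  # mass within 2h of a lone mid-ocean point: 1 - exp(-2)
  g <- mask$grid
  ctr <- expand.grid(row = seq_len(g$n_rows), col = seq_len(g$n_cols))
  xy <- rc_to_xy(g, ctr$row, ctr$col)
  within <- matrix(sqrt((xy[, "x"] - 30)^2 + (xy[, "y"] - 30)^2) <= 8,
                   g$n_rows, g$n_cols)
  expect_equal(sum(ud$density[within]), 1 - exp(-2), tolerance = 0.02)

  set.seed(2)
  pos2 <- data.frame(x_km = runif(50, 10, 50), y_km = runif(50, 10, 50))
  expect_identical(kernel_ud(pos2, 3, mask)$density, kernel_ud(pos2, 3, mask)$density)

  # all mass on land is an explicit failure
  landy <- grid_raster(g, matrix(TRUE, 60, 60))
  landy$values[1, 1] <- FALSE
  expect_error(kernel_ud(pos, h = 0.5, landy), "land")
})

test_that("colony UD averages individuals and rejects single-individual colonies", {
  mask <- open_sea_mask(40)
  u1 <- kernel_ud(data.frame(x_km = 10, y_km = 10), 2, mask)
  u2 <- kernel_ud(data.frame(x_km = 30, y_km = 30), 2, mask)
  expect_error(colony_ud(list(u1)), "one individual")

  same <- colony_ud(list(u1, u1))
  expect_equal(same$density, u1$density, tolerance = 1e-12)

  both <- colony_ud(list(u1, u2))
  expect_equal(sum(both$density), 1, tolerance = 1e-9)
  # disjoint supports: half the mass on each
  near1 <- abs(row(both$density) - 10.5) < 8 & abs(col(both$density) - 10.5) < 8
  expect_equal(sum(both$density[near1]), 0.5, tolerance = 1e-3)
})

test_that("isopleth equals exhaustive minimal-subset search on small grids", {
  brute_min_cells <- function(dens, level) {
    ord <- order(dens, decreasing = TRUE)
    k <- which(cumsum(dens[ord]) >= level)[1]
    k
  }
  set.seed(6)
  for (rep in 1:25) {
    g <- grid_spec(0, 0, 4, 5, 1)
    land <- matrix(FALSE, 5, 4); land[1, 1] <- TRUE
    dens <- matrix(rexp(20), 5, 4); dens[1, 1] <- 0
    dens <- dens / sum(dens)
    ud <- structure(list(grid = g, density = dens, h = 1, n_positions = 1),
                    class = "ud")
    level <- runif(1, 0.2, 0.8)
    iso <- isopleth(ud, level)
    expect_gte(iso$enclosed_mass, level)
    # continuous densities: no ties, so cardinality matches the brute minimum
    expect_equal(nrow(iso$cells), brute_min_cells(as.vector(dens), level))
    # removing the lowest-density member drops the mass below the level
    dmin <- min(dens[iso$member])
    expect_lt(iso$enclosed_mass - dmin, level)
  }
})

test_that("uniform UD at level 0.5 returns all tied cells", {
  g <- grid_spec(0, 0, 10, 10, 1)
  dens <- matrix(1 / 100, 10, 10)
  ud <- structure(list(grid = g, density = dens, h = 1, n_positions = 1),
                  class = "ud")
  iso <- isopleth(ud, 0.5)
  expect_equal(nrow(iso$cells), 100)   # all cells tie at the cut
  expect_equal(iso$area, 100)
})

test_that("merged isopleths count memberships cell-wise", {
  g <- grid_spec(0, 0, 10, 10, 1)
  mk <- function(rows, cols) {
    member <- matrix(FALSE, 10, 10); member[rows, cols] <- TRUE
    structure(list(level = 0.5, cells = which(member, arr.ind = TRUE),
                   member = member, area = sum(member), grid = g),
              class = "isopleth_set")
  }
  a <- mk(1:3, 1:3); b <- mk(6:9, 6:9)
  disjoint <- merge_isopleths(list(a, b))
  expect_true(all(disjoint$values <= 1))
  triple <- merge_isopleths(list(a, a, a))
  expect_equal(max(triple$values), 3)
  expect_equal(sum(triple$values == 3), 9)

  set.seed(9)
  sets <- lapply(1:5, function(i) mk(sample(10, 4), sample(10, 4)))
  merged <- merge_isopleths(sets)
  brute <- Reduce(`+`, lapply(sets, function(s) s$member * 1L))
  expect_identical(merged$values, brute)

  g2 <- grid_spec(0, 0, 10, 10, 2)
  bad <- mk(1:2, 1:2); bad$grid <- g2
  expect_error(merge_isopleths(list(a, bad)), "grid")
})

test_that("identical trips give a flat curve and representativeness exactly 100", {
  mask <- open_sea_mask(40)
  tr <- straight_trip(v = 2, n = 10)
  tr$x_km <- tr$x_km + 10; tr$y_km <- tr$y_km + 20
  res <- representativeness(rep(list(tr), 6), h = 3, mask, n_iter = 50, seed = 4)
  expect_equal(res$value, 100)
  expect_true(res$representative)
  expect_equal(diff(range(res$curve$mean_area)), 0)
})

test_that("i.i.d. trips from one home range saturate the curve", {
  mask <- open_sea_mask(50)
  set.seed(11)
  trips <- lapply(1:25, function(i) {
    n <- 12
    fixes_df(0:(n - 1), x = rnorm(n, 25, 6), y = rnorm(n, 25, 6))
  })
  res <- representativeness(trips, h = 3, mask, n_iter = 200, seed = 12)
  expect_false(is.na(res$value))
  # non-decreasing means up to Monte-Carlo error: at most one decrease
  # exceeding twice the pairwise standard error
  mc_tol <- 2 * (res$curve$se[-1] + res$curve$se[-nrow(res$curve)])
  expect_lte(sum(diff(res$curve$mean_area) < -mc_tol), 1)
  expect_gte(res$value, 75)
})
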