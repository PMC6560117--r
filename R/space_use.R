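#' Utilization distributions, core areas and representativeness
#'
#' Space use is summarized by kernel utilization distributions (UDs) on the
#' shared analysis grid, masked so no density falls on land and normalized to
#' unit mass. The kernel bandwidth is the mean area-restricted-search (ARS)
#' scale derived from first-passage-time (FPT) analysis of the regularized
#' trips. Core areas are the 50% isopleth (smallest set of highest-density
#' cells holding half the mass); shared areas come from counting overlapping
#' isopleths; sampling adequacy is assessed by trip-subsampling saturation
#' curves fitted with an asymptotic regression.
#'
#' @name space_use
NULL

#' First passage time along a trip
#'
#' For each position, the time the trajectory takes to first cross a circle of
#' radius `radius` centred on that position, summing the forward and backward
#' crossing times. Crossing instants are linearly interpolated (in distance)
#' between the last position inside and the first outside the circle.
#' Positions whose circle is never exited in either direction get `NA`
#' (undefined, not zero).
#'
#' @param trip Regularized trip data.frame (`timestamp`, `x_km`, `y_km`).
#' @param radius Circle radius in km, > 0.
#' @return Numeric vector (hours) of per-position FPTs, `NA` where undefined.
#' @export
first_passage_time <- function(trip, radius) {
  stopifnot(radius > 0)
  n <- nrow(trip)
  t_h <- as.numeric(difftime(trip$timestamp, trip$timestamp[1], units = "hours"))
  x <- trip$x_km; y <- trip$y_km
  half_time <- function(i, dir) {
    js <- if (dir > 0) seq(i + 1L, n) else seq(i - 1L, 1L)
    if (i + dir < 1 || i + dir > n) return(NA_real_)
    d_prev <- 0; t_prev <- t_h[i]
    for (j in js) {
      d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
      if (d > radius) {
        frac <- (radius - d_prev) / (d - d_prev)
        tc <- t_prev + frac * (t_h[j] - t_prev)
        return(abs(tc - t_h[i]))
      }
      d_prev <- d; t_prev <- t_h[j]
    }
    NA_real_
  }
  vapply(seq_len(n), function(i) {
    f <- half_time(i, +1L); b <- half_time(i, -1L)
    if (is.na(f) || is.na(b)) NA_real_ else f + b
  }, numeric(1))
}

#' Area-restricted-search scale from FPT variance
#'
#' For each trip, computes `var(log FPT)` across positions at every radius of
#' the evaluation grid and takes the radius maximizing it; the group ARS scale
#' is the mean of per-trip scales. Trips whose variance profile has no
#' interior maximum (monotone, or maximum at a grid endpoint) are excluded and
#' counted. This scale is the kernel bandwidth `h` used for the group's UDs.
#'
#' @param trips List of regularized trip data.frames.
#' @param radii Radius grid in km (default 1 to 150 km).
#' @return List of class `ars_result`: `scale` (km), `per_trip` (per-trip
#'   scales, `NA` for excluded trips), `n_excluded`, `radii`.
#' @export
ars_scale <- function(trips, radii = seq(1, 150, by = 2)) {
  stopifnot(length(radii) >= 3, all(radii > 0))
  per_trip <- vapply(trips, function(tr) {
    vl <- vapply(radii, function(r) {
      f <- first_passage_time(tr, r)
      f <- f[!is.na(f) & f > 0]
      if (length(f) < 2) return(NA_real_)
      stats::var(log(f))
    }, numeric(1))
    ok <- which(!is.na(vl))
    if (length(ok) < 3) return(NA_real_)
    imax <- ok[which.max(vl[ok])]
    # require an interior maximum of the defined part of the profile
    if (imax == ok[1] || imax == ok[length(ok)]) return(NA_real_)
    radii[imax]
  }, numeric(1))
  if (all(is.na(per_trip))) {
    stop("no trip yielded an interior FPT-variance maximum; ",
         "supply a fallback bandwidth h explicitly")
  }
  structure(list(scale = mean(per_trip, na.rm = TRUE),
                 per_trip = per_trip,
                 n_excluded = sum(is.na(per_trip)),
                 radii = radii),
            class = "ars_result")
}

# unnormalized Gaussian kernel density stamped on the grid (separable form),
# truncated at `truncate` * h from each position
kernel_density_matrix <- function(x, y, h, grid, truncate = 5) {
  xs <- cell_x(grid); ys <- cell_y(grid)
  dens <- matrix(0, grid$n_rows, grid$n_cols)
  lim <- truncate * h
  for (p in seq_along(x)) {
    jc <- which(abs(xs - x[p]) <= lim)
    ir <- which(abs(ys - y[p]) <= lim)
    if (!length(jc) || !length(ir)) next
    kx <- exp(-((xs[jc] - x[p])^2) / (2 * h^2))
    ky <- exp(-((ys[ir] - y[p])^2) / (2 * h^2))
    dens[ir, jc] <- dens[ir, jc] + outer(ky, kx)
  }
  dens
}

#' Kernel utilization distribution
#'
#' Isotropic bivariate Gaussian kernel with standard deviation `h` in both
#' axes, evaluated at cell centres (truncated at `5 h`), zeroed on land and
#' renormalized to total mass 1.
#'
#' @param positions data.frame with `x_km`, `y_km` (or `x`, `y`).
#' @param h Bandwidth in km, > 0.
#' @param mask Land mask [grid_raster()].
#' @return Object of class `ud`: `grid`, `density` matrix (sums to 1, land
#'   exactly 0), `h`, `n_positions`.
#' @export
kernel_ud <- function(positions, h, mask) {
  stopifnot(h > 0)
  x <- positions[[if ("x_km" %in% names(positions)) "x_km" else "x"]]
  y <- positions[[if ("y_km" %in% names(positions)) "y_km" else "y"]]
  stopifnot(length(x) >= 1)
  dens <- kernel_density_matrix(x, y, h, mask$grid)
  dens[mask$values] <- 0
  total <- sum(dens)
  if (total <= 0) stop("all kernel mass fell on land; cannot form a UD")
  structure(list(grid = mask$grid, density = dens / total, h = h,
                 n_positions = length(x)),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("<ud> %d x %d grid, h = %g km, %d positions\n",
              x$grid$n_rows, x$grid$n_cols, x$h, x$n_positions))
  invisible(x)
}

#' Colony-level utilization distribution
#'
#' Cell-wise arithmetic mean of individual UDs, renormalized. Colonies with a
#' single tracked individual are excluded from colony-level estimates; calling
#' this with one UD raises that exclusion as an error.
#'
#' @param uds List of `ud` objects on a shared grid (>= 2).
#' @return A `ud`.
#' @export
colony_ud <- function(uds) {
  if (length(uds) < 2) {
    stop("colony excluded: only one individual tracked (need >= 2 UDs)")
  }
  g <- uds[[1]]$grid
  for (u in uds[-1]) check_same_grid(g, u$grid, "individual UDs")
  dens <- Reduce(`+`, lapply(uds, `[[`, "density")) / length(uds)
  dens <- dens / sum(dens)
  structure(list(grid = g, density = dens,
                 h = mean(vapply(uds, `[[`, numeric(1), "h")),
                 n_positions = sum(vapply(uds, `[[`, numeric(1), "n_positions"))),
            class = "ud")
}

# minimal highest-density prefix holding >= level of the mass, ties at the cut
# density all included; operates on a bare density vector, shared by
# isopleth() and the representativeness resampler
isopleth_members <- function(dens_vec, level) {
  total <- sum(dens_vec)
  ds <- sort(dens_vec[dens_vec > 0], decreasing = TRUE)
  cum <- cumsum(ds)
  k <- which(cum >= level * total)[1]
  cut <- ds[k]
  dens_vec >= cut & dens_vec > 0
}

#' Core-area isopleth of a UD
#'
#' Cells sorted by density descending; the shortest prefix whose cumulative
#' mass reaches `level` forms the isopleth, with all cells tied at the cut
#' density included (so a perfectly uniform UD returns every positive cell).
#'
#' @param ud A `ud`.
#' @param level Mass fraction in (0, 1); 0.5 is the conventional core area.
#' @return Object of class `isopleth_set`: `level`, `cells` (row/col matrix),
#'   `member` (logical matrix), `area` (km^2), `enclosed_mass`, `grid`.
#' @export
isopleth <- function(ud, level = 0.5) {
  stopifnot(level > 0, level < 1)
  member <- matrix(isopleth_members(as.vector(ud$density), level),
                   ud$grid$n_rows, ud$grid$n_cols)
  structure(list(level = level,
                 cells = which(member, arr.ind = TRUE),
                 member = member,
                 area = sum(member) * cell_area_km2(ud$grid),
                 enclosed_mass = sum(ud$density[member]),
                 grid = ud$grid),
            class = "isopleth_set")
}

#' Merge isopleth sets into an overlap-count raster
#'
#' @param isopleths List of `isopleth_set`s on one grid.
#' @return A [grid_raster()] whose integer values count how many input sets
#'   contain each cell.
#' @export
merge_isopleths <- function(isopleths) {
  stopifnot(length(isopleths) >= 1)
  g <- isopleths[[1]]$grid
  for (s in isopleths[-1]) check_same_grid(g, s$grid, "isopleth sets")
  counts <- Reduce(`+`, lapply(isopleths, function(s) s$member * 1L))
  grid_raster(g, counts)
}

#' Representativeness of a trip sample
#'
#' For each subsample size `n = 1..N`, draws `n_iter` random subsets of trips
#' (without replacement within a draw), pools their positions into a UD and
#' records the `level`-isopleth area; the mean-area curve is fitted with the
#' asymptotic regression `A(n) = A_inf (1 - exp(-n / c))` and the
#' representative value is `100 * observed_area / A_inf`, where the observed
#' area uses all `N` trips. Values of at least `rep_threshold` (default 75)
#' are flagged representative. When every subset yields the same area (e.g.
#' identical trips) the curve is constant and the value is exactly 100.
#'
#' @param trips List of regularized trip data.frames (>= 3).
#' @param h Kernel bandwidth (km).
#' @param mask Land mask [grid_raster()].
#' @param n_iter Random subsets per sample size (default 500).
#' @param seed Integer seed.
#' @param level Isopleth level (default 0.5).
#' @param rep_threshold Representativeness cutoff in percent (default 75).
#' @return Object of class `representativeness_result`: `curve` (data.frame
#'   `n`, `mean_area`, `ci_lo`, `ci_hi`, `se`; percentile CI and Monte-Carlo
#'   standard error of the mean over iterations), `asymptote_area`,
#'   `observed_area`, `value` (percent, `NA` when the regression fails),
#'   `representative`. The mean-area curve is non-decreasing up to
#'   Monte-Carlo error; use `se` to judge material inversions.
#' @export
representativeness <- function(trips, h, mask, n_iter = 500, seed = 1,
                               level = 0.5, rep_threshold = 75) {
  N <- length(trips)
  stopifnot(N >= 3, n_iter >= 1)
  grid <- mask$grid
  # per-trip unnormalized kernel stamps; a subset's UD is the masked,
  # renormalized sum of its trips' stamps
  M <- vapply(trips, function(tr) {
    d <- kernel_density_matrix(tr$x_km, tr$y_km, h, grid)
    d[mask$values] <- 0
    as.vector(d)
  }, numeric(grid$n_rows * grid$n_cols))
  if (any(colSums(M) <= 0)) stop("a trip's kernel mass fell entirely on land")
  a_cell <- cell_area_km2(grid)
  area_of <- function(dv) sum(isopleth_members(dv, level)) * a_cell
  observed_area <- area_of(rowSums(M))
  res <- with_seed(seed, {
    lapply(seq_len(N), function(n) {
      areas <- vapply(seq_len(n_iter), function(it) {
        idx <- sample.int(N, n)
        area_of(rowSums(M[, idx, drop = FALSE]))
      }, numeric(1))
      c(mean(areas), stats::quantile(areas, c(0.025, 0.975), names = FALSE),
        stats::sd(areas) / sqrt(n_iter))
    })
  })
  curve <- data.frame(n = seq_len(N),
                      mean_area = vapply(res, `[`, numeric(1), 1),
                      ci_lo = vapply(res, `[`, numeric(1), 2),
                      ci_hi = vapply(res, `[`, numeric(1), 3),
                      se = vapply(res, `[`, numeric(1), 4))
  if (diff(range(curve$mean_area)) <= 1e-9 * max(curve$mean_area)) {
    asym <- observed_area; value <- 100
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(mean_area ~ Ainf * (1 - exp(-n / cc)),
                        data = curve,
                        start = list(Ainf = max(curve$mean_area), cc = N / 3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("asymptotic regression failed to converge; value undefined")
      asym <- NA_real_; value <- NA_real_
    } else {
      asym <- stats::coef(fit)[["Ainf"]]
      value <- 100 * observed_area / asym
    }
  }
  structure(list(curve = curve, asymptote_area = asym,
                 observed_area = observed_area, value = value,
                 representative = !is.na(value) && value >= rep_threshold,
                 n_trips = N, n_iter = n_iter, level = level),
            class = "representativeness_result")
}
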