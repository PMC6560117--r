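#' Probability-of-use surfaces and multi-group maps
#'
#' Fitted case-control models are converted to probability-of-use rasters with
#' the offset-corrected logistic equation
#' `tau(x) = plogis(log((1 - P_a) P_u / P_a) + beta_0 + beta_1 x_1 + ... )`,
#' where `P_a` and `P_u` are the absence and presence proportions of the
#' case-control design (the offset undoes the artificial 3:1 class balance).
#' Surfaces are computed per colony — tracked or untracked — inside that
#' colony's accessible region, aggregated to species surfaces (optionally
#' weighted by colony size), and combined across groups into cumulative and
#' overlap maps.
#'
#' @name prediction_surfaces
NULL

#' Case-control offset and tau transform
#'
#' @param eta Linear predictor value(s).
#' @param P_a Proportion of absences; `P_a + P_u` must equal 1.
#' @param P_u Proportion of presences.
#' @return `tau_from_eta`: probability-of-use value(s) in (0, 1);
#'   `case_control_offset`: the scalar offset `log((1 - P_a) P_u / P_a)`.
#' @export
tau_from_eta <- function(eta, P_a, P_u) {
  stopifnot(abs(P_a + P_u - 1) < 1e-9)
  stats::plogis(eta + case_control_offset(P_a, P_u))
}

#' @rdname tau_from_eta
#' @export
case_control_offset <- function(P_a, P_u) log((1 - P_a) * P_u / P_a)

#' Predict the probability-of-use surface for a set of covariate values
#'
#' Raw covariate values are standardized with the model's stored parameters
#' (it is an error if those are absent), scored on the link scale, offset by
#' the case-control correction and passed through the logistic.
#'
#' @param model A `habitat_model` from [forward_stepwise()] (or any list with
#'   `fit`, `standardization`, `P_a`, `P_u`).
#' @param newdata data.frame of raw covariate values (unstandardized).
#' @param P_a,P_u Case-control proportions (default: the model's).
#' @return Numeric vector of tau values in (0, 1); `NA` where covariates are
#'   missing.
#' @export
tau_predict <- function(model, newdata, P_a = model$P_a, P_u = model$P_u) {
  std <- model$standardization
  if (is.null(std) || nrow(std) == 0) {
    stop("model carries no standardization parameters; ",
         "fit it on a table from standardize_covariates()")
  }
  need <- unique(c(model$terms, model$tensor))
  for (v in need) {
    p <- std[std$covariate == v, ]
    if (nrow(p) == 0) stop("no standardization parameters stored for '", v, "'")
    newdata[[paste0(v, "_std")]] <- (newdata[[v]] - p$mean) / p$sd
  }
  ok <- if (length(need)) stats::complete.cases(newdata[, paste0(need, "_std"), drop = FALSE])
        else rep(TRUE, nrow(newdata))
  eta <- rep(NA_real_, nrow(newdata))
  eta[ok] <- predict.cpf_gam(model$fit, newdata[ok, , drop = FALSE], type = "link")
  tau_from_eta(eta, P_a, P_u)
}

# mean dynamic layer over a date window
window_mean <- function(arr, dates, window) {
  use <- if (is.null(window)) seq_along(dates) else which(dates %in% window)
  if (!length(use)) stop("prediction window has no overlap with the dynamic layers")
  apply(arr[, , use, drop = FALSE], c(1, 2), mean)
}

#' Per-colony probability-of-use surfaces
#'
#' Builds one tau surface per colony in the registry — no tracking data
#' needed, so untracked colonies are covered — using that colony's least-cost
#' distance and competition rasters, static covariates, and dynamic covariates
#' averaged over the tracked date window. Cells beyond the colony's
#' accessible region are set to 0; land is `NA`.
#'
#' @param model A `habitat_model`.
#' @param colonies Colony registry data.frame (`id`, `x`, `y`,
#'   `population_size`).
#' @param env An `env_stack`.
#' @param mask Land mask [grid_raster()].
#' @param max_trip_distance Group maximum trip distance (km), setting the
#'   accessible radius.
#' @param accessibility_factor Multiplier on `max_trip_distance` (default 1.1).
#' @param window Optional Date vector: the tracking period over which dynamic
#'   covariates are averaged (default: all env dates).
#' @param graph Optional precomputed [sea_graph()].
#' @return Named list (by colony id) of [grid_raster()] tau surfaces, each
#'   with attributes `colony_id` and `radius_used`.
#' @export
colony_surfaces <- function(model, colonies, env, mask, max_trip_distance,
                            accessibility_factor = 1.1, window = NULL,
                            graph = NULL) {
  if (nrow(colonies) == 0) stop("colony registry is empty")
  if (is.null(graph)) graph <- sea_graph(mask)
  dists <- lapply(seq_len(nrow(colonies)), function(i) {
    distance_raster(colonies[i, ], mask, graph = graph)
  })
  names(dists) <- colonies$id
  dyn <- lapply(env$dynamic[c("sst", "sla", "eke")], window_mean,
                dates = env$dates, window = window)
  grid <- mask$grid
  out <- lapply(colonies$id, function(cid) {
    region <- accessible_region(colonies[colonies$id == cid, ], max_trip_distance,
                                mask, accessibility_factor, dist = dists[[cid]])
    comp <- null_density(colonies, dists, cid)
    idx <- region$cells
    newdata <- data.frame(
      distance = dists[[cid]]$values[idx],
      density = comp$values[idx],
      bathymetry = env$static$bathymetry[idx],
      slope = env$static$slope[idx],
      sst = dyn$sst[idx], sla = dyn$sla[idx], eke = dyn$eke[idx]
    )
    tau <- tau_predict(model, newdata)
    vals <- matrix(0, grid$n_rows, grid$n_cols)
    vals[mask$values] <- NA_real_
    vals[idx] <- tau
    r <- grid_raster(grid, vals)
    attr(r, "colony_id") <- cid
    attr(r, "radius_used") <- region$radius_used
    r
  })
  names(out) <- colonies$id
  out
}

#' Aggregate per-colony surfaces to a species surface
#'
#' Unweighted mode takes the cell-wise maximum over colonies (a cell is used
#' if animals from any colony use it); `"mean"` averages. Weighted mode
#' computes the colony-size weighted mean `sum(w_c tau_c) / sum(w_c)`.
#'
#' @param surfaces Named list of per-colony [grid_raster()]s.
#' @param weights Optional numeric vector of colony sizes (one per surface).
#' @param mode Unweighted aggregation: `"max"` (default) or `"mean"`.
#' @return A [grid_raster()].
#' @export
species_surface <- function(surfaces, weights = NULL, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(surfaces) >= 1)
  g <- surfaces[[1]]$grid
  for (s in surfaces[-1]) check_same_grid(g, s$grid, "colony surfaces")
  mats <- lapply(surfaces, `[[`, "values")
  if (!is.null(weights)) {
    if (length(weights) != length(surfaces)) {
      stop("weights length (", length(weights), ") does not match the ",
           length(surfaces), " surfaces")
    }
    acc <- Reduce(`+`, Map(function(m, w) m * w, mats, weights))
    out <- acc / sum(weights)
  } else if (mode == "max") {
    out <- Reduce(pmax, mats)
  } else {
    out <- Reduce(`+`, mats) / length(mats)
  }
  grid_raster(g, out)
}

standardize_surface <- function(values) {
  mx <- max(values, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) return(NULL)
  values / mx
}

#' Cumulative probability-of-occurrence raster across groups
#'
#' Each group surface is standardized by dividing by its maximum (so every
#' group contributes a peak of 1), then the standardized surfaces are summed
#' cell-wise. All-zero surfaces are excluded with a warning.
#'
#' @param surfaces List of group [grid_raster()]s on one grid.
#' @return A [grid_raster()]; `NA` where all inputs are `NA` (land).
#' @export
cumulative_surface <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  g <- surfaces[[1]]$grid
  for (s in surfaces[-1]) check_same_grid(g, s$grid, "group surfaces")
  std <- lapply(surfaces, function(s) standardize_surface(s$values))
  drop <- vapply(std, is.null, logical(1))
  if (any(drop)) warning(sum(drop), " all-zero surface(s) excluded from the cumulative map")
  std <- std[!drop]
  if (!length(std)) stop("no non-zero surfaces to combine")
  acc <- Reduce(function(a, b) {
    out <- ifelse(is.na(a) & is.na(b), NA_real_,
                  ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b))
    out
  }, std)
  grid_raster(g, acc)
}

#' Overlap count raster across groups
#'
#' Each group's surface is standardized by its maximum; cells at or above
#' `presence_threshold` count as predicted presence for that group, and the
#' output counts the groups predicted present in each cell. A companion
#' cumulative raster (summed standardized tau) is attached.
#'
#' @param surfaces List of group [grid_raster()]s on one grid.
#' @param presence_threshold Standardized-tau cutoff in (0, 1), default 0.5.
#' @return List of class `overlap_raster`: `count` ([grid_raster()], integer)
#'   and `cumulative` ([grid_raster()]).
#' @export
overlap_surface <- function(surfaces, presence_threshold = 0.5) {
  stopifnot(presence_threshold > 0, presence_threshold < 1)
  g <- surfaces[[1]]$grid
  for (s in surfaces[-1]) check_same_grid(g, s$grid, "group surfaces")
  std <- lapply(surfaces, function(s) standardize_surface(s$values))
  std <- std[!vapply(std, is.null, logical(1))]
  bins <- lapply(std, function(m) {
    b <- (m >= presence_threshold) * 1L
    b[is.na(m)] <- NA_integer_
    b
  })
  na_sum <- function(a, b) {
    ifelse(is.na(a) & is.na(b), NA_real_,
           ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b))
  }
  structure(list(count = grid_raster(g, Reduce(na_sum, bins)),
                 cumulative = grid_raster(g, Reduce(na_sum, std)),
                 presence_threshold = presence_threshold),
            class = "overlap_raster")
}
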