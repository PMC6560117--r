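#' Continuous-time correlated random walk smoother
#'
#' One-dimensional integrated Ornstein-Uhlenbeck (IOU) velocity model: the
#' velocity decays at rate `beta` (1/h) and is perturbed by white noise of
#' intensity `sigma` (km/h^1.5); position integrates velocity. Observations
#' are position plus independent Gaussian noise. Both coordinates are treated
#' as independent copies with shared parameters (isotropic model). The
#' transition and process-noise moments over a step `dt` are the exact IOU
#' expressions, so irregular sampling is handled without discretization error.
#'
#' @param t_obs Observation times (hours, strictly increasing).
#' @param z Observed coordinate values (km).
#' @param r_var Per-observation noise variance (km^2); 0 is allowed and makes
#'   the smoother exact at that observation.
#' @param t_out Times at which smoothed positions are wanted.
#' @param beta Velocity autocorrelation decay rate (1/h), > 0.
#' @param sigma Velocity noise intensity, > 0.
#' @return `ctcrw_smooth`: numeric vector of smoothed positions at `t_out`.
#' @export
ctcrw_smooth <- function(t_obs, z, r_var, t_out, beta, sigma) {
  kf <- ctcrw_kalman(t_obs, z, r_var, t_out, beta, sigma, want_smooth = TRUE)
  kf$smoothed_pos
}

# Exact IOU transition over dt: state (position, velocity)
iou_step <- function(dt, beta, sigma) {
  phi <- exp(-beta * dt)
  F <- matrix(c(1, 0, (1 - phi) / beta, phi), 2, 2)
  s2 <- sigma^2
  q_xx <- s2 / beta^2 * (dt - 2 * (1 - phi) / beta + (1 - phi^2) / (2 * beta))
  q_xv <- s2 / (2 * beta^2) * (1 - phi)^2
  q_vv <- s2 * (1 - phi^2) / (2 * beta)
  list(F = F, Q = matrix(c(q_xx, q_xv, q_xv, q_vv), 2, 2))
}

# Kalman filter (+ optional RTS smoother) on the union of obs and output times.
# Returns the marginal log-likelihood and smoothed positions at t_out.
ctcrw_kalman <- function(t_obs, z, r_var, t_out, beta, sigma, want_smooth = FALSE) {
  t_all <- sort(unique(c(t_obs, t_out)))
  obs_at <- match(t_obs, t_all)
  n <- length(t_all)
  zz <- rep(NA_real_, n); rr <- rep(NA_real_, n)
  zz[obs_at] <- z; rr[obs_at] <- r_var
  H <- c(1, 0)
  q_inf <- sigma^2 / (2 * beta)      # stationary velocity variance
  m <- c(zz[!is.na(zz)][1], 0)
  P <- diag(c(max(rr[!is.na(rr)][1], 1e-8) + 1, 4 * q_inf + 1))
  ll <- 0
  m_pred <- matrix(NA_real_, 2, n); P_pred <- array(NA_real_, c(2, 2, n))
  m_filt <- matrix(NA_real_, 2, n); P_filt <- array(NA_real_, c(2, 2, n))
  Fs <- array(NA_real_, c(2, 2, n))
  for (k in seq_len(n)) {
    if (k == 1) {
      mp <- m; Pp <- P; Fs[, , k] <- diag(2)
    } else {
      st <- iou_step(t_all[k] - t_all[k - 1], beta, sigma)
      mp <- st$F %*% m; Pp <- st$F %*% P %*% t(st$F) + st$Q
      Fs[, , k] <- st$F
    }
    m_pred[, k] <- mp; P_pred[, , k] <- Pp
    if (!is.na(zz[k])) {
      S <- drop(H %*% Pp %*% H) + rr[k]
      S <- max(S, 1e-12)
      innov <- zz[k] - drop(H %*% mp)
      K <- (Pp %*% H) / S
      m <- drop(mp + K * innov)
      P <- Pp - K %*% (H %*% Pp)
      ll <- ll + stats::dnorm(innov, 0, sqrt(S), log = TRUE)
    } else {
      m <- drop(mp); P <- Pp
    }
    m_filt[, k] <- m; P_filt[, , k] <- P
  }
  out <- list(loglik = ll)
  if (want_smooth) {
    ms <- m_filt; Ps <- P_filt
    if (n >= 2) {
      for (k in (n - 1):1) {
        Fk <- Fs[, , k + 1]
        Pp <- P_pred[, , k + 1]
        G <- P_filt[, , k] %*% t(Fk) %*% solve(Pp + diag(1e-12, 2))
        ms[, k] <- m_filt[, k] + G %*% (ms[, k + 1] - m_pred[, k + 1])
        Ps[, , k] <- P_filt[, , k] + G %*% (Ps[, , k + 1] - Pp) %*% t(G)
      }
    }
    out$smoothed_pos <- ms[1, match(t_out, t_all)]
  }
  out
}

#' @rdname ctcrw_smooth
#' @param x,y Observed coordinates (km) at `t_obs`.
#' @return `ctcrw_fit`: list with maximum-likelihood `beta`, `sigma`, and the
#'   joint log-likelihood.
#' @export
ctcrw_fit <- function(t_obs, x, y, r_var) {
  # moment-based starting values from crude velocities
  dt <- diff(t_obs); dt[dt <= 0] <- min(dt[dt > 0])
  v0 <- stats::sd(c(diff(x), diff(y)) / rep(dt, 2))
  if (!is.finite(v0) || v0 <= 0) v0 <- 1
  nll <- function(par) {
    beta <- exp(par[1]); sigma <- exp(par[2])
    if (!is.finite(beta) || beta > 1e3) return(1e10)
    -(ctcrw_kalman(t_obs, x, r_var, numeric(0), beta, sigma)$loglik +
        ctcrw_kalman(t_obs, y, r_var, numeric(0), beta, sigma)$loglik)
  }
  opt <- stats::optim(c(log(1), log(v0 * sqrt(2))), nll, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-6))
  list(beta = exp(opt$par[1]), sigma = exp(opt$par[2]), loglik = -opt$value)
}
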