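#' Gaussian belief over the log-concentration state
#'
#' The estimator carries a Gaussian posterior over `z = log x`, the
#' elementwise logarithm of the two-compartment concentration state.
#' Estimating the log-state keeps concentration estimates positive.
#'
#' @param mean Length-2 numeric mean of `z = (log x_e, log x_c)`.
#' @param cov 2x2 symmetric positive-definite covariance.
#' @return An object of class `bsp_belief`.
#' @export
belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  if (length(mean) != nrow(cov) || nrow(cov) != ncol(cov)) {
    stop("Dimension mismatch between `mean` and `cov`.", call. = FALSE)
  }
  if (any(!is.finite(mean)) || any(!is.finite(cov))) {
    stop("Belief mean and covariance must be finite.", call. = FALSE)
  }
  if (max(abs(cov - t(cov))) > 1e-12) {
    stop("`cov` must be symmetric.", call. = FALSE)
  }
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("`cov` must be positive definite.", call. = FALSE)
  }
  structure(list(mean = mean, cov = cov), class = "bsp_belief")
}

#' @export
print.bsp_belief <- function(x, ...) {
  cat("<bsp_belief> mean =", signif(x$mean, 5),
      " var =", signif(diag(x$cov), 5), "\n")
  invisible(x)
}

#' Estimator configuration
#'
#' @param process_noise 2x2 positive semidefinite process-noise covariance
#'   `W` of the log-state random disturbance (per step). The default
#'   `diag(1e-4, 1e-4)` encodes slow unmodeled drift of the kinetics.
#' @param init Optional `bsp_belief` used to initialize the filter. When
#'   `NULL`, the filter starts at the log-concentration matching the first
#'   interval's empirical suppression fraction (floored at 0.05) with unit
#'   variance on both components.
#' @param newton_tol Convergence tolerance of the damped Newton mode
#'   search in the update step.
#' @param newton_max_iter Iteration cap for the Newton search.
#' @param conc_floor Floor applied to predicted concentrations before
#'   taking logarithms (guards `log(0)` when the state washes out).
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(process_noise = diag(1e-4, 2), init = NULL,
                             newton_tol = 1e-10, newton_max_iter = 50L,
                             conc_floor = 1e-12) {
  W <- as.matrix(process_noise)
  if (max(abs(W - t(W))) > 1e-12 ||
      any(eigen(W, symmetric = TRUE, only.values = TRUE)$values < -1e-12)) {
    stop("`process_noise` must be symmetric positive semidefinite.",
         call. = FALSE)
  }
  if (newton_tol <= 0) stop("`newton_tol` must be positive.", call. = FALSE)
  structure(
    list(process_noise = W, init = init, newton_tol = newton_tol,
         newton_max_iter = as.integer(newton_max_iter),
         conc_floor = conc_floor),
    class = "estimator_config"
  )
}

#' Prediction step of the BSP estimator
#'
#' Propagates the Gaussian belief over the log-state through the
#' (nonlinear in log-space) plant map `z' = log(A exp(z) + B u)`,
#' linearizing about the posterior mean as in an extended Kalman filter:
#' the predicted mean is the exact image of the mean, and the covariance
#' is pushed through the Jacobian
#' `F = diag(1/x') A diag(x)` (with `x = exp(z)`) and inflated by the
#' process noise `W`.
#'
#' @param bel A `bsp_belief` (the previous posterior).
#' @param u Infusion rate applied over the step (mg/min, nonnegative).
#' @param dyn A `pk_dynamics` object.
#' @param cfg An [estimator_config()].
#' @return The predicted `bsp_belief`.
#' @export
predict_belief <- function(bel, u, dyn, cfg = estimator_config()) {
  if (!is.finite(u) || u < 0) {
    stop("Infusion rate `u` must be nonnegative.", call. = FALSE)
  }
  x <- exp(bel$mean)
  xp <- drop(dyn$A %*% x + dyn$B * u)
  xp <- pmax(xp, cfg$conc_floor)
  F <- (1 / xp) * dyn$A * rep(x, each = 2)  # diag(1/xp) %*% A %*% diag(x)
  cov <- F %*% bel$cov %*% t(F) + cfg$process_noise
  cov <- (cov + t(cov)) / 2
  structure(list(mean = log(xp), cov = cov), class = "bsp_belief")
}

# Log-likelihood of a binomial suppression count and its first two
# derivatives with respect to z1 = log(x_e), by the chain rule through
# p = g(exp(z1)). Probabilities are clamped away from {0, 1} for safety.
binom_loglik_z <- function(z1, n, N, tr) {
  x <- exp(z1)
  p <- pmin(pmax(tr$g(x), 1e-12), 1 - 1e-12)
  dp <- tr$dg(x) * x                      # dp/dz1
  d2p <- tr$d2g(x) * x^2 + tr$dg(x) * x   # d2p/dz1^2
  dl_dp <- n / p - (N - n) / (1 - p)
  d2l_dp2 <- -n / p^2 - (N - n) / (1 - p)^2
  list(
    ll = n * log(p) + (N - n) * log(1 - p),
    grad = dl_dp * dp,
    hess = d2l_dp2 * dp^2 + dl_dp * d2p
  )
}

#' Update step of the BSP estimator
#'
#' Combines the Gaussian prediction with the binomial observation
#' (`n` suppressed sub-samples out of `N`) through a Gaussian (Laplace)
#' approximation of the posterior
#' `N(z; prediction) x Binomial(n; N, p(exp(z1)))`: the posterior mean is
#' the mode of the log-posterior, found by damped Newton iterations with
#' analytic gradient and Hessian, and the posterior covariance is the
#' inverse of the negative log-posterior Hessian at the mode. A vacuous
#' observation (`N = 0`) returns the prediction unchanged; if the Newton
#' search fails to converge the prediction is kept with inflated
#' covariance and a warning.
#'
#' @param pred A `bsp_belief` (the prediction).
#' @param n Suppression count, integer in `[0, N]`.
#' @param N Sub-samples per interval (10 at the default 10 Hz binary
#'   sampling of 1-s intervals).
#' @param transform BSP transform family.
#' @param cfg An [estimator_config()].
#' @return The posterior `bsp_belief`.
#' @export
update_belief <- function(pred, n, N,
                          transform = c("hyperbolic_ratio", "tanh"),
                          cfg = estimator_config()) {
  transform <- match.arg(transform)
  if (N < 0 || n < 0 || n > N) stop("Need 0 <= n <= N.", call. = FALSE)
  if (N == 0) return(pred)
  tr <- bsp_transform(transform)
  d <- length(pred$mean)
  Pinv <- solve(pred$cov)
  m <- pred$mean

  neg_obj <- function(z) {
    dz <- z - m
    0.5 * drop(dz %*% Pinv %*% dz) - binom_loglik_z(z[1], n, N, tr)$ll
  }

  z <- m
  f <- neg_obj(z)
  converged <- FALSE
  for (it in seq_len(cfg$newton_max_iter)) {
    lik <- binom_loglik_z(z[1], n, N, tr)
    g <- drop(Pinv %*% (z - m)); g[1] <- g[1] - lik$grad
    H <- Pinv; H[1, 1] <- H[1, 1] - lik$hess
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # damped: halve until the objective decreases
    alpha <- 1
    repeat {
      z_new <- z + alpha * step
      f_new <- neg_obj(z_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    moved <- max(abs(alpha * step))
    z <- z + alpha * step
    f <- neg_obj(z)
    if (moved < cfg$newton_tol) { converged <- TRUE; break }
  }

  lik <- binom_loglik_z(z[1], n, N, tr)
  H <- Pinv; H[1, 1] <- H[1, 1] - lik$hess
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (!converged || any(ev <= 0)) {
    warning("Laplace update did not converge; keeping prediction with ",
            "inflated covariance.", call. = FALSE)
    return(structure(list(mean = m, cov = 2 * pred$cov),
                     class = "bsp_belief"))
  }
  cov <- solve(H)
  cov <- (cov + t(cov)) / 2
  structure(list(mean = z, cov = cov), class = "bsp_belief")
}

default_init_belief <- function(n1, N1, transform, d = 2) {
  p0 <- if (N1 > 0) max(n1 / N1, 0.05) else 0.05
  p0 <- min(p0, 0.95)
  z0 <- log(conc_from_bsp(p0, transform))
  structure(list(mean = rep(z0, d), cov = diag(1, d)), class = "bsp_belief")
}

#' Run the two-dimensional BSP filter over an observation stream
#'
#' Alternates [predict_belief()] and [update_belief()] over aligned
#' sequences of binomial suppression counts and infusion rates (one pair
#' per control interval). The BSP estimate at each step is the transform
#' of the exponentiated posterior mean of the effect-site log
#' concentration. The filter is causal: the output at step `t` depends
#' only on inputs up to `t`.
#'
#' @param obs A data frame with columns `n` and `N` (and optionally `t`),
#'   one row per interval, as produced by [aggregate_counts()].
#' @param u Numeric vector of infusion rates (mg/min), aligned with `obs`;
#'   `u[t]` is the rate applied over interval `t`.
#' @param dyn A `pk_dynamics` object.
#' @param cfg An [estimator_config()].
#' @return A tibble with one row per interval: `t`, `N`, `n`, `u`,
#'   `p_hat`, posterior means `z1_mean`, `z2_mean` and covariance entries
#'   `var11`, `var22`, `cov12`.
#' @examples
#' dyn <- discretize(pk_params(0.3, 1.2, 0.6, 1))
#' obs <- tibble::tibble(n = rbinom(60, 10, 0.4), N = 10)
#' filter_bsp(obs, u = rep(0.3, 60), dyn)
#' @export
filter_bsp <- function(obs, u, dyn, cfg = estimator_config()) {
  obs <- tibble::as_tibble(obs)
  if (nrow(obs) != length(u)) {
    stop("`obs` and `u` must have the same length.", call. = FALSE)
  }
  n_steps <- nrow(obs)
  bel <- cfg$init
  if (is.null(bel)) {
    bel <- default_init_belief(obs$n[1], obs$N[1], dyn$transform, d = 2)
  }
  out <- matrix(NA_real_, nrow = n_steps, ncol = 6)
  for (t in seq_len(n_steps)) {
    pred <- predict_belief(bel, u[t], dyn, cfg)
    bel <- update_belief(pred, obs$n[t], obs$N[t], dyn$transform, cfg)
    out[t, ] <- c(bel$mean, bel$cov[1, 1], bel$cov[2, 2], bel$cov[1, 2],
                  bsp_from_conc(exp(bel$mean[1]), dyn$transform))
  }
  tibble::tibble(
    t = if ("t" %in% names(obs)) obs$t else seq_len(n_steps),
    N = obs$N, n = obs$n, u = u,
    p_hat = out[, 6],
    z1_mean = out[, 1], z2_mean = out[, 2],
    var11 = out[, 3], var22 = out[, 4], cov12 = out[, 5]
  )
}

#' One-dimensional random-walk BSP filter
#'
#' The scalar special case of the estimator used for system
#' identification: the state is the scalar log effect-site concentration
#' with a first-order random-walk prior `z' = z + w`, which imposes a
#' smoothness constraint on the BSP trace without requiring a kinetic
#' model. The update step is the same binomial Laplace approximation as
#' in [update_belief()].
#'
#' @param obs Data frame with columns `n` and `N` (and optionally `t`).
#' @param process_noise Scalar random-walk variance per step (> 0).
#' @param init Optional scalar `bsp_belief` (length-1 mean, 1x1 cov).
#' @param transform BSP transform family.
#' @param cfg An [estimator_config()] (Newton settings are reused).
#' @return A tibble with columns `t`, `N`, `n`, `p_hat`, `z_mean`,
#'   `z_var`.
#' @export
filter_bsp_1d <- function(obs, process_noise = 1e-3, init = NULL,
                          transform = c("hyperbolic_ratio", "tanh"),
                          cfg = estimator_config()) {
  transform <- match.arg(transform)
  if (process_noise <= 0) {
    stop("`process_noise` must be positive.", call. = FALSE)
  }
  obs <- tibble::as_tibble(obs)
  n_steps <- nrow(obs)
  bel <- init
  if (is.null(bel)) {
    bel <- default_init_belief(obs$n[1], obs$N[1], transform, d = 1)
  }
  out <- matrix(NA_real_, nrow = n_steps, ncol = 3)
  for (t in seq_len(n_steps)) {
    pred <- structure(
      list(mean = bel$mean,
           cov = bel$cov + matrix(process_noise)),
      class = "bsp_belief"
    )
    bel <- update_belief(pred, obs$n[t], obs$N[t], transform, cfg)
    out[t, ] <- c(bel$mean, bel$cov[1, 1],
                  bsp_from_conc(exp(bel$mean[1]), transform))
  }
  tibble::tibble(
    t = if ("t" %in% names(obs)) obs$t else seq_len(n_steps),
    N = obs$N, n = obs$n,
    p_hat = out[, 3], z_mean = out[, 1], z_var = out[, 2]
  )
}
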