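#' Two-compartment pharmacokinetic model parameters
#'
#' The anesthetic is modeled with two compartments: a central (plasma)
#' compartment through which drug enters and is eliminated, and an
#' effect-site (brain) compartment that drives the EEG burst suppression
#' level. Drug flows in both directions between the compartments. All rate
#' constants are first-order and expressed per minute; concentrations are
#' dimensionless (their scale is absorbed into `b_in`, which is identified
#' from data rather than being a physical constant).
#'
#' @param k10 Elimination rate from the central compartment (1/min).
#' @param k12 Central-to-effect-site transfer rate (1/min).
#' @param k21 Effect-site-to-central transfer rate (1/min).
#' @param b_in Input gain mapping infusion (mg/min) to central-compartment
#'   concentration rate (concentration units/min per mg/min).
#' @param dt Discretization step in seconds (default 1 s, the control
#'   update interval).
#' @param transform BSP transform family (see [bsp_from_conc()]).
#' @return An object of class `pk_params`.
#' @seealso [discretize()], [fit_pk()]
#' @examples
#' pk <- pk_params(k10 = 0.3, k12 = 1.2, k21 = 0.6, b_in = 1)
#' @export
pk_params <- function(k10, k12, k21, b_in, dt = 1,
                      transform = c("hyperbolic_ratio", "tanh")) {
  transform <- match.arg(transform)
  vals <- c(k10 = k10, k12 = k12, k21 = k21, b_in = b_in, dt = dt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("All PK rates, `b_in` and `dt` must be finite and strictly positive.",
         call. = FALSE)
  }
  structure(
    list(k10 = k10, k12 = k12, k21 = k21, b_in = b_in, dt = dt,
         transform = transform),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params> two-compartment model\n")
  cat(sprintf("  k10 = %.4g  k12 = %.4g  k21 = %.4g  (1/min)\n",
              x$k10, x$k12, x$k21))
  cat(sprintf("  b_in = %.4g  dt = %g s  transform = %s\n",
              x$b_in, x$dt, x$transform))
  invisible(x)
}

# Continuous-time rate matrix on state order (x_e, x_c), standard
# mammillary form: drug enters/leaves via the central compartment.
pk_rate_matrix <- function(params) {
  matrix(c(-params$k21,  params$k12,
            params$k21, -(params$k10 + params$k12)),
         nrow = 2, byrow = TRUE)
}

#' Discretize the two-compartment model
#'
#' Exact zero-order-hold discretization of the continuous two-compartment
#' kinetics over one control interval `dt`: `A = expm(K dt)` and
#' `B = K^{-1} (A - I) B_c` where `K` is the continuous rate matrix on
#' state order `(x_e, x_c)` and `B_c = (0, b_in)'` injects the infusion
#' into the central compartment. The discrete state recursion is
#' `x[t+1] = A x[t] + B u[t]` with `u` in mg/min.
#'
#' @param params A [pk_params()] object.
#' @return An object of class `pk_dynamics` with elements `A` (2x2), `B`
#'   (2x1), `dt`, `transform` and the originating `params`.
#' @examples
#' dyn <- discretize(pk_params(0.3, 1.2, 0.6, 1))
#' dyn$A
#' @export
discretize <- function(params) {
  if (!inherits(params, "pk_params")) {
    stop("`params` must be a `pk_params` object.", call. = FALSE)
  }
  K <- pk_rate_matrix(params) * (params$dt / 60)  # rates are per minute
  A <- as.matrix(Matrix::expm(K))
  Bc <- c(0, params$b_in) * (params$dt / 60)
  B <- solve(K, (A - diag(2)) %*% Bc)
  structure(
    list(A = A, B = matrix(B, ncol = 1), dt = params$dt,
         transform = params$transform, params = params),
    class = "pk_dynamics"
  )
}

#' @export
print.pk_dynamics <- function(x, ...) {
  cat("<pk_dynamics> discrete two-compartment dynamics, dt =", x$dt, "s\n")
  cat("A =\n"); print(signif(x$A, 6))
  cat("B =\n"); print(signif(drop(x$B), 6))
  invisible(x)
}

#' Controllability of the discrete dynamics
#'
#' Rank of the controllability (Kalman) matrix `[B, AB, ...]`. For the
#' two-compartment model the pair is controllable (rank 2) whenever the
#' central and effect-site compartments exchange drug (`k12 > 0`), which
#' holds for all experimentally fitted models.
#'
#' @param dyn A `pk_dynamics` object (or any list with matrices `A`,
#'   `B`).
#' @param tol Singular-value tolerance for the rank decision.
#' @return A list with `rank` (integer) and `controllable` (logical,
#'   `TRUE` iff the rank equals the state dimension).
#' @export
controllability <- function(dyn, tol = 1e-10) {
  A <- as.matrix(dyn$A); B <- as.matrix(dyn$B)
  n <- nrow(A)
  blocks <- vector("list", n)
  blocks[[1]] <- B
  for (k in seq_len(n - 1)) blocks[[k + 1]] <- A %*% blocks[[k]]
  C <- do.call(cbind, blocks)
  sv <- svd(C)$d
  rank <- sum(sv > tol * max(sv[1], 1))
  list(rank = as.integer(rank), controllable = rank == n)
}

#' Advance the plant one step
#'
#' Applies the noiseless discrete dynamics `x' = A x + B u` for one control
#' interval. Nonnegative states and inputs yield a nonnegative next state
#' (the zero-order-hold of a compartment model is entrywise nonnegative).
#'
#' @param x Length-2 state `(x_e, x_c)`.
#' @param u Infusion rate in mg/min (scalar, nonnegative).
#' @param dyn A `pk_dynamics` object.
#' @return The next state as a length-2 numeric vector.
#' @export
plant_step <- function(x, u, dyn) {
  if (!is.finite(u) || u < 0) {
    stop("Infusion rate `u` must be nonnegative.", call. = FALSE)
  }
  drop(dyn$A %*% x + dyn$B * u)
}

#' Simulate the noiseless plant over an infusion profile
#'
#' Deterministic response of the discretized model to a sequence of
#' infusion rates, starting from `x0` (default drug-naive, the zero
#' state). `u[t]` acts over the step from `t-1` to `t`.
#'
#' @param dyn A `pk_dynamics` object.
#' @param u Numeric vector of infusion rates (mg/min), one per step.
#' @param x0 Initial state `(x_e, x_c)`.
#' @return A tibble with columns `t` (seconds at the end of each step),
#'   `u`, `x_e`, `x_c` and the implied BSP `p`.
#' @examples
#' dyn <- discretize(pk_params(0.3, 1.2, 0.6, 1))
#' simulate_plant(dyn, u = rep(1, 60))
#' @export
simulate_plant <- function(dyn, u, x0 = c(0, 0)) {
  n <- length(u)
  xs <- matrix(0, nrow = n, ncol = 2)
  x <- x0
  for (t in seq_len(n)) {
    x <- drop(dyn$A %*% x + dyn$B * u[t])
    xs[t, ] <- x
  }
  tibble::tibble(
    t = seq_len(n) * dyn$dt,
    u = u,
    x_e = xs[, 1],
    x_c = xs[, 2],
    p = bsp_from_conc(xs[, 1], dyn$transform)
  )
}

#' Equilibrium set-point for a target BSP
#'
#' For a nonzero target BSP the regulator's origin is shifted to the
#' corresponding equilibrium `(x*, u*)`: the effect-site concentration is
#' fixed at `conc_from_bsp(p_star)` and the two linear equilibrium
#' equations `(I - A) x* = B u*` are solved for the central concentration
#' and the constant infusion rate that hold the state there.
#'
#' @param dyn A `pk_dynamics` object.
#' @param p_star Target BSP in `(0, 1)`.
#' @return An object of class `bsp_setpoint`: list with `p_star`, `x_star`
#'   (named length-2 vector) and `u_star` (mg/min).
#' @examples
#' dyn <- discretize(pk_params(0.3, 1.2, 0.6, 1))
#' setpoint(dyn, 0.7)
#' @export
setpoint <- function(dyn, p_star) {
  if (!is.finite(p_star) || p_star <= 0 || p_star >= 1) {
    stop("`p_star` must lie in (0, 1).", call. = FALSE)
  }
  x_e <- conc_from_bsp(p_star, dyn$transform)
  M <- diag(2) - dyn$A
  # unknowns (x_c*, u*):  M[,2] x_c - B u = -M[,1] x_e
  S <- cbind(M[, 2], -dyn$B)
  if (abs(det(S)) < 1e-14) {
    stop("Degenerate model: equilibrium system is singular.", call. = FALSE)
  }
  sol <- solve(S, -M[, 1] * x_e)
  x_star <- c(x_e = x_e, x_c = sol[1])
  u_star <- sol[2]
  if (u_star < -1e-12) {
    stop("Infeasible target: equilibrium infusion rate is negative.",
         call. = FALSE)
  }
  res <- M %*% x_star - dyn$B * u_star
  stopifnot(max(abs(res)) < 1e-10 * max(1, sum(abs(x_star))))
  structure(
    list(p_star = p_star, x_star = x_star, u_star = max(u_star, 0)),
    class = "bsp_setpoint"
  )
}

#' @export
print.bsp_setpoint <- function(x, ...) {
  cat(sprintf("<bsp_setpoint> p* = %.3f  x* = (%.4g, %.4g)  u* = %.4g mg/min\n",
              x$p_star, x$x_star[1], x$x_star[2], x$u_star))
  invisible(x)
}
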