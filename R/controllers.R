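#' LQR controller configuration
#'
#' Quadratic cost weights and infusion-rate bounds for the regulator. The
#' default state weight `Q = diag(1, 0)` penalizes only the effect-site
#' concentration error — the quantity observable through the EEG and the
#' actual control target — and `R` trades off drug use against response
#' speed (smaller `R`, faster response).
#'
#' @param Q Positive semidefinite state-cost matrix, or a vector of
#'   diagonal weights (length 2, `(q_e, q_c)`, for the two-compartment
#'   model).
#' @param R Positive scalar input cost.
#' @param u_min,u_max Infusion-rate bounds in mg/min. The default
#'   `u_min = 0` enforces nonnegative infusion by clipping.
#' @return An object of class `lqr_config`.
#' @export
lqr_config <- function(Q = c(1, 0), R = 0.5, u_min = 0, u_max = Inf) {
  if (is.vector(Q) && is.null(dim(Q)) && length(Q) > 1) Q <- diag(Q)
  Q <- as.matrix(Q)
  if (max(abs(Q - t(Q))) > 1e-12 ||
      any(eigen(Q, symmetric = TRUE, only.values = TRUE)$values < -1e-12)) {
    stop("`Q` must be symmetric positive semidefinite.", call. = FALSE)
  }
  if (!is.finite(R) || R <= 0) stop("`R` must be positive.", call. = FALSE)
  if (u_min > u_max) stop("`u_min` must not exceed `u_max`.", call. = FALSE)
  structure(list(Q = Q, R = R, u_min = u_min, u_max = u_max),
            class = "lqr_config")
}

#' Solve the discrete algebraic Riccati equation
#'
#' Computes the steady-state Riccati solution `S` of
#' `S = Q + A'SA - A'SB (R + B'SB)^{-1} B'SA` by value iteration (the
#' backward finite-horizon recursion run to its fixed point), and the
#' corresponding steady-state feedback row `L = (R + B'SB)^{-1} B'SA`.
#' Requires a controllable pair; the closed-loop matrix `A - BL` is then
#' stable.
#'
#' @param dyn A `pk_dynamics` object (or any list with matrices `A`, `B`).
#' @param cfg An [lqr_config()].
#' @param tol Fixed-point convergence tolerance.
#' @param max_iter Iteration cap.
#' @return An object of class `lqr_gain` with `S` (2x2), `L` (1x2) and
#'   the closed-loop spectral radius `rho_cl`.
#' @examples
#' dyn <- discretize(pk_params(0.3, 1.2, 0.6, 1))
#' solve_dare(dyn, lqr_config())
#' @export
solve_dare <- function(dyn, cfg = lqr_config(), tol = 1e-12,
                       max_iter = 1e6L) {
  A <- dyn$A; B <- matrix(dyn$B, ncol = 1)
  ctrl <- controllability(dyn)
  if (!ctrl$controllable) {
    stop("Pair (A, B) is not controllable (controllability matrix rank ",
         ctrl$rank, " < ", nrow(as.matrix(dyn$A)), "); the steady-state ",
         "Riccati solution is not defined.", call. = FALSE)
  }
  Q <- cfg$Q; R <- cfg$R
  S <- Q
  for (it in seq_len(max_iter)) {
    SB <- S %*% B
    K <- drop(R + t(B) %*% SB)
    AtSB <- t(A) %*% SB
    S_new <- Q + t(A) %*% S %*% A - AtSB %*% t(AtSB) / K
    S_new <- (S_new + t(S_new)) / 2
    if (max(abs(S_new - S)) < tol * max(1, max(abs(S_new)))) {
      S <- S_new
      break
    }
    S <- S_new
    if (it == max_iter) {
      stop("Riccati value iteration did not converge.", call. = FALSE)
    }
  }
  L <- drop(t(B) %*% S %*% A) / drop(R + t(B) %*% S %*% B)
  L <- matrix(L, nrow = 1)
  rho <- max(Mod(eigen(A - B %*% L, only.values = TRUE)$values))
  structure(list(S = S, L = L, rho_cl = rho), class = "lqr_gain")
}

#' @export
print.lqr_gain <- function(x, ...) {
  cat("<lqr_gain> L =", signif(drop(x$L), 6),
      " closed-loop spectral radius =", signif(x$rho_cl, 6), "\n")
  invisible(x)
}

#' Bounded LQR infusion rate
#'
#' Certainty-equivalent steady-state LQR law with the origin shifted to
#' the target equilibrium: `u = u* - L (x_hat - x*)`, clipped to
#' `[u_min, u_max]` (with the default `u_min = 0`, a negative solution
#' becomes zero). The feedback acts on the concentration estimate
#' `x_hat = exp(z_hat)` supplied by the estimator.
#'
#' @param x_hat Length-2 concentration estimate `(x_e, x_c)`.
#' @param sp A [setpoint()].
#' @param gain An `lqr_gain` from [solve_dare()].
#' @param cfg The [lqr_config()] whose bounds apply.
#' @return Scalar infusion rate in mg/min.
#' @export
lqr_rate <- function(x_hat, sp, gain, cfg = lqr_config()) {
  u <- sp$u_star - drop(gain$L %*% (x_hat - sp$x_star))
  min(max(u, cfg$u_min), cfg$u_max)
}

#' Build a model-predictive controller
#'
#' Precomputes the condensed quadratic program for receding-horizon
#' control: stage cost `(x - x*)'Q(x - x*) + R (u - u*)^2` over a
#' `horizon`-step window, with the linear dynamics eliminated into
#' prediction matrices, box constraints on the infusion rate, optional
#' per-component state bounds, and an optional Riccati terminal cost.
#' Because the dynamics and weights are fixed, the Hessian and its
#' Cholesky factor are computed once; each control step only rebuilds the
#' linear term.
#'
#' @param dyn A `pk_dynamics` object.
#' @param horizon Prediction horizon T in steps (>= 1).
#' @param cfg An [lqr_config()] providing `Q`, `R` and the input bounds.
#' @param x_min,x_max Optional length-2 state bounds enforced at every
#'   step of the horizon.
#' @param terminal_cost If `TRUE`, the stage weight at the end of the
#'   horizon is replaced by the steady-state Riccati solution.
#' @return An object of class `mpc_controller`.
#' @export
mpc_controller <- function(dyn, horizon = 30L, cfg = lqr_config(),
                           x_min = NULL, x_max = NULL,
                           terminal_cost = FALSE) {
  T <- as.integer(horizon)
  if (T < 1) stop("`horizon` must be at least 1.", call. = FALSE)
  A <- dyn$A; B <- matrix(dyn$B, ncol = 1)
  # prediction: X = Phi x0 + Gamma U, X stacks x_1..x_T (2T), U is u_0..u_{T-1}
  Phi <- matrix(0, 2 * T, 2)
  Gamma <- matrix(0, 2 * T, T)
  Ak <- diag(2)
  for (k in seq_len(T)) {
    Ak <- A %*% Ak                       # A^k
    Phi[(2 * k - 1):(2 * k), ] <- Ak
  }
  for (k in seq_len(T)) {                # block (k, j) = A^(k-1-j) B
    for (j in seq_len(k)) {
      pw <- k - j
      Akj <- if (pw == 0) B else {
        M <- B
        for (i in seq_len(pw)) M <- A %*% M
        M
      }
      Gamma[(2 * k - 1):(2 * k), j] <- Akj
    }
  }
  QT <- if (terminal_cost) solve_dare(dyn, cfg)$S else cfg$Q
  Qbar <- matrix(0, 2 * T, 2 * T)
  for (k in seq_len(T)) {
    blk <- if (k == T) QT else cfg$Q
    Qbar[(2 * k - 1):(2 * k), (2 * k - 1):(2 * k)] <- blk
  }
  H <- t(Gamma) %*% Qbar %*% Gamma + diag(cfg$R, T)
  H <- (H + t(H)) / 2
  structure(
    list(dyn = dyn, T = T, cfg = cfg,
         x_min = x_min, x_max = x_max, terminal_cost = terminal_cost,
         Phi = Phi, Gamma = Gamma,
         GtQ = t(Gamma) %*% Qbar,        # T x 2T
         H = H, cholH = chol(H)),
    class = "mpc_controller"
  )
}

#' MPC infusion rate
#'
#' Solves the receding-horizon quadratic program from the current state
#' and a schedule of set-points over the horizon, and returns the first
#' control of the optimal sequence. When no input or state constraint is
#' active the solution is obtained directly from the precomputed Cholesky
#' factor; otherwise the box-/linearly-constrained program is solved with
#' an active-set QP.
#'
#' @param ctrl An [mpc_controller()].
#' @param x_hat Length-2 current concentration state (estimate or truth).
#' @param sps A single [setpoint()] (held over the horizon) or a list of
#'   `T` setpoints, one per horizon step.
#' @return Scalar infusion rate in mg/min (the first horizon control).
#' @export
mpc_rate <- function(ctrl, x_hat, sps) {
  T <- ctrl$T
  if (ctrl$cfg$u_min == ctrl$cfg$u_max) return(ctrl$cfg$u_min)
  if (inherits(sps, "bsp_setpoint")) sps <- rep(list(sps), T)
  if (length(sps) != T) {
    stop("`sps` must supply one setpoint per horizon step.", call. = FALSE)
  }
  xref <- unlist(lapply(sps, function(s) s$x_star), use.names = FALSE)
  uref <- vapply(sps, function(s) s$u_star, numeric(1))
  f <- drop(ctrl$GtQ %*% (ctrl$Phi %*% x_hat - xref)) - ctrl$cfg$R * uref
  # unconstrained minimizer via the cached Cholesky factor
  U <- backsolve(ctrl$cholH, backsolve(ctrl$cholH, -f, transpose = TRUE))
  lb <- rep(ctrl$cfg$u_min, T)
  ub <- rep(ctrl$cfg$u_max, T)
  need_qp <- any(U < lb - 1e-12) || any(U > ub + 1e-12)
  Ain <- NULL; bin <- NULL
  if (!is.null(ctrl$x_min) || !is.null(ctrl$x_max)) {
    px <- drop(ctrl$Phi %*% x_hat)
    if (!is.null(ctrl$x_max)) {
      Ain <- rbind(Ain, ctrl$Gamma)
      bin <- c(bin, rep(ctrl$x_max, T) - px)
    }
    if (!is.null(ctrl$x_min)) {
      Ain <- rbind(Ain, -ctrl$Gamma)
      bin <- c(bin, px - rep(ctrl$x_min, T))
    }
    if (any(Ain %*% U > bin + 1e-12)) need_qp <- TRUE
  }
  if (need_qp) {
    lb_qp <- if (all(is.finite(lb))) lb else NULL
    ub_qp <- if (all(is.finite(ub))) ub else NULL
    sol <- tryCatch(
      pracma::quadprog(ctrl$H, f, A = Ain, b = bin, lb = lb_qp, ub = ub_qp),
      error = function(e) {
        stop("MPC quadratic program failed: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (!is.null(sol$eflag) && sol$eflag < 0) {
      stop("MPC quadratic program is infeasible under the supplied ",
           "input/state bounds.", call. = FALSE)
    }
    U <- sol$xmin
  }
  min(max(U[1], ctrl$cfg$u_min), ctrl$cfg$u_max)
}
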