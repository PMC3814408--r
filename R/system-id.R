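#' Estimate a smoothed BSP trace from a bolus experiment
#'
#' First step of subject-specific system identification: a BSP trace is
#' recovered from the binary thresholded EEG of a preliminary bolus
#' experiment with the one-dimensional random-walk filter
#' ([filter_bsp_1d()]), which imposes a smoothness constraint without
#' assuming kinetics. The trace is then the fitting target for
#' [fit_pk()].
#'
#' @param obs Data frame with columns `n`, `N` (one row per interval).
#' @param process_noise Random-walk variance of the scalar filter.
#' @param ... Passed to [filter_bsp_1d()].
#' @return Numeric BSP trace, one value per observation interval.
#' @export
estimate_bsp_trace <- function(obs, process_noise = 1e-3, ...) {
  filter_bsp_1d(obs, process_noise = process_noise, ...)$p_hat
}

#' Fit two-compartment PK parameters to a BSP trace
#'
#' Second step of system identification: nonlinear least squares over the
#' model parameters `(k10, k12, k21, b_in)`, minimizing the sum of
#' squared errors between the target BSP trace and the BSP implied by the
#' deterministic discretized model response to the recorded infusion
#' profile from a drug-naive initial state `x(0) = 0`. Optimization uses
#' bounded Levenberg-Marquardt least squares with multiple seeded starts
#' (the landscape can hold local minima when the bolus excites the
#' compartments weakly); the best sum of squared errors is returned.
#'
#' Because only the effect site is observed (through the BSP), infusion
#' data identify just three functionals of the four parameters: the
#' input-to-effect-site gain `k12 * b_in` and the two kinetic modes
#' (`k10 + k12 + k21` and `k10 * k21`). The absolute concentration scale
#' is unobservable, so the four-parameter problem has a one-dimensional
#' ridge of prediction-equivalent solutions. Pass `fix = c(b_in = ...)`
#' (or fix any one rate) to pin the unit system; even then `k10` and
#' `k21` enter the transfer function only through their sum and product,
#' so the exact swap `k10 <-> k21` is prediction-equivalent. Among
#' starts whose final SSE ties, the fit closest to `init` is kept, so
#' supplying a physiologically plausible `init` selects the intended
#' branch.
#'
#' @param target Numeric BSP trace to fit (e.g. from
#'   [estimate_bsp_trace()]).
#' @param infusion Infusion profile in mg/min, aligned with `target`
#'   (`infusion[t]` acts over step `t`). A bolus of `D` mg delivered in
#'   one `dt`-second step enters as `u = D / dt * 60` for that step.
#' @param dt Discretization step in seconds.
#' @param init Optional [pk_params()] initial guess; also always used as
#'   one of the starts.
#' @param lower,upper Named bounds on `(k10, k12, k21, b_in)`; defaults
#'   are wide and positivity-enforcing.
#' @param n_starts Number of optimization starts (log-uniform within the
#'   bounds).
#' @param seed Seed for the start draws.
#' @param transform BSP transform family.
#' @param fix Optional named numeric vector of parameters held fixed
#'   during the fit (e.g. `c(b_in = 1)` to define the concentration
#'   unit); the remaining parameters are optimized.
#' @return An object of class `pk_fit`: list with `params`
#'   ([pk_params()]), `sse`, `converged`, `n_iter`, `fitted_trace`,
#'   `target`, `infusion`, `sse_trace` (per-iteration SSE of the winning
#'   start). Supports [generics::tidy()], [generics::glance()] and
#'   `autoplot()`.
#' @export
fit_pk <- function(target, infusion, dt = 1, init = NULL,
                   lower = c(k10 = 1e-4, k12 = 1e-4, k21 = 1e-4,
                             b_in = 1e-4),
                   upper = c(k10 = 10, k12 = 10, k21 = 10, b_in = 100),
                   n_starts = 8, seed = 1,
                   transform = c("hyperbolic_ratio", "tanh"),
                   fix = NULL) {
  transform <- match.arg(transform)
  if (length(target) != length(infusion)) {
    stop("`target` and `infusion` must be aligned.", call. = FALSE)
  }
  if (all(infusion == 0)) {
    stop("Infusion profile is identically zero; nothing to fit.",
         call. = FALSE)
  }
  par_names <- c("k10", "k12", "k21", "b_in")
  lower <- lower[par_names]; upper <- upper[par_names]
  if (!is.null(fix) && !all(names(fix) %in% par_names)) {
    stop("`fix` names must be among k10, k12, k21, b_in.", call. = FALSE)
  }
  free <- setdiff(par_names, names(fix))
  lo_f <- lower[free]; up_f <- upper[free]

  full_theta <- function(theta_free) {
    th <- stats::setNames(numeric(4), par_names)
    th[free] <- pmin(pmax(theta_free, lo_f), up_f)
    th[names(fix)] <- fix
    th
  }
  residual_fn <- function(theta_free) {
    th <- full_theta(theta_free)
    dyn <- discretize(pk_params(th[["k10"]], th[["k12"]], th[["k21"]],
                                th[["b_in"]], dt = dt,
                                transform = transform))
    target - simulate_plant(dyn, infusion)$p
  }

  starts <- list()
  if (!is.null(init)) {
    init_full <- c(k10 = init$k10, k12 = init$k12, k21 = init$k21,
                   b_in = init$b_in)
    starts[[1]] <- init_full[free]
  }
  rng <- local({
    set.seed(seed)
    n_rand <- n_starts - length(starts)
    lapply(seq_len(max(n_rand, 0)), function(i) {
      exp(stats::runif(length(free), log(lo_f), log(pmin(up_f, 5))))
    })
  })
  starts <- c(starts, rng)

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = lo_f, upper = up_f, fn = residual_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    dist_init <- if (length(starts) > 0 && !is.null(init)) {
      sum((log(pmax(full_theta(fit$par)[free], 1e-12)) -
             log(starts[[1]]))^2)
    } else 0
    tol_tie <- 1e-9 * max(best$sse %||% sse, 1e-12)
    better <- is.null(best) || sse < best$sse - tol_tie ||
      (sse < best$sse + tol_tie && dist_init < best$dist_init)
    if (better) {
      best <- list(fit = fit, sse = sse, start = s, dist_init = dist_init)
    }
  }
  if (is.null(best)) {
    stop("All optimization starts failed.", call. = FALSE)
  }
  th <- full_theta(best$fit$par)
  params <- pk_params(th[["k10"]], th[["k12"]], th[["k21"]], th[["b_in"]],
                      dt = dt, transform = transform)
  fitted_trace <- simulate_plant(discretize(params), infusion)$p
  converged <- best$fit$info %in% 1:4
  structure(
    list(params = params, sse = best$sse, converged = converged,
         n_iter = best$fit$niter, fitted_trace = fitted_trace,
         target = target, infusion = infusion,
         sse_trace = best$fit$rsstrace),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> SSE =", signif(x$sse, 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$params)
  invisible(x)
}

#' Tidy a PK fit
#'
#' @param x A `pk_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k10", "k12", "k21", "b_in"),
    estimate = c(x$params$k10, x$params$k12, x$params$k21, x$params$b_in)
  )
}

#' Glance at a PK fit
#'
#' @param x A `pk_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `sse`, `rmse`, `converged`, `n_iter`,
#'   `n_obs`.
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse,
    rmse = sqrt(x$sse / length(x$target)),
    converged = x$converged,
    n_iter = x$n_iter,
    n_obs = length(x$target)
  )
}
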