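test_that("the scalar Riccati equation has its closed-form golden-ratio root", {
  gain <- solve_dare(list(A = matrix(1), B = matrix(1)),
                     lqr_config(Q = matrix(1), R = 1))
  expect_equal(gain$S[1, 1], (1 + sqrt(5)) / 2, tolerance = 1e-9)
  expect_equal(gain$L[1, 1], (1 + sqrt(5)) / 2 / ((1 + sqrt(5)) / 2 + 1),
               tolerance = 1e-9)
})

test_that("Riccati solutions satisfy the fixed point and stabilize the loop", {
  set.seed(31)
  for (i in 1:20) {
    sys <- random_stable_system()
    gain <- solve_dare(sys$dyn, sys$cfg)
    expect_lt(dare_residual(gain$S, sys$dyn$A, sys$dyn$B, sys$cfg$Q,
                            sys$cfg$R), 1e-9)
    expect_lt(gain$rho_cl, 1)
    expect_lt(max(abs(gain$S - t(gain$S))), 1e-12)
  }
})

test_that("value iteration agrees with an explicit long backward recursion", {
  dyn <- discretize(reference_pk())
  cfg <- lqr_config()
  gain <- solve_dare(dyn, cfg)
  A <- dyn$A; B <- matrix(dyn$B, ncol = 1)
  S <- cfg$Q
  for (k in seq_len(1e4)) {
    SB <- S %*% B
    S <- cfg$Q + t(A) %*% S %*% A -
      (t(A) %*% SB) %*% t(t(A) %*% SB) / drop(cfg$R + t(B) %*% SB)
  }
  expect_lt(max(abs(S - gain$S)), 1e-8)
})

test_that("uncontrollable pairs are rejected with the failed rank", {
  expect_error(
    solve_dare(list(A = diag(c(0.9, 0.8)), B = matrix(0, 2, 1)),
               lqr_config()),
    "rank 0"
  )
})

test_that("the bounded LQR law is exact at equilibrium and clips elsewhere", {
  dyn <- discretize(reference_pk())
  cfg <- lqr_config()
  gain <- solve_dare(dyn, cfg)
  sp <- setpoint(dyn, 0.7)
  expect_equal(lqr_rate(sp$x_star, sp, gain, cfg), sp$u_star,
               tolerance = 1e-12)
  # far above target the raw solution is negative and clips to zero
  expect_identical(lqr_rate(10 * sp$x_star, sp, gain, cfg), 0)
  # deterministic
  x <- c(1.1, 0.9)
  expect_identical(lqr_rate(x, sp, gain, cfg), lqr_rate(x, sp, gain, cfg))
})

test_that("noiseless LQR closed loop settles on the target", {
  dyn <- discretize(reference_pk())
  cfg <- lqr_config()
  gain <- solve_dare(dyn, cfg)
  sp <- setpoint(dyn, 0.7)
  x <- c(0, 0); u <- 0
  for (t in seq_len(1800)) {
    x <- plant_step(x, u, dyn)
    u <- lqr_rate(x, sp, gain, cfg)
  }
  expect_lt(abs(bsp_from_conc(x[1]) - 0.7), 1e-3)
})

test_that("a one-step MPC matches the finite-horizon LQR closed form", {
  dyn <- discretize(reference_pk())
  cfg <- lqr_config(u_min = -Inf, u_max = Inf)
  sp <- setpoint(dyn, 0.6)
  ctrl <- mpc_controller(dyn, horizon = 1, cfg = cfg)
  x0 <- c(0.8, 1.4)
  A <- dyn$A; B <- matrix(dyn$B, ncol = 1)
  u_exact <- drop(
    solve(cfg$R + t(B) %*% cfg$Q %*% B,
          cfg$R * sp$u_star + t(B) %*% cfg$Q %*% (sp$x_star - A %*% x0))
  )
  expect_equal(mpc_rate(ctrl, x0, sp), u_exact, tolerance = 1e-10)
})

test_that("MPC respects input constraints, degenerate and active", {
  dyn <- discretize(reference_pk())
  sp <- setpoint(dyn, 0.9)
  # forced u = 0
  ctrl0 <- mpc_controller(dyn, horizon = 10,
                          cfg = lqr_config(u_min = 0, u_max = 0))
  expect_identical(mpc_rate(ctrl0, c(0.1, 0.1), sp), 0)
  # 2.4 mg/min cap active during an upward transition; bounded LQR clips
  # to the same value
  cfg_cap <- lqr_config(u_max = 2.4)
  gain <- solve_dare(dyn, cfg_cap)
  ctrl <- mpc_controller(dyn, horizon = 30, cfg = cfg_cap)
  sp0 <- setpoint(dyn, 0.2)
  x <- sp0$x_star; u_m <- sp0$u_star
  x_l <- x; u_l <- u_m
  mpc_us <- numeric(240); lqr_us <- numeric(240)
  for (t in seq_len(240)) {
    x <- plant_step(x, u_m, dyn)
    u_m <- mpc_rate(ctrl, x, sp)
    mpc_us[t] <- u_m
    x_l <- plant_step(x_l, u_l, dyn)
    u_l <- lqr_rate(x_l, sp, gain, cfg_cap)
    lqr_us[t] <- u_l
  }
  expect_true(all(mpc_us <= 2.4 + 1e-9))
  expect_true(all(mpc_us >= -1e-9))
  expect_gt(sum(abs(mpc_us - 2.4) < 1e-6), 10)  # the cap binds early on
  expect_equal(max(lqr_us), 2.4)
})

test_that("long-horizon MPC converges to the steady-state LQR law", {
  dyn <- discretize(reference_pk())
  cfg <- lqr_config(u_min = -Inf, u_max = Inf)
  gain <- solve_dare(dyn, cfg)
  sp <- setpoint(dyn, 0.7)
  set.seed(32)
  diffs <- sapply(c(5, 15, 45, 135), function(T) {
    ctrl <- mpc_controller(dyn, horizon = T, cfg = cfg)
    max(sapply(1:5, function(i) {
      x <- stats::runif(2, 0, 3)
      abs(mpc_rate(ctrl, x, sp) - lqr_rate(x, sp, gain, cfg))
    }))
  })
  expect_true(all(diff(diffs) <= 1e-12))
  expect_lt(diffs[4], 1e-3)
})

test_that("a Riccati terminal cost makes even a short-horizon MPC exact", {
  dyn <- discretize(reference_pk())
  cfg <- lqr_config(u_min = -Inf, u_max = Inf)
  gain <- solve_dare(dyn, cfg)
  sp <- setpoint(dyn, 0.5)
  ctrl <- mpc_controller(dyn, horizon = 3, cfg = cfg, terminal_cost = TRUE)
  x <- c(2, 0.4)
  expect_equal(mpc_rate(ctrl, x, sp), lqr_rate(x, sp, gain, cfg),
               tolerance = 1e-8)
})
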