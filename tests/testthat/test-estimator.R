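test_that("noise-free degenerate prediction reproduces the deterministic log-plant", {
  dyn <- discretize(reference_pk())
  cfg <- estimator_config(process_noise = matrix(0, 2, 2))
  bel <- make_belief(log(c(1.2, 0.7)), matrix(0, 2, 2))
  pred <- predict_belief(bel, 0.4, dyn, cfg)
  expect_equal(pred$mean,
               log(drop(dyn$A %*% c(1.2, 0.7) + dyn$B * 0.4)),
               tolerance = 1e-14)
  expect_equal(max(abs(pred$cov)), 0)
})

test_that("prediction Jacobian matches central finite differences", {
  set.seed(21)
  for (i in 1:5) {
    dyn <- discretize(random_pk())
    z <- stats::rnorm(2, 0, 1)
    u <- stats::runif(1, 0, 2)
    cfg <- estimator_config(process_noise = matrix(0, 2, 2))
    # implied Jacobian: propagate identity covariance with W = 0
    pred <- predict_belief(make_belief(z, diag(1, 2)), u, dyn, cfg)
    h <- 1e-6
    Ffd <- matrix(0, 2, 2)
    for (j in 1:2) {
      zp <- z; zm <- z
      zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
      fp <- log(drop(dyn$A %*% exp(zp) + dyn$B * u))
      fm <- log(drop(dyn$A %*% exp(zm) + dyn$B * u))
      Ffd[, j] <- (fp - fm) / (2 * h)
    }
    expect_lt(max(abs(pred$cov - Ffd %*% t(Ffd))), 1e-6)
  }
})

test_that("prediction moments match a Monte-Carlo propagation oracle", {
  set.seed(22)
  dyn <- discretize(reference_pk())
  z0 <- log(c(2, 1))
  cov0 <- diag(1e-6, 2)
  u <- 0.5
  cfg <- estimator_config(process_noise = matrix(0, 2, 2))
  pred <- predict_belief(make_belief(z0, cov0), u, dyn, cfg)
  n_mc <- 1e5
  Z <- cbind(stats::rnorm(n_mc, z0[1], sqrt(cov0[1, 1])),
             stats::rnorm(n_mc, z0[2], sqrt(cov0[2, 2])))
  X <- exp(Z) %*% t(dyn$A) + matrix(drop(dyn$B) * u, n_mc, 2,
                                    byrow = TRUE)
  Zp <- log(X)
  se_mean <- apply(Zp, 2, stats::sd) / sqrt(n_mc)
  expect_true(all(abs(colMeans(Zp) - pred$mean) < 3 * se_mean))
  emp_cov <- stats::cov(Zp)
  se_var <- sqrt(2 / n_mc) * diag(emp_cov)
  expect_true(all(abs(diag(emp_cov) - diag(pred$cov)) < 4 * se_var))
})

test_that("a vacuous observation leaves the prediction untouched", {
  pred <- make_belief(c(0, 0), diag(0.5, 2))
  post <- update_belief(pred, 0, 0)
  expect_identical(post$mean, pred$mean)
  expect_identical(post$cov, pred$cov)
})

test_that("Laplace update mode matches the dense-grid posterior oracle", {
  set.seed(23)
  for (i in 1:15) {
    m <- c(stats::rnorm(1, 0, 1.5), stats::rnorm(1, 0, 1.5))
    L <- matrix(stats::rnorm(4, sd = 0.5), 2)
    P <- crossprod(L) + diag(0.05, 2)
    N <- sample(c(1, 10, 20), 1)
    n <- sample(0:N, 1)
    pred <- make_belief(m, P)
    post <- update_belief(pred, n, N)
    mode <- grid_posterior_mode(pred, n, N)
    expect_lt(max(abs(post$mean - mode)), 1e-3)
  }
})

test_that("the update moves the BSP estimate in the direction of the evidence", {
  # prediction centred at BSP 0.5 (z1 = log 1 = 0)
  pred <- make_belief(c(0, 0), diag(0.3, 2))
  up <- update_belief(pred, 10, 10)
  down <- update_belief(pred, 0, 10)
  expect_gt(bsp_from_conc(exp(up$mean[1])), 0.5)
  expect_lt(bsp_from_conc(exp(down$mean[1])), 0.5)
})

test_that("posterior covariance stays symmetric positive definite and shrinks with more data", {
  set.seed(24)
  for (i in 1:20) {
    m <- stats::rnorm(2, 0, 1)
    L <- matrix(stats::rnorm(4, sd = 0.4), 2)
    P <- crossprod(L) + diag(0.05, 2)
    pred <- make_belief(m, P)
    post10 <- update_belief(pred, 5, 10)
    post1 <- update_belief(pred, 0, 1)
    for (post in list(post10, post1)) {
      expect_lt(max(abs(post$cov - t(post$cov))), 1e-12)
      expect_true(all(eigen(post$cov, symmetric = TRUE,
                            only.values = TRUE)$values > 0))
    }
    # information monotonicity in the binomial sample size
    expect_lte(post10$cov[1, 1], post1$cov[1, 1] + 1e-12)
  }
})

test_that("the 2-D filter tracks model-matched simulated data and is causal", {
  set.seed(25)
  pk <- reference_pk()
  dyn <- discretize(pk)
  n_steps <- 600
  u <- rep(c(2, 0.5, 1.2), each = 200)
  x <- c(0.5, 0.5)
  p_true <- numeric(n_steps)
  n_obs <- integer(n_steps)
  for (t in seq_len(n_steps)) {
    x <- plant_step(x, u[t], dyn)
    p_true[t] <- bsp_from_conc(x[1])
    n_obs[t] <- stats::rbinom(1, 10, p_true[t])
  }
  obs <- tibble::tibble(n = n_obs, N = 10)
  est <- filter_bsp(obs, u, dyn)
  expect_lt(mean(abs(est$p_hat - p_true)), 0.05)
  # causality: truncating the stream leaves earlier outputs bit-identical
  est_trunc <- filter_bsp(obs[1:200, ], u[1:200], dyn)
  expect_identical(est$p_hat[1:200], est_trunc$p_hat)
  # length mismatch is an input error
  expect_error(filter_bsp(obs, u[-1], dyn), "same length")
})

test_that("with no suppression evidence and no drug the estimate washes out", {
  dyn <- discretize(reference_pk())
  obs <- tibble::tibble(n = rep(0L, 300), N = 10L)
  est <- filter_bsp(obs, rep(0, 300), dyn,
                    estimator_config(init = make_belief(log(c(2, 1)),
                                                        diag(0.5, 2))))
  expect_lt(est$p_hat[300], 0.05)
  expect_lt(est$p_hat[300], est$p_hat[1])
})

test_that("the 1-D random-walk filter matches its grid oracle and the data", {
  set.seed(26)
  # per-step agreement with a dense scalar grid
  for (i in 1:10) {
    m <- stats::rnorm(1, 0, 1)
    v <- stats::runif(1, 0.05, 1)
    N <- 10; n <- sample(0:N, 1)
    pred <- make_belief(m, matrix(v))
    post <- update_belief(pred, n, N)
    mode <- grid_posterior_mode(pred, n, N)
    expect_lt(abs(post$mean - mode), 1e-3)
  }
  # long constant-p stream converges near p
  set.seed(27)
  obs <- tibble::tibble(n = stats::rbinom(600, 10, 0.7), N = 10)
  est <- filter_bsp_1d(obs, process_noise = 1e-3)
  expect_lt(abs(est$p_hat[600] - 0.7), 0.05)
  # vanishing process noise: estimate approaches the pooled fraction
  est0 <- filter_bsp_1d(obs, process_noise = 1e-8)
  expect_lt(abs(est0$p_hat[600] - mean(obs$n) / 10), 0.02)
  expect_error(filter_bsp_1d(obs, process_noise = 0), "positive")
})
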