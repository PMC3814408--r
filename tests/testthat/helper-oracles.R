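# Independent oracles and small generators shared across the suite.

# Fine-step forward-Euler discretization of the continuous two-compartment
# kinetics: an independent check on the matrix-exponential route.
euler_discretize <- function(params, n_sub = 1e5) {
  K <- matrix(c(-params$k21, params$k12,
                params$k21, -(params$k10 + params$k12)),
              nrow = 2, byrow = TRUE)
  Bc <- c(0, params$b_in)
  h <- (params$dt / 60) / n_sub
  A <- diag(2)
  B <- c(0, 0)
  for (i in seq_len(n_sub)) {
    B <- B + h * (K %*% B + Bc)
    A <- A + h * K %*% A
  }
  list(A = A, B = matrix(B, ncol = 1))
}

# Dense-grid mode of the exact unnormalized posterior
# N(z; pred) * Binomial(n; N, p(exp(z1))), refined around the argmax.
# Independent of the package's Newton search.
grid_posterior_mode <- function(pred, n, N,
                                transform = "hyperbolic_ratio",
                                n_grid = 201, n_refine = 3) {
  g <- if (transform == "hyperbolic_ratio") {
    function(x) x / (1 + x)
  } else {
    function(x) tanh(x)
  }
  Pinv <- solve(pred$cov)
  m <- pred$mean
  d <- length(m)
  logpost <- function(Z) {
    # Z: matrix with d columns
    dz <- sweep(Z, 2, m)
    quad <- rowSums((dz %*% Pinv) * dz)
    p <- pmin(pmax(g(exp(Z[, 1])), 1e-300), 1 - 1e-16)
    -0.5 * quad + n * log(p) + (N - n) * log(1 - p)
  }
  sds <- sqrt(diag(pred$cov))
  centers <- m
  spans <- 5 * sds
  for (r in seq_len(n_refine)) {
    axes <- lapply(seq_len(d), function(i) {
      seq(centers[i] - spans[i], centers[i] + spans[i], length.out = n_grid)
    })
    Z <- as.matrix(expand.grid(axes))
    lp <- logpost(Z)
    centers <- as.numeric(Z[which.max(lp), ])
    spans <- spans * (3 / n_grid)   # zoom around the incumbent argmax
  }
  centers
}

# Random stable discrete 2-D systems for Riccati property sweeps.
random_stable_system <- function() {
  A <- matrix(stats::rnorm(4), 2)
  A <- A * (stats::runif(1, 0.3, 0.95) / max(Mod(eigen(A)$values)))
  B <- matrix(stats::rnorm(2), ncol = 1)
  M <- matrix(stats::rnorm(4), 2)
  list(dyn = list(A = A, B = B),
       cfg = lqr_config(Q = crossprod(M), R = stats::runif(1, 0.1, 10),
                        u_min = -Inf, u_max = Inf))
}

# Random valid PK parameter sets.
random_pk <- function() {
  pk_params(
    k10 = stats::runif(1, 0.2, 2),
    k12 = stats::runif(1, 0.2, 2),
    k21 = stats::runif(1, 0.2, 2),
    b_in = stats::runif(1, 0.5, 5),
    dt = 1
  )
}

# DARE fixed-point residual, written out independently of solve_dare.
dare_residual <- function(S, A, B, Q, R) {
  SB <- S %*% B
  S2 <- Q + t(A) %*% S %*% A -
    (t(A) %*% SB) %*% t(t(A) %*% SB) / drop(R + t(B) %*% SB)
  max(abs(S - S2))
}

make_belief <- function(mean, cov) {
  structure(list(mean = mean, cov = as.matrix(cov)), class = "bsp_belief")
}
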