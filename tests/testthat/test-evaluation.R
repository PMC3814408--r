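test_that("steady-state masking removes transition and acquisition windows", {
  dt <- 1
  times <- seq(dt, 2700, by = dt)
  # one upward and one downward transition
  sched <- target_schedule(c(0, 900, 1800), c(0.4, 0.9, 0.7))
  mask <- steady_state_mask(times, sched)
  expect_identical(sum(!mask), as.integer(300 + 300 + 420))
  # up-window after the upward breakpoint, down-window after the downward
  expect_false(any(mask[times > 900 & times <= 1200]))
  expect_true(all(mask[times > 1200 & times <= 1800]))
  expect_false(any(mask[times > 1800 & times <= 2220]))
  # single level: everything after the initial window is retained
  m1 <- steady_state_mask(times, target_schedule(0, 0.7))
  expect_identical(sum(!m1), 300L)
  # a time-reversed schedule mirrors the mask up to window widths
  sched_rev <- target_schedule(c(0, 900, 1800), c(0.7, 0.9, 0.4))
  m_rev <- steady_state_mask(times, sched_rev)
  expect_false(any(m_rev[times > 900 & times <= 1200]))   # up: 300 s
  expect_false(any(m_rev[times > 1800 & times <= 2220]))  # down: 420 s
})

test_that("performance errors use the documented sign and scale conventions", {
  pe <- performance_error(c(0.5, 0.52, 0.48), c(0.5, 0.5, 0.5))
  expect_equal(pe$deviation, c(0, 0.02, -0.02))
  expect_equal(pe$percent, c(0, 4, -4))
  expect_error(performance_error(0.5, 0), "positive")
})

test_that("steady-state metrics reproduce hand-computed medians", {
  d <- tibble::tibble(
    t = 1:3,
    p_hat = 0.5 + c(0.01, -0.02, 0.03),
    target = 0.5
  )
  m <- steady_state_metrics(d, target_schedule(0, 0.5),
                            mask = rep(TRUE, 3))
  expect_setequal(m$level, c("mid", "all"))
  all_row <- m[m$level == "all", ]
  expect_equal(all_row$mad, 0.02)
  expect_equal(all_row$mdpe, 2)
  expect_equal(all_row$mdape, 4)
  expect_identical(all_row$n_samples, 3L)
})

test_that("cross-experiment pooling reproduces the published medians", {
  agg <- aggregate_metrics(invivo_session_metrics())
  # published medians are printed to two decimals: agree to half an ULP
  half_ulp <- 0.005 + 1e-12
  expect_lt(abs(agg$mdape[agg$level == "all"] - 3.61), half_ulp)
  expect_lt(abs(agg$mdpe[agg$level == "all"] - (-1.44)), half_ulp)
  expect_lt(abs(agg$mad[agg$level == "all"] - 0.022), 5e-4)
  expect_lt(abs(agg$mdape[agg$level == "high"] - 2.78), half_ulp)
  expect_lt(abs(agg$mdape[agg$level == "low"] - 7.32), half_ulp)
  expect_lt(abs(agg$mdape[agg$level == "mid"] - 3.02), half_ulp)
})

test_that("transition timing handles ramps, immediate arrival and failure", {
  # linear ramp 0.4 -> 0.9 at 0.005/s starting at the breakpoint t = 50
  times <- 0:300
  p_hat <- ifelse(times < 50, 0.4, pmin(0.4 + 0.005 * (times - 50), 0.9))
  sched <- target_schedule(c(0, 50), c(0.4, 0.9))
  tm <- transition_metrics(tibble::tibble(t = times, p_hat = p_hat), sched)
  expect_identical(tm$direction, "up")
  expect_equal(tm$time_s, 90)  # first crossing of 0.85
  expect_equal(tm$rate_per_min, 0.5 / 1.5, tolerance = 1e-12)
  expect_true(tm$reached)
  # mirrored downward ramp gives the same time
  p_dn <- ifelse(times < 50, 0.9, pmax(0.9 - 0.005 * (times - 50), 0.4))
  sched_dn <- target_schedule(c(0, 50), c(0.9, 0.4))
  tm_dn <- transition_metrics(tibble::tibble(t = times, p_hat = p_dn),
                              sched_dn)
  expect_identical(tm_dn$direction, "down")
  expect_equal(tm_dn$time_s, 90)
  # already within the band: time zero
  tm0 <- transition_metrics(
    tibble::tibble(t = times, p_hat = rep(0.88, length(times))), sched)
  expect_equal(tm0$time_s, 0)
  # never reaches the band
  tmna <- transition_metrics(
    tibble::tibble(t = times, p_hat = rep(0.4, length(times))), sched)
  expect_false(tmna$reached)
  expect_true(is.na(tmna$time_s))
})

test_that("per-level reliability thresholds the 95th percentile", {
  # perfect control
  r0 <- level_reliability(rep(0, 50))
  expect_true(r0$reliable && r0$highly_reliable)
  # 6 of 100 samples at 0.2 push the 95th percentile to 0.2
  r1 <- level_reliability(c(rep(0.01, 94), rep(0.2, 6)))
  expect_gte(r1$p95, 0.15)
  expect_false(r1$reliable)
  # evenly spread errors on [0, 0.12]: p95 = 0.114
  r2 <- level_reliability(seq(0, 0.12, length.out = 100))
  expect_equal(r2$p95, 0.114, tolerance = 1e-12)
  expect_true(r2$reliable)
  expect_false(r2$highly_reliable)
  # too few samples: verdict undetermined
  r3 <- level_reliability(rep(0.01, 5))
  expect_true(is.na(r3$reliable))
  # quantile monotonicity: appending a sample above the current p95
  # never lowers it
  set.seed(61)
  for (i in 1:20) {
    x <- stats::runif(50, 0, 0.2)
    p95 <- stats::quantile(x, 0.95, names = FALSE)
    p95_new <- stats::quantile(c(x, p95 + stats::runif(1, 0, 0.1)),
                               0.95, names = FALSE)
    expect_gte(p95_new, p95)
  }
})

test_that("the Beta posterior summary matches quadrature and closed forms", {
  # closed forms
  r20 <- overall_reliability(20, 20)
  expect_equal(r20$mode, 1)
  expect_equal(r20$q05, 0.05^(1 / 21), tolerance = 1e-12)
  r01 <- overall_reliability(0, 1)
  expect_equal(r01$mode, 0)
  expect_equal(r01$q05, 1 - 0.95^(1 / 2), tolerance = 1e-12)
  expect_true(r01$reliable_overall)
  # quadrature oracle for the posterior 5th percentile
  for (kn in list(c(17, 20), c(3, 8), c(0, 5))) {
    k <- kn[1]; n <- kn[2]
    r <- overall_reliability(k, n)
    dens <- function(x) x^k * (1 - x)^(n - k)
    Z <- stats::integrate(dens, 0, 1, rel.tol = 1e-12)$value
    mass_below <- stats::integrate(dens, 0, r$q05,
                                   rel.tol = 1e-12)$value / Z
    expect_equal(mass_below, 0.05, tolerance = 1e-6)
  }
  expect_error(overall_reliability(5, 4), "k <= n")
})
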