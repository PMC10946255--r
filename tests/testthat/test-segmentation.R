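test_that("total relaxation time matches the closed form for pure decay", {
  tt <- c(0, 10^seq(-3, 1.2, length.out = 600))
  # chi = e^{-t}: relative deviation falls below 1e-3 at t = ln(1000)
  traj <- traj_from_fun(tt, a = function(t) 1 + exp(-t),
                        b = function(t) 2 + 0.5 * exp(-t))
  Tinf <- total_relaxation_time(traj, eps_inf = 1e-3,
                                x_ss = c(a = 1, b = 2))
  expect_equal(as.numeric(Tinf), log(1000), tolerance = 0.05)
  expect_true(attr(Tinf, "resolved"))
  # starting at steady state: zero relaxation time
  traj0 <- traj_from_fun(tt, a = function(t) rep(1, length(t)))
  expect_equal(as.numeric(total_relaxation_time(traj0)), 0)
  # unresolved flag when the criterion is never met
  traj_bad <- traj_from_fun(seq(0, 1, length.out = 50),
                            a = function(t) exp(-t))
  Tb <- total_relaxation_time(traj_bad, eps_inf = 1e-6)
  expect_false(attr(Tb, "resolved"))
})

test_that("slow-mode bound brackets the linear pathway's relaxation time", {
  fit <- toy1_fit_cached()
  mu4 <- toy1_reference_spectrum(build_toy_model_1())$mu[4]
  expect_gt(fit$T_inf, 1 / abs(mu4) / 10)
  expect_lt(fit$T_inf, 10 * log(1e3) / abs(mu4))
})

test_that("pool trajectories project onto pooling maps as stated", {
  tt <- seq(0, 5, length.out = 100)
  traj <- traj_from_fun(tt, a = function(t) exp(-t), b = function(t) 2 * exp(-t))
  # unit vector picks out a species
  pi_a <- pool_trajectory(c(1, 0), traj)
  expect_equal(pi_a$pi, traj$a)
  # a map orthogonal to the deviations gives a constant pool
  pi_o <- pool_trajectory(c(2, -1), traj, use_deviations = TRUE,
                          x_ss = c(a = 0, b = 0))
  expect_lt(max(abs(pi_o$pi)), 1e-12)
})

test_that("first-pool deviation trajectory decays at the fast analytic rate", {
  fit <- toy1_fit_cached()
  net <- build_toy_model_1()
  mu1 <- toy1_reference_spectrum(net)$mu[1]
  ss <- find_steady_state(net)
  p1 <- c(-1, 1, 0, 0)          # first pooling map at unit Keq
  pit <- pool_trajectory(p1, fit$trajectory, use_deviations = TRUE,
                         x_ss = ss$x_ss)
  sel <- pit$time >= 0.5 & pit$time <= 1.5   # inside the first timescale
  slope <- coef(lm(log(abs(pit$pi[sel])) ~ pit$time[sel]))[2]
  expect_equal(unname(slope), mu1, tolerance = 0.02)
})

test_that("pool timescale is the settledness time of the pool trajectory", {
  tt <- seq(0, 12, length.out = 4000)
  ts <- pool_timescale(tt, exp(-tt), eps_p = exp(-3), scale = 1)
  expect_equal(ts$timescale, 3, tolerance = 0.01)
  expect_true(ts$resolved)
  ts0 <- pool_timescale(tt, rep(2.5, length(tt)))
  expect_equal(ts0$timescale, 0)
})

test_that("first-pool timescale shrinks tenfold when the fast constants are scaled", {
  cfg <- dma_config()
  ts_for <- function(base) {
    net <- build_toy_model_1(k_intracellular_base = base)
    ss <- find_steady_state(net)
    x0 <- perturb_state(ss, cfg$perturbation[c("x1", "x4")])
    tt <- c(0, 10^seq(-4, 2, length.out = 400))
    traj <- simulate_network(net, x0, tt)
    pit <- pool_trajectory(c(-1, 1, 0, 0), traj, use_deviations = TRUE,
                           x_ss = ss$x_ss)
    pool_timescale(pit$time, pit$pi, eps_p = 0.01)$timescale
  }
  expect_equal(ts_for(1) / ts_for(10), 10, tolerance = 0.1)
})

test_that("a single-mode trajectory yields one interval with a uniform spectrum", {
  tt <- c(0, 10^seq(-2, 1.2, length.out = 1500))
  traj <- traj_from_fun(tt, a = function(t) 1 + 0.5 * exp(-t),
                        b = function(t) 2 - 0.3 * exp(-t))
  sw <- sweep_windows(traj, dma_config(eps_inf = 1e-3))
  expect_true(all(sw$nu == 1))
  lam <- vapply(sw$lambda, function(l) Re(l[1]), numeric(1))
  expect_lt(diff(range(lam)) / abs(mean(lam)), 1e-3)
  iv <- detect_intervals(sw)
  expect_equal(nrow(iv), 1)
  # log-ladder spacing: fixed ratio between consecutive centers
  r <- sw$t_center[-1] / sw$t_center[-nrow(sw)]
  expect_equal(r, rep(10^(1 / 8), length(r)), tolerance = 1e-10)
})

test_that("the linear pathway sweep tracks the analytic eigenvalue hierarchy", {
  fit <- toy1_fit_cached()
  ref <- toy1_reference_spectrum(build_toy_model_1())
  w <- fit$windows
  lam1 <- Re(w$lambda[[2]][1])
  expect_equal(lam1, ref$mu[1], tolerance = 0.05)
  lam4 <- Re(w$lambda[[nrow(w) - 2]][1])
  expect_equal(lam4, ref$mu[4], tolerance = 0.05)
})

test_that("interval detection recovers the hierarchical staircase of both models", {
  fit1 <- toy1_fit_cached()
  expect_equal(nrow(fit1$intervals), 7)
  expect_true(all(fit1$intervals$transition_kind[-1] == "dimensionality_change"))
  # contiguous tiling of [0, T_inf]
  expect_equal(fit1$intervals$t_start[-1],
               fit1$intervals$t_end[-nrow(fit1$intervals)])
  expect_equal(fit1$intervals$t_start[1], 0)
  expect_equal(fit1$intervals$t_end[nrow(fit1$intervals)], fit1$T_inf)
  # dimensionality relaxes to one as the steady state is approached
  expect_equal(fit1$intervals$nu[nrow(fit1$intervals)], 1)
  # the cofactor-coupled build resolves four timescale groups: a stable
  # seven-interval staircase under the default reconstruction
  fit2 <- toy2_fit_cached()
  expect_equal(nrow(fit2$intervals), 7)
  expect_equal(fit2$intervals$nu[nrow(fit2$intervals)], 1)
})

test_that("slowest-interval pooling maps match the analytic aggregate patterns", {
  fit1 <- toy1_fit_cached()
  p_slow <- fit1$intervals$pooling[[nrow(fit1$intervals)]][1, ]
  expect_equal(unname(p_slow), rep(1, 4), tolerance = 0.05)
  fit2 <- toy2_fit_cached()
  p2 <- fit2$intervals$pooling[[nrow(fit2$intervals)]][1, ]
  pathway <- p2[c("x1", "x2", "x3", "x4")] / p2[["x1"]]
  expect_equal(unname(pathway), c(1, 2, 2, 1), tolerance = 0.1)
  # cofactors carry negligible weight in the slowest pool
  expect_lt(max(abs(p2[c("x5", "x6")])), 0.01)
})
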