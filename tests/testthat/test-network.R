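test_that("mass-action fluxes reproduce the deviation-form rate laws", {
  net <- build_toy_model_1()
  ss <- find_steady_state(net)
  # deviation form of reaction 2: theta2 = k2+ chi1 - k2- chi2
  k2p <- net$k_fwd[2]; k2m <- net$k_rev[2]
  for (chi in list(c(0.1, 0, 0, 0), c(0.05, -0.02, 0.01, 0.03))) {
    theta <- mass_action_flux(net, ss$x_ss + chi) - mass_action_flux(net, ss$x_ss)
    expect_equal(theta[2], k2p * chi[1] - k2m * chi[2], tolerance = 1e-12)
    # boundary reactions: theta1 = -k1- chi1, theta5 = k5+ chi4
    expect_equal(theta[1], -net$k_rev[1] * chi[1], tolerance = 1e-12)
    expect_equal(theta[5], net$k_fwd[5] * chi[4], tolerance = 1e-12)
  }
})

test_that("zero-rate kinetics give zero flux and zero Jacobian", {
  net <- reaction_network(
    c("a", "b"), boundary = c(ext = 1),
    reactions = list(
      list(id = "r1", reactants = c(ext = 1), products = c(a = 1),
           k_fwd = 0, k_rev = 0),
      list(id = "r2", reactants = c(a = 1), products = c(b = 1),
           k_fwd = 0, k_rev = 0)))
  expect_equal(mass_action_flux(net, c(1, 2)), c(0, 0))
  expect_equal(network_jacobian(net, c(1, 2)), matrix(0, 2, 2),
               ignore_attr = TRUE)
})

test_that("bimolecular mass-action product is evaluated by hand correctly", {
  net <- reaction_network(
    c("x1", "x2", "x5", "x6"),
    reactions = list(
      list(id = "r", reactants = c(x1 = 1, x5 = 1),
           products = c(x2 = 1, x6 = 1), k_fwd = 2, k_rev = 1),
      list(id = "drain", reactants = c(x2 = 1), products = c(x1 = 1),
           k_fwd = 1, k_rev = 0)))
  # v = k+ x1 x5 - k- x2 x6 = 2*1*1 - 1*1*1 = 1 at the all-ones state
  expect_equal(mass_action_flux(net, c(1, 1, 1, 1))[1], 1)
})

test_that("input validation rejects bad states and bad networks", {
  net <- build_toy_model_1()
  expect_error(mass_action_flux(net, c(-1, 1, 1, 1)), "negative")
  expect_error(mass_action_flux(net, c(1, 1)), "length")
  expect_error(
    reaction_network(c("a"), reactions = list(
      list(id = "r", reactants = c(a = 1), products = c(ghost = 1),
           k_fwd = 1, k_rev = 1))),
    "ghost")
})

test_that("analytic Jacobian matches finite differences on the bilinear model", {
  net <- build_toy_model_2()
  set.seed(11)
  for (rep in 1:3) {
    x <- runif(6, 0.5, 3)
    J <- network_jacobian(net, x)
    f <- function(y) as.numeric(net$S %*% mass_action_flux(net, y))
    Jfd <- matrix(0, 6, 6)
    for (l in 1:6) {
      h <- 1e-6 * max(1, abs(x[l]))
      e <- rep(0, 6); e[l] <- h
      Jfd[, l] <- (f(x + e) - f(x - e)) / (2 * h)
    }
    expect_equal(J, Jfd, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # unit-rate linear chain: J[2,1] = +k2+ from dchi2/dt = theta2 - theta3
  net1 <- build_toy_model_1(k_intracellular_base = 1)
  J1 <- network_jacobian(net1, find_steady_state(net1)$x_ss)
  expect_equal(J1[2, 1], net1$k_fwd[2])
})

test_that("steady-state solver converges, is stable and reproducible", {
  net <- build_toy_model_1()
  ss <- find_steady_state(net)
  expect_lt(ss$residual, 1e-10)
  expect_true(ss$stable)
  expect_true(all(Re(eigen(ss$jacobian, only.values = TRUE)$values) < 0))
  # two different positive guesses converge to the same state
  ss2 <- find_steady_state(net, x_guess = c(5, 0.1, 2, 0.5))
  expect_equal(ss$x_ss, ss2$x_ss, tolerance = 1e-8)
  # equal boundary concentrations and unit Keq: uniform equilibrium,
  # all intracellular fluxes vanish
  net_eq <- build_toy_model_1(x1_ext = 1.5, x4_ext = 1.5)
  ss_eq <- find_steady_state(net_eq)
  expect_equal(unname(ss_eq$x_ss), rep(1.5, 4), tolerance = 1e-8)
  expect_equal(ss_eq$v_ss, rep(0, 5), tolerance = 1e-10)
})

test_that("long-time integration endpoint agrees with the root-found steady state", {
  net <- build_toy_model_1()
  ss <- find_steady_state(net)
  lam_slow <- min(abs(Re(eigen(ss$jacobian, only.values = TRUE)$values)))
  x0 <- perturb_state(ss, c(x1 = 0.2, x4 = 0.1))
  traj <- simulate_network(net, x0, c(0, 20 / lam_slow))
  x_end <- as.numeric(traj[nrow(traj), -1])
  expect_equal(x_end, unname(ss$x_ss), tolerance = 1e-6)
})

test_that("simulation is a fixed point at the steady state and matches Exp(Jt)", {
  net <- build_toy_model_1()
  ss <- find_steady_state(net)
  tt <- c(0, 10^seq(-2, 2, length.out = 40))
  traj0 <- simulate_network(net, ss$x_ss, tt)
  expect_lt(max(abs(sweep(as.matrix(traj0[, -1]), 2, ss$x_ss))), 1e-8)
  # linear deviation dynamics: chi(t) = Exp(Jt) chi0 (matrix-exponential oracle)
  chi0 <- c(0.2, 0, 0, -0.1) * ss$x_ss
  traj <- simulate_network(net, ss$x_ss + chi0, tt)
  for (i in c(5, 15, 25, 40)) {
    chi_ode <- unname(as.numeric(traj[i, -1]) - ss$x_ss)
    chi_exp <- as.numeric(Matrix::expm(ss$jacobian * tt[i]) %*% chi0)
    expect_equal(chi_ode, chi_exp, tolerance = 1e-6)
  }
})

test_that("late-time decay rate of the linear pathway matches the analytic slow mode", {
  net <- build_toy_model_1()
  ss <- find_steady_state(net)
  mu4 <- toy1_reference_spectrum(net)$mu[4]
  t1 <- 2 / abs(mu4); t2 <- 4 / abs(mu4)
  x0 <- perturb_state(ss, c(x1 = 0.2, x4 = 0.1))
  traj <- simulate_network(net, x0, c(0, t1, t2))
  nrm <- function(i) sqrt(sum((as.numeric(traj[i, -1]) - ss$x_ss)^2))
  slope <- log(nrm(3) / nrm(2)) / (t2 - t1)
  expect_equal(slope, mu4, tolerance = 0.05)
})

test_that("perturbation helper applies relative bumps and validates names", {
  net <- build_toy_model_1()
  ss <- find_steady_state(net)
  x0 <- perturb_state(ss, c(x1 = 0.1, x4 = -0.1))
  expect_equal(unname(x0["x1"] / ss$x_ss["x1"]), 1.1)
  expect_equal(unname(x0["x4"] / ss$x_ss["x4"]), 0.9)
  expect_error(perturb_state(ss, c(zz = 0.1)), "unknown species")
})
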