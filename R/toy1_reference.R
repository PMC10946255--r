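#' Rate constants and equilibrium constants of a linear pathway network
#'
#' Extracts the per-reaction forward/reverse constants and equilibrium
#' constants of a [build_toy_model_1()]-shaped network (5 reactions) as a
#' named list, for use by the analytic reference.
#'
#' @param network a 4-species, 5-reaction linear pathway network.
#' @return list with `k_fwd`, `k_rev` (length 5) and `Keq` (length 5).
#' @export
toy1_rates <- function(network) {
  stopifnot(inherits(network, "reaction_network"),
            length(network$reactions) == 5,
            length(network$species_names) == 4)
  list(k_fwd = network$k_fwd, k_rev = network$k_rev,
       Keq = ifelse(network$k_rev > 0, network$k_fwd / network$k_rev, NA))
}

#' Closed-form timescale hierarchy of the linear pathway model
#'
#' Analytic approximations for the four dominant eigenvalues of the
#' hierarchical linear pathway, derived by describing each timescale through
#' the flux relaxation of a single reaction:
#' * `mu1 = -(k2+ + k2-)` (relaxation of reaction 2),
#' * `mu2 = (theta_a - 1) k3+ - k3-` with `theta_a = 1 / (1 + K2)`,
#' * `mu3 = k4+ (beta_a - 1) - k4-` with
#'   `beta_a = (K2 + 1) / (K2 K3 + K2 + 1)`,
#' * `mu4 = k5+ (gamma_a - 1)` with `gamma_a` the root in (0, 1) of the
#'   quadratic closure of the slowest transitory regime.
#'
#' The transition coefficients `theta`, `beta`, `gamma` quantify the
#' order-of-magnitude balance between consecutive flux deviations in each
#' transitory regime; `kappa = k5+ / k1-` couples the two boundary
#' reactions in the slowest regime. The transitory eigenvalues `mu_check`
#' equal the next regime's eigenvalue at the asymptotic coefficients. The
#' third regime updates `theta_a` and `beta_a` (secondary relaxation of
#' reactions 2 and 3); both first- and third-regime values are returned.
#'
#' The analysis assumes `|mu_check3| < k1-` (slowest timescale carried by
#' the secretion-side mode); the opposite branch is flagged, not computed.
#'
#' @param k list with `k_fwd`, `k_rev` per reaction (as from
#'   [toy1_rates()]), or a [build_toy_model_1()] network.
#' @return list of class `toy1_reference` with `mu` (length 4), `mu_check`
#'   (length 3), `theta_a`, `beta_a`, `gamma_a`, `theta_a3`, `beta_a3`,
#'   `kappa`, `Keq`, `gamma_roots`, `gamma_residual`, `branch_ok`.
#' @export
toy1_reference_spectrum <- function(k) {
  if (inherits(k, "reaction_network")) k <- toy1_rates(k)
  kf <- k$k_fwd; kr <- k$k_rev
  stopifnot(length(kf) == 5, all(kf > 0), all(kr[2:4] > 0), kr[1] > 0)
  K2 <- kf[2] / kr[2]; K3 <- kf[3] / kr[3]; K4 <- kf[4] / kr[4]
  kappa <- kf[5] / kr[1]

  theta_a <- 1 / (1 + K2)
  beta_a <- (K2 + 1) / (K2 * K3 + K2 + 1)
  mu1 <- -(kf[2] + kr[2])
  mu2 <- (theta_a - 1) * kf[3] - kr[3]
  mu3 <- kf[4] * (beta_a - 1) - kr[4]

  # quadratic closure for gamma_a:
  # gamma + kappa gamma (gamma-1) K2K3K4 / [kappa (gamma-1) S + 1] = 1,
  # S = K2K3 + K2 + 1  =>  (kS + kP) g^2 + (1 - 2kS - kP) g + (kS - 1) = 0
  S <- K2 * K3 + K2 + 1
  P <- K2 * K3 * K4
  a <- kappa * S + kappa * P
  b <- 1 - 2 * kappa * S - kappa * P
  cc <- kappa * S - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no real root for the slow-regime closure")
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  in_unit <- roots > 0 & roots < 1
  if (!any(in_unit))
    stop("no closure root in (0, 1); roots = ",
         paste(format(roots, digits = 6), collapse = ", "))
  gamma_a <- roots[in_unit][which.min(kf[5] * (roots[in_unit] - 1))]
  resid <- gamma_a + kappa * gamma_a * (gamma_a - 1) * P /
    (kappa * (gamma_a - 1) * S + 1) - 1
  mu4 <- kf[5] * (gamma_a - 1)

  # third-regime (secondary) transition coefficients
  u <- kappa * (gamma_a - 1)
  theta_a3 <- (u + 1) / (u * (K2 + 1) + 1)
  beta_a3 <- (u * (K2 + 1) + 1) / (u * (K2 * K3 + K2 + 1) + 1)

  branch_ok <- abs(mu4) < kr[1]
  if (!branch_ok)
    warning("|mu_check3| >= k1-: the slowest timescale is carried by the ",
            "uptake-side mode; analytic expressions use the stated branch")

  structure(list(mu = c(mu1, mu2, mu3, mu4),
                 mu_check = c(mu2, mu3, mu4),
                 theta_a = theta_a, beta_a = beta_a, gamma_a = gamma_a,
                 theta_a3 = theta_a3, beta_a3 = beta_a3, kappa = kappa,
                 Keq = c(kf[1] / kr[1], K2, K3, K4, NA),
                 gamma_roots = roots, gamma_residual = resid,
                 branch_ok = branch_ok),
            class = "toy1_reference")
}

#' Analytic pooling-map representations of the linear pathway model
#'
#' All printed representations of the four pools as functions of the
#' equilibrium constants: the primed partial representations and their
#' sum-total maps. The slowest pool `p4 = (1, K2, K2 K3, K2 K3 K4)`
#' aggregates every intracellular metabolite; at unit equilibrium constants
#' its coefficients are (1, 1, 1, 1).
#'
#' @param Keq equilibrium constants of reactions 2--4 (length-3 vector
#'   `c(K2, K3, K4)`), or a network / `toy1_reference`.
#' @return list of pooling vectors `p1`, `p1_check`, `p2p`, `p2pp`, `p2`,
#'   `p3p`, `p3pp`, `p3ppp`, `p3`, `p4p`, `p4pp`, `p4ppp`, `p4pppp`, `p4`.
#' @export
toy1_reference_pooling <- function(Keq) {
  if (inherits(Keq, "reaction_network"))
    Keq <- toy1_rates(Keq)$Keq[2:4]
  if (inherits(Keq, "toy1_reference")) Keq <- Keq$Keq[2:4]
  stopifnot(length(Keq) == 3, all(Keq > 0))
  K2 <- Keq[1]; K3 <- Keq[2]; K4 <- Keq[3]
  p2p <- c(0, -K3, 1, 0)
  p2pp <- c(-K2 * K3, 0, 1, 0)
  p3p <- c(0, 0, -K4, 1)
  p3pp <- c(0, -K3 * K4, 0, 1)
  p3ppp <- c(-K2 * K3 * K4, 0, 0, 1)
  p4p <- c(1, 0, 0, 0)
  p4pp <- c(0, K2, 0, 0)
  p4ppp <- c(0, 0, K2 * K3, 0)
  p4pppp <- c(0, 0, 0, K2 * K3 * K4)
  list(p1 = c(-K2, 1, 0, 0), p1_check = c(-1, -1, 2, 0),
       p2p = p2p, p2pp = p2pp, p2 = p2p + p2pp,
       p3p = p3p, p3pp = p3pp, p3ppp = p3ppp, p3 = p3p + p3pp + p3ppp,
       p4p = p4p, p4pp = p4pp, p4ppp = p4ppp, p4pppp = p4pppp,
       p4 = p4p + p4pp + p4ppp + p4pppp)
}

#' Analytic eigenmodes of the linear pathway model
#'
#' The approximate dominant eigenmodes and their transitory counterparts:
#' `phi1 = (-1, 1, 0, 0)`; `phi1_check(theta) = (-theta, theta - 1, 1, 0)`;
#' `phi2_check(beta) = (-theta_a beta, (theta_a - 1) beta, beta - 1, 1)`;
#' `phi3 = phi2_check(beta_a)`; the third transitory mode carries the
#' boundary coupling `kappa`, and the slowest mode `phi4` is its limit at
#' the asymptotic coefficients (with the third-regime `theta_a`, `beta_a`).
#' Also returns the equilibration direction of reaction 3,
#' `g3 = (0, k3+, -k3-, 0)`, which the slow modes must leave unperturbed.
#'
#' @param k rates as for [toy1_reference_spectrum()].
#' @return list with `phi1`, `phi1_check`, `phi2_check`, `phi2_check_fun`,
#'   `phi3`, `phi3_check_fun`, `phi4`, `g3`, plus the underlying reference.
#' @export
toy1_reference_modes <- function(k) {
  if (inherits(k, "reaction_network")) k <- toy1_rates(k)
  ref <- toy1_reference_spectrum(k)
  th <- ref$theta_a; be <- ref$beta_a; ga <- ref$gamma_a; kap <- ref$kappa
  phi1 <- c(-1, 1, 0, 0)
  phi1_check_fun <- function(theta) c(-theta, theta - 1, 1, 0)
  phi2_check_fun <- function(beta) c(-th * beta, (th - 1) * beta, beta - 1, 1)
  phi3_check_fun <- function(gamma, theta = ref$theta_a3, beta = ref$beta_a3)
    c(kap * (1 - gamma) / (kap * (gamma - 1) + 1) * theta * beta * gamma,
      (theta - 1) * beta * gamma,
      (beta - 1) * gamma,
      gamma - 1)
  list(phi1 = phi1,
       phi1_check = phi1_check_fun(th),
       phi1_check_fun = phi1_check_fun,
       phi2_check = phi2_check_fun(be),
       phi2_check_fun = phi2_check_fun,
       phi3 = phi2_check_fun(be),
       phi3_check_fun = phi3_check_fun,
       phi4 = phi3_check_fun(ga),
       g3 = c(0, k$k_fwd[3], -k$k_rev[3], 0),
       reference = ref)
}

#' Check reciprocal orthogonality of pooling maps and eigenmodes
#'
#' Reports the largest inner product between non-corresponding pooling rows
#' and mode columns, and the largest deviation of `P Phi` from the
#' identity.
#'
#' @param P pooling matrix (rows = pooling maps).
#' @param Phi modal matrix (columns = modes), compatible shapes.
#' @param tol pass tolerance on the off-diagonal products.
#' @return list with `max_off_diagonal`, `max_identity_deviation`, `pass`.
#' @export
verify_reciprocal_orthogonality <- function(P, Phi, tol = 1e-8) {
  P <- as.matrix(P); Phi <- as.matrix(Phi)
  stopifnot(ncol(P) == nrow(Phi))
  G <- P %*% Phi
  off <- G - diag(1, nrow(G), ncol(G))
  max_off <- if (nrow(G) > 1) max(Mod(G[row(G) != col(G)])) else 0
  list(max_off_diagonal = max_off,
       max_identity_deviation = max(Mod(off)),
       pass = max(Mod(off)) <= tol)
}
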