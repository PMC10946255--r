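#' Hierarchical linear pathway model (Toy Model 1)
#'
#' A linear pathway of four intracellular metabolites and five reversible
#' mass-action reactions: uptake of the substrate from the environment,
#' three consecutive interconversions, and secretion of the product. All
#' equilibrium constants are 1, so flux is driven purely by the gradient
#' between the fixed boundary concentrations. Consecutive intracellular rate
#' constants are separated by `separation` (default two orders of
#' magnitude), and the boundary reactions are the rate-limiting steps. This
#' construction yields a clean timescale hierarchy: each intracellular
#' reaction equilibrates on its own timescale, and the slowest dynamics are
#' governed by the boundary exchange of a single aggregate pool with
#' coefficients (1, 1, 1, 1).
#'
#' The secretion and uptake rate constants are set to `k_boundary` and
#' `2 * k_boundary`, so their ratio (the asymptotic coefficient `kappa`) is
#' 1/2: of the same order, as required, while avoiding the degenerate
#' `kappa = 1` point at which the third-regime transition coefficients of
#' the analytic reference are singular.
#'
#' @param k_intracellular_base forward rate constant of the fastest
#'   intracellular reaction (reaction 2), units 1/time.
#' @param separation ratio between consecutive intracellular rate constants
#'   (> 1; default 100).
#' @param k_boundary secretion rate constant (must stay below the slowest
#'   intracellular constant so the boundary reactions are rate-limiting).
#' @param x1_ext,x4_ext fixed boundary concentrations of substrate and
#'   product; their gradient drives the pathway flux.
#' @return a [reaction_network()] with species `x1..x4`.
#' @export
build_toy_model_1 <- function(k_intracellular_base = 1, separation = 100,
                              k_boundary = 1e-6, x1_ext = 2, x4_ext = 1) {
  if (separation <= 1) stop("separation must be > 1")
  k2 <- k_intracellular_base
  k3 <- k2 / separation
  k4 <- k3 / separation
  if (2 * k_boundary >= k4)
    warning("boundary reactions are not rate-limiting ",
            "(k_boundary is not below the slowest intracellular constant)")
  reaction_network(
    species = c("x1", "x2", "x3", "x4"),
    boundary = c(x1s = x1_ext, x4s = x4_ext),
    reactions = list(
      list(id = "R1", reactants = c(x1s = 1), products = c(x1 = 1),
           k_fwd = 2 * k_boundary, k_rev = 2 * k_boundary),
      list(id = "R2", reactants = c(x1 = 1), products = c(x2 = 1),
           k_fwd = k2, k_rev = k2),
      list(id = "R3", reactants = c(x2 = 1), products = c(x3 = 1),
           k_fwd = k3, k_rev = k3),
      list(id = "R4", reactants = c(x3 = 1), products = c(x4 = 1),
           k_fwd = k4, k_rev = k4),
      list(id = "R5", reactants = c(x4 = 1), products = c(x4s = 1),
           k_fwd = k_boundary, k_rev = k_boundary)))
}

#' Cofactor-coupled pathway model (Toy Model 2)
#'
#' The same four-metabolite pathway as [build_toy_model_1()], but with
#' energy coupling: a high-energy cofactor `x5` drives the first
#' interconversion (reaction 2, bilinear `x1 + x5 <-> x2 + x6`) and is
#' recovered in the last (reaction 4, bilinear `x3 + x6 <-> x4 + x5`).
#' Cofactors and the substrate/product are exchanged with the environment in
#' proportion to their concentration gradient across the membrane; the
#' cofactor exchange reactions (6 and 7) are the fastest in the network,
#' while the substrate uptake and product secretion (reactions 1 and 5) are
#' rate-limiting.
#'
#' Default rate constants honor the orderings above and reproduce the
#' characteristic relaxation chronology of a cofactor-driven pathway: the
#' cofactor pair equilibrates almost immediately, the two cofactor-coupled
#' reactions relax on the seconds timescale, the middle reaction two orders
#' of magnitude later, and the boundary reactions last. Equilibrium
#' constants of the coupled reactions (2 and 1/2, with unit cofactor
#' concentrations) make the slow-regime equilibria `x2 = 2 x1` and
#' `x3 = 2 x4`, so the slowest pool aggregates the pathway metabolites with
#' coefficients (1, 2, 2, 1).
#'
#' @param k_uptake,k_secretion boundary exchange constants for substrate and
#'   product (rate-limiting; `k_secretion/k_uptake = 1/2` by default).
#' @param k_coupled_up base rate constant of the uphill cofactor-driven
#'   reaction 2 (units 1/(conc time)).
#' @param k_coupled_down base rate constant of the downhill cofactor-
#'   recovering reaction 4; by default three-fold smaller than reaction 2's,
#'   so the two coupled reactions relax at distinct (but same-band) rates.
#' @param k_mid rate constant of the middle interconversion (reaction 3).
#' @param k_exchange cofactor membrane exchange constant (fastest rates).
#' @param x1_ext,x4_ext,x5_ext,x6_ext fixed boundary concentrations.
#' @return a [reaction_network()] with species `x1..x6` (`x5`, `x6` the
#'   high- and low-energy cofactors).
#' @export
build_toy_model_2 <- function(k_uptake = 5e-5, k_secretion = 2.5e-5,
                              k_coupled_up = 0.3, k_coupled_down = 0.1,
                              k_mid = 5e-3, k_exchange = 25,
                              x1_ext = 2, x4_ext = 1, x5_ext = 1, x6_ext = 1) {
  if (k_exchange <= max(2 * k_coupled_up, 2 * k_coupled_down, k_mid,
                        k_uptake, k_secretion))
    warning("cofactor exchange reactions are not the fastest in the network")
  if (max(k_uptake, k_secretion) >= k_mid)
    warning("boundary reactions 1 and 5 are not rate-limiting")
  reaction_network(
    species = c("x1", "x2", "x3", "x4", "x5", "x6"),
    boundary = c(x1s = x1_ext, x4s = x4_ext, x5s = x5_ext, x6s = x6_ext),
    reactions = list(
      list(id = "R1", reactants = c(x1s = 1), products = c(x1 = 1),
           k_fwd = k_uptake, k_rev = k_uptake),
      list(id = "R2", reactants = c(x1 = 1, x5 = 1), products = c(x2 = 1, x6 = 1),
           k_fwd = 2 * k_coupled_up, k_rev = k_coupled_up),
      list(id = "R3", reactants = c(x2 = 1), products = c(x3 = 1),
           k_fwd = k_mid, k_rev = k_mid),
      list(id = "R4", reactants = c(x3 = 1, x6 = 1), products = c(x4 = 1, x5 = 1),
           k_fwd = k_coupled_down, k_rev = 2 * k_coupled_down),
      list(id = "R5", reactants = c(x4 = 1), products = c(x4s = 1),
           k_fwd = k_secretion, k_rev = k_secretion),
      list(id = "R6", reactants = c(x5s = 1), products = c(x5 = 1),
           k_fwd = k_exchange, k_rev = k_exchange),
      list(id = "R7", reactants = c(x6s = 1), products = c(x6 = 1),
           k_fwd = k_exchange, k_rev = k_exchange)))
}

#' Specification of a synthetic inhomogeneous linear fixture
#'
#' Describes discrete linear dynamics `h[k+1] = A h[k] + omega + eps[k]`
#' with known propagator, offset and i.i.d. Gaussian noise, used to test the
#' decomposition solver against planted ground truth.
#'
#' @param A_true square discrete propagator (spectral radius < 1 for a
#'   decaying fixture).
#' @param omega_true inhomogeneous offset vector.
#' @param h1_init initial local deviation vector.
#' @param N number of columns of each data matrix.
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer random seed (used for the noise draws).
#' @return a list of class `synthetic_linear_spec`.
#' @export
synthetic_linear_spec <- function(A_true, omega_true, h1_init, N,
                                  noise_sd = 0, seed = 1L) {
  A_true <- as.matrix(A_true)
  stopifnot(nrow(A_true) == ncol(A_true),
            length(omega_true) == nrow(A_true),
            length(h1_init) == nrow(A_true),
            N >= 2, noise_sd >= 0)
  rho <- max(Mod(eigen(A_true, only.values = TRUE)$values))
  structure(list(A_true = A_true, omega_true = as.numeric(omega_true),
                 h1_init = as.numeric(h1_init), N = as.integer(N),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 spectral_radius = rho),
            class = "synthetic_linear_spec")
}

#' Generate paired snapshot matrices from a synthetic linear spec
#'
#' Runs the recursion `h[k+1] = A h[k] + omega + eps[k]` for `k = 1..N` and
#' compiles the time-shifted data matrices `H0 = [h1 .. hN]` and
#' `H1 = [h2 .. h(N+1)]`. With `noise_sd = 0` the matrices satisfy the
#' recursion exactly; the seed makes noisy draws reproducible.
#'
#' @param spec a [synthetic_linear_spec()].
#' @return list with matrices `H0`, `H1` (each `n x N`).
#' @export
generate_synthetic_linear <- function(spec) {
  stopifnot(inherits(spec, "synthetic_linear_spec"))
  n <- nrow(spec$A_true)
  H <- matrix(0, n, spec$N + 1)
  H[, 1] <- spec$h1_init
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  for (k in seq_len(spec$N)) {
    eps <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    H[, k + 1] <- spec$A_true %*% H[, k] + spec$omega_true + eps
  }
  list(H0 = H[, 1:spec$N, drop = FALSE], H1 = H[, 2:(spec$N + 1), drop = FALSE])
}
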