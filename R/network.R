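#' Construct a mass-action reaction network
#'
#' A reaction network is defined by a set of intracellular species, a set of
#' boundary (external) species held at fixed concentrations, and a list of
#' elementary mass-action reactions. Each reaction carries a forward and a
#' reverse rate constant; reversible reactions have an equilibrium constant
#' `Keq = k_fwd / k_rev`. Boundary species appear in reactions but are
#' excluded from the state vector, so their concentrations act as parameters
#' of the kinetics.
#'
#' @param species character vector of intracellular species identifiers.
#' @param boundary named numeric vector of fixed boundary concentrations
#'   (names are the boundary species identifiers). May be empty.
#' @param reactions list of reactions. Each reaction is a list with elements
#'   `id` (character), `reactants` and `products` (named integer vectors of
#'   stoichiometric coefficients; names may refer to intracellular or
#'   boundary species), `k_fwd` (> 0) and `k_rev` (>= 0; 0 marks an
#'   irreversible step such as a boundary drain).
#'
#' @return an object of class `reaction_network` with components
#'   `species_names`, `boundary_conc`, `reactions`, the intracellular
#'   stoichiometric matrix `S` (species x reactions) and `k_fwd`, `k_rev`.
#' @export
reaction_network <- function(species, boundary = numeric(), reactions = list()) {
  species <- as.character(species)
  if (anyDuplicated(species) > 0) stop("duplicated species identifiers")
  if (length(boundary) > 0 && is.null(names(boundary)))
    stop("boundary concentrations must be named")
  if (any(names(boundary) %in% species))
    stop("boundary species must not also be intracellular species")
  if (length(reactions) == 0) stop("a reaction network needs at least one reaction")

  known <- c(species, names(boundary))
  m <- length(reactions)
  n <- length(species)
  S <- matrix(0L, n, m, dimnames = list(species, vapply(reactions, function(r) r$id, "")))
  k_fwd <- numeric(m)
  k_rev <- numeric(m)
  for (j in seq_len(m)) {
    r <- reactions[[j]]
    for (fld in c("id", "reactants", "products", "k_fwd", "k_rev"))
      if (is.null(r[[fld]])) stop("reaction ", j, " is missing field '", fld, "'")
    refs <- c(names(r$reactants), names(r$products))
    bad <- setdiff(refs, known)
    if (length(bad) > 0)
      stop("reaction '", r$id, "' references undeclared species: ",
           paste(bad, collapse = ", "))
    if (r$k_fwd < 0) stop("reaction '", r$id, "': k_fwd must be >= 0")
    if (r$k_rev < 0) stop("reaction '", r$id, "': k_rev must be >= 0")
    for (sp in names(r$reactants)) {
      i <- match(sp, species)
      if (!is.na(i)) S[i, j] <- S[i, j] - as.integer(r$reactants[[sp]])
    }
    for (sp in names(r$products)) {
      i <- match(sp, species)
      if (!is.na(i)) S[i, j] <- S[i, j] + as.integer(r$products[[sp]])
    }
    k_fwd[j] <- r$k_fwd
    k_rev[j] <- r$k_rev
    # canonical storage (integer stoichiometries) so that round-trips compare
    # identical regardless of how the reaction list was built
    reactions[[j]]$reactants <-
      stats::setNames(as.integer(r$reactants), names(r$reactants))
    reactions[[j]]$products <-
      stats::setNames(as.integer(r$products), names(r$products))
    reactions[[j]]$k_fwd <- as.numeric(r$k_fwd)
    reactions[[j]]$k_rev <- as.numeric(r$k_rev)
  }
  if (any(rowSums(abs(S)) == 0))
    stop("stoichiometric matrix has an all-zero row (orphan species)")
  if (any(colSums(abs(S)) == 0))
    stop("stoichiometric matrix has an all-zero column (reaction without net ",
         "intracellular turnover)")

  structure(
    list(species_names = species, boundary_conc = boundary,
         reactions = reactions, S = S, k_fwd = k_fwd, k_rev = k_rev),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species_names), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  species: ", paste(x$species_names, collapse = ", "), "\n", sep = "")
  if (length(x$boundary_conc) > 0)
    cat("  boundary: ",
        paste(sprintf("%s=%g", names(x$boundary_conc), x$boundary_conc),
              collapse = ", "), "\n", sep = "")
  for (r in x$reactions) {
    lhs <- paste(sprintf("%s %s", ifelse(r$reactants > 1, r$reactants, ""),
                         names(r$reactants)), collapse = " + ")
    rhs <- paste(sprintf("%s %s", ifelse(r$products > 1, r$products, ""),
                         names(r$products)), collapse = " + ")
    cat(sprintf("  %s: %s <-> %s  (k+ = %g, k- = %g)\n",
                r$id, trimws(lhs), trimws(rhs), r$k_fwd, r$k_rev))
  }
  invisible(x)
}

# full concentration lookup: intracellular state + fixed boundary values
.full_conc <- function(network, x) {
  c(stats::setNames(as.numeric(x), network$species_names), network$boundary_conc)
}

#' Mass-action reaction fluxes
#'
#' Evaluates `v_j = k_fwd[j] * prod(reactant conc.) - k_rev[j] * prod(product
#' conc.)` for every reaction, with boundary species held at their fixed
#' concentrations. Supports one- and two-substrate (bilinear) reactions and
#' arbitrary integer stoichiometries.
#'
#' @param network a [reaction_network()].
#' @param x nonnegative concentration vector over the intracellular species
#'   (in the order of `network$species_names`).
#' @return numeric flux vector of length `m` (one entry per reaction).
#' @export
mass_action_flux <- function(network, x) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(x) != length(network$species_names))
    stop("state vector has length ", length(x), ", expected ",
         length(network$species_names))
  if (any(x < 0)) stop("negative concentration in state vector")
  conc <- .full_conc(network, x)
  vapply(network$reactions, function(r) {
    fwd <- if (r$k_fwd > 0) r$k_fwd * prod(conc[names(r$reactants)]^r$reactants) else 0
    rev <- if (r$k_rev > 0) r$k_rev * prod(conc[names(r$products)]^r$products) else 0
    fwd - rev
  }, numeric(1))
}

# dv/dx (m x n): analytic derivative of the mass-action rate law
.flux_gradient <- function(network, x) {
  conc <- .full_conc(network, x)
  n <- length(network$species_names)
  m <- length(network$reactions)
  G <- matrix(0, m, n, dimnames = list(NULL, network$species_names))
  for (j in seq_len(m)) {
    r <- network$reactions[[j]]
    if (r$k_fwd > 0) for (sp in names(r$reactants)) {
      l <- match(sp, network$species_names)
      if (is.na(l)) next
      a <- r$reactants[[sp]]
      others <- conc[names(r$reactants)]^r$reactants
      others <- prod(others[names(others) != sp])
      G[j, l] <- G[j, l] + r$k_fwd * a * conc[[sp]]^(a - 1) * others
    }
    if (r$k_rev > 0) {
      for (sp in names(r$products)) {
        l <- match(sp, network$species_names)
        if (is.na(l)) next
        b <- r$products[[sp]]
        others <- conc[names(r$products)]^r$products
        others <- prod(others[names(others) != sp])
        G[j, l] <- G[j, l] - r$k_rev * b * conc[[sp]]^(b - 1) * others
      }
    }
  }
  G
}

#' Jacobian of the mass-balance equations
#'
#' Returns `J = S G` with `G = dv/dx` evaluated analytically from the
#' mass-action structure at the state `x`. For a linear (unimolecular)
#' network `J` is state-independent; bilinear cofactor-coupled reactions make
#' it state-dependent.
#'
#' @inheritParams mass_action_flux
#' @return an `n x n` numeric matrix.
#' @export
network_jacobian <- function(network, x) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(x) != length(network$species_names))
    stop("state vector has wrong length")
  network$S %*% .flux_gradient(network, x)
}

#' Steady state of a reaction network
#'
#' Solves `S v(x) = 0` by a damped Newton iteration with backtracking line
#' search on the residual norm, falling back to pseudo-transient continuation
#' (integrating the mass-balance equations for a stretch, then retrying
#' Newton) if the iteration stagnates. The returned steady state is checked
#' for linear stability: all eigenvalues of the Jacobian must have negative
#' real parts, otherwise the result is flagged unstable with a warning.
#'
#' @inheritParams mass_action_flux
#' @param x_guess positive initial guess for the intracellular concentrations.
#' @param tol convergence tolerance on the infinity norm of `S v(x)`.
#' @param max_iter maximum Newton iterations per attempt.
#' @return a list of class `deviation_state` with `x_ss`, `v_ss`,
#'   `residual` (infinity norm of `S v`), `stable` (logical) and
#'   `jacobian` (the Jacobian at the steady state).
#' @export
find_steady_state <- function(network, x_guess = NULL, tol = 1e-10,
                              max_iter = 200L) {
  stopifnot(inherits(network, "reaction_network"))
  n <- length(network$species_names)
  if (is.null(x_guess)) x_guess <- rep(1, n)
  if (any(x_guess <= 0)) stop("initial guess must be strictly positive")

  f <- function(x) as.numeric(network$S %*% mass_action_flux(network, x))
  x <- as.numeric(x_guess)

  newton <- function(x) {
    for (it in seq_len(max_iter)) {
      fx <- f(x)
      if (max(abs(fx)) < tol) return(list(x = x, ok = TRUE))
      J <- network_jacobian(network, x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step))
        step <- -as.numeric(qr.solve(J + 1e-12 * mean(abs(diag(J))) * diag(n), fx))
      lam <- 1
      repeat {
        x_new <- x + lam * step
        if (all(x_new > 0) && max(abs(f(x_new))) < max(abs(fx)) * (1 - 1e-4 * lam))
          break
        lam <- lam / 2
        if (lam < 1e-12) { x_new <- NULL; break }
      }
      if (is.null(x_new)) return(list(x = x, ok = FALSE))
      x <- x_new
    }
    list(x = x, ok = max(abs(f(x))) < tol)
  }

  res <- newton(x)
  if (!res$ok) {
    # pseudo-transient continuation: relax along the flow, then retry Newton
    rates <- c(network$k_fwd[network$k_fwd > 0],
               network$k_rev[network$k_rev > 0])
    t_relax <- 10 / min(rates)
    ode_fun <- function(t, y, parms)
      list(as.numeric(network$S %*% mass_action_flux(network, pmax(y, 0))))
    sol <- deSolve::lsoda(y = res$x, times = c(0, t_relax), func = ode_fun,
                          rtol = 1e-9, atol = 1e-12)
    res <- newton(pmax(as.numeric(sol[nrow(sol), -1]), 1e-12))
  }
  if (!res$ok)
    stop("steady-state iteration did not converge; residual = ",
         format(max(abs(f(res$x))), digits = 3))

  x_ss <- res$x
  J <- network_jacobian(network, x_ss)
  ev <- eigen(J, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  if (!stable) warning("steady state is not linearly stable")
  structure(
    list(x_ss = stats::setNames(x_ss, network$species_names),
         v_ss = mass_action_flux(network, x_ss),
         residual = max(abs(f(x_ss))), stable = stable, jacobian = J),
    class = "deviation_state")
}

#' @export
print.deviation_state <- function(x, ...) {
  cat("<deviation_state> residual =", format(x$residual, digits = 3),
      if (x$stable) "(stable)" else "(UNSTABLE)", "\n")
  print(x$x_ss)
  invisible(x)
}

#' Simulate concentration trajectories
#'
#' Integrates the transient mass-balance equations `dx/dt = S v(x)` with a
#' stiff solver (`deSolve::lsoda`) and the analytic Jacobian. Tight default
#' tolerances are used because rate constants in hierarchical networks span
#' several orders of magnitude and downstream interval detection is
#' sensitive to integration error.
#'
#' @inheritParams mass_action_flux
#' @param x0 nonnegative initial concentrations.
#' @param t_grid strictly increasing time grid (should start at 0).
#' @param rtol,atol relative and absolute solver tolerances.
#' @return a tibble with a `time` column and one column per species; the
#'   attribute `provenance` is set to `"simulated"`.
#' @export
simulate_network <- function(network, x0, t_grid, rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(network, "reaction_network"))
  if (any(x0 < 0)) stop("negative initial concentration")
  if (any(diff(t_grid) <= 0)) stop("time grid must be strictly increasing")
  ode_fun <- function(t, y, parms)
    list(as.numeric(network$S %*% mass_action_flux(network, pmax(y, 0))))
  jac_fun <- function(t, y, parms) network_jacobian(network, pmax(y, 0))
  sol <- deSolve::lsoda(y = stats::setNames(as.numeric(x0), network$species_names),
                        times = t_grid, func = ode_fun, jacfunc = jac_fun,
                        jactype = "fullusr", rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("stiff integration failed (istate = ", diagn[1], ")")
  X <- as.matrix(sol[, -1, drop = FALSE])
  if (any(X < -atol * 10))
    stop("solver produced negative concentrations beyond tolerance")
  X[X < 0] <- 0
  out <- tibble::as_tibble(as.data.frame(cbind(time = sol[, 1], X)))
  attr(out, "provenance") <- "simulated"
  out
}

#' Perturb a steady state
#'
#' Applies relative concentration bumps to selected species of a steady
#' state, producing the initial condition for a relaxation experiment.
#'
#' @param state a `deviation_state` from [find_steady_state()].
#' @param perturbation named numeric vector of relative bumps, e.g.
#'   `c(x1 = 0.1, x4 = -0.1)` raises `x1` by 10% and lowers `x4` by 10%.
#' @return named numeric vector of perturbed concentrations.
#' @export
perturb_state <- function(state, perturbation) {
  stopifnot(inherits(state, "deviation_state"))
  x0 <- state$x_ss
  bad <- setdiff(names(perturbation), names(x0))
  if (length(bad) > 0)
    stop("unknown species in perturbation: ", paste(bad, collapse = ", "))
  x0[names(perturbation)] <- x0[names(perturbation)] * (1 + perturbation)
  if (any(x0 < 0)) stop("perturbation drives a concentration negative")
  x0
}

# trajectory helpers -----------------------------------------------------

.traj_matrix <- function(traj) {
  stopifnot(is.data.frame(traj), "time" %in% names(traj))
  as.matrix(traj[, setdiff(names(traj), "time"), drop = FALSE])
}

.traj_species <- function(traj) setdiff(names(traj), "time")

.validate_trajectory <- function(traj) {
  if (!is.data.frame(traj) || !"time" %in% names(traj))
    stop("a trajectory must be a data frame with a 'time' column")
  if (any(diff(traj$time) <= 0)) stop("trajectory time column must be strictly increasing")
  invisible(traj)
}
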