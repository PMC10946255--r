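#' Assemble paired snapshot matrices for a sliding time window
#'
#' Evaluates local concentration deviations `h(t) = x(t) - x_ref` at `N + 1`
#' equally spaced time points spanning `[t1, t2]` (monotone cubic
#' interpolation of the native trajectory grid) and compiles the two
#' time-shifted data matrices `H0 = [h1 .. hN]`, `H1 = [h2 .. h(N+1)]`,
#' together with the differential matrix `D = H1 - H0` whose columns are the
#' one-step increments (the differential data eliminate the inhomogeneous
#' offset of the locally linearized dynamics).
#'
#' @param traj trajectory tibble (`time` plus species columns).
#' @param t1,t2 window bounds, inside the trajectory support.
#' @param N number of columns of each data matrix (`N + 1` samples;
#'   `dt = (t2 - t1) / N`).
#' @param t_ref_rule where the linearization reference `t_ref` sits:
#'   `"left"` (the window's left edge, default) or `"midpoint"`.
#' @return a list of class `sliding_window` with `t1`, `t2`, `N`, `dt`,
#'   `t_ref`, `x_ref`, `H0`, `H1`, `D` and the species names.
#' @export
assemble_window <- function(traj, t1, t2, N = 40L,
                            t_ref_rule = c("left", "midpoint")) {
  .validate_trajectory(traj)
  t_ref_rule <- match.arg(t_ref_rule)
  if (!(t2 > t1)) stop("window bounds must satisfy t1 < t2")
  if (N < 2) stop("N must be >= 2")
  tt <- traj$time
  if (t1 < tt[1] || t2 > tt[length(tt)])
    stop("window [", t1, ", ", t2, "] lies outside the trajectory support")

  # native samples covering the window (with margin for the interpolant)
  i1 <- max(1L, findInterval(t1, tt) - 2L)
  i2 <- min(length(tt), findInterval(t2, tt) + 3L)
  idx <- i1:i2
  dt <- (t2 - t1) / N
  native_spacing <- stats::median(diff(tt[idx]))
  if (is.finite(native_spacing) && dt < native_spacing / 10)
    warning("window sampling exceeds the native trajectory resolution ",
            "by more than 10x; interpolation error may dominate")

  grid <- t1 + dt * (0:N)
  species <- .traj_species(traj)
  X <- vapply(species, function(sp) {
    fun <- stats::splinefun(tt[idx], traj[[sp]][idx], method = "monoH.FC")
    fun(grid)
  }, numeric(N + 1))          # (N+1) x n
  t_ref <- if (t_ref_rule == "left") t1 else (t1 + t2) / 2
  x_ref <- vapply(species, function(sp) {
    stats::splinefun(tt[idx], traj[[sp]][idx], method = "monoH.FC")(t_ref)
  }, numeric(1))
  H <- t(X) - x_ref           # n x (N+1), columns h_k
  H0 <- H[, 1:N, drop = FALSE]
  H1 <- H[, 2:(N + 1), drop = FALSE]
  structure(list(t1 = t1, t2 = t2, N = as.integer(N), dt = dt,
                 t_ref = t_ref, x_ref = x_ref,
                 H0 = H0, H1 = H1, D = H1 - H0, species = species),
            class = "sliding_window")
}

#' Dynamic dimensionality of a snapshot matrix
#'
#' The number of singular values of `H0` above `eps_svd` relative to the
#' leading one: the count of exponential decay modes that contribute
#' appreciably to the signal inside the window.
#'
#' @param H0 snapshot matrix (species x samples).
#' @param eps_svd relative singular-value threshold in (0, 1).
#' @return list with `nu` and the truncated factors `U` (n x nu), `sigma`
#'   (length nu) and `V` (N x nu). An all-zero `H0` gives `nu = 0`
#'   (degenerate window).
#' @export
effective_rank <- function(H0, eps_svd = 0.05) {
  stopifnot(is.matrix(H0))
  if (all(H0 == 0) || max(abs(H0)) == 0)
    return(list(nu = 0L, U = NULL, sigma = numeric(), V = NULL))
  sv <- svd(H0)
  nu <- sum(sv$d / sv$d[1] > eps_svd)
  list(nu = as.integer(nu),
       U = sv$u[, seq_len(nu), drop = FALSE],
       sigma = sv$d[seq_len(nu)],
       V = sv$v[, seq_len(nu), drop = FALSE])
}

#' Optimal propagator and inhomogeneity of a window
#'
#' Closed-form solution of the unconstrained quadratic program
#' `min_{F, omega} || H1 - A H0 - omega 1^T ||_F^2` for the locally
#' linearized, inhomogeneous dynamics, with `A = U F U^T` restricted to the
#' leading `nu` proper orthogonal modes of `H0`. The optimum is
#' `F = Xbar10 Xbar0^{-1}` (time-delayed autocorrelation times inverse
#' covariance, both in the projected basis, column means removed) and
#' `omega = U (h1av_bar - F h0av_bar)`.
#'
#' @param window a [assemble_window()] result.
#' @param nu projection rank (defaults to [effective_rank()] of `H0`).
#' @param eps_svd threshold used when `nu` is not supplied.
#' @param cond_threshold condition-number threshold above which the
#'   covariance inverse is Tikhonov-regularized (ridge
#'   `1e-10 trace(Xbar0)/nu`), with a warning.
#' @return list with `F_hat` (nu x nu), `omega_hat` (length n), `Xbar0`,
#'   `Xbar10`, `U`, `h0av_bar`, `h1av_bar`, `residual_norm` (Frobenius norm
#'   of the fit residual) and `regularized` (logical).
#' @export
solve_fhat_omega <- function(window, nu = NULL, eps_svd = 0.05,
                             cond_threshold = 1e12) {
  stopifnot(inherits(window, "sliding_window"))
  sv0 <- svd(window$H0)
  if (is.null(nu)) nu <- sum(sv0$d / max(sv0$d, .Machine$double.xmin) > eps_svd)
  if (nu < 1) stop("degenerate window: dynamic dimensionality is zero")
  nu <- min(nu, sum(sv0$d > 0))
  U <- sv0$u[, seq_len(nu), drop = FALSE]
  N <- window$N

  Hbar0 <- crossprod(U, window$H0)          # nu x N
  Hbar1 <- crossprod(U, window$H1)
  h0av <- rowMeans(Hbar0)
  h1av <- rowMeans(Hbar1)
  Xbar10 <- tcrossprod(Hbar1, Hbar0) / N - tcrossprod(h1av, h0av)
  Xbar0 <- tcrossprod(Hbar0, Hbar0) / N - tcrossprod(h0av, h0av)

  sv <- svd(Xbar0)
  regularized <- FALSE
  cond <- if (min(sv$d) > 0) sv$d[1] / min(sv$d) else Inf
  if (!is.finite(cond) || cond > cond_threshold) {
    ridge <- 1e-10 * sum(diag(as.matrix(Xbar0))) / nu
    warning("covariance matrix ill-conditioned (cond = ",
            format(cond, digits = 3), "); applying ridge ",
            format(ridge, digits = 3))
    Xbar0_reg <- Xbar0 + ridge * diag(nu)
    Xinv <- solve(Xbar0_reg)
    regularized <- TRUE
  } else {
    keep <- sv$d / sv$d[1] > 1e-12
    Xinv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  F_hat <- Xbar10 %*% Xinv
  omega_bar <- h1av - as.numeric(F_hat %*% h0av)
  omega_hat <- as.numeric(U %*% omega_bar)

  resid <- window$H1 - U %*% (F_hat %*% Hbar0) - outer(omega_hat, rep(1, N))
  list(F_hat = F_hat, omega_hat = omega_hat,
       Xbar0 = Xbar0, Xbar10 = Xbar10, U = U,
       h0av_bar = h0av, h1av_bar = h1av,
       residual_norm = sqrt(sum(resid^2)), regularized = regularized)
}

#' Dominant eigenvalues and eigenmodes of a window propagator
#'
#' Eigen-decomposes the projected propagator `F_hat = Theta_bar Xi
#' Theta_bar^{-1}`; the discrete eigenvalues `mu_i` map to continuous decay
#' rates `lambda_i = log(mu_i) / dt` (principal branch), the dominant
#' eigenvalues of the local Jacobian. Modes are lifted to the species space
#' (`Theta = U Theta_bar`), ordered slowest first by `|Re lambda|` (ties by
#' ascending `|Im lambda|`), and each mode's sign/phase is fixed by making
#' its largest-magnitude entry positive real.
#'
#' @param F_hat projected propagator (nu x nu).
#' @param dt window sample spacing.
#' @param U proper orthogonal modes used for the projection (n x nu); if
#'   omitted, modes are reported in the projected basis.
#' @return list with `mu`, `lambda` (complex), `Theta_bar`, `Theta`, and
#'   `defective` (logical: eigenvector matrix numerically singular).
#' @export
dominant_spectrum <- function(F_hat, dt, U = NULL) {
  F_hat <- as.matrix(F_hat)
  stopifnot(nrow(F_hat) == ncol(F_hat), dt > 0)
  eg <- eigen(F_hat)
  mu <- eg$values
  Theta_bar <- eg$vectors
  keep <- Mod(mu) > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " mode(s) with zero discrete eigenvalue")
    mu <- mu[keep]
    Theta_bar <- Theta_bar[, keep, drop = FALSE]
  }
  lambda <- log(as.complex(mu)) / dt
  ord <- order(abs(Re(lambda)), abs(Im(lambda)))
  mu <- mu[ord]
  lambda <- lambda[ord]
  Theta_bar <- Theta_bar[, ord, drop = FALSE]
  Theta <- if (is.null(U)) Theta_bar else U %*% Theta_bar
  # deterministic phase: largest-magnitude entry of each mode positive real
  for (i in seq_along(mu)) {
    s <- Theta[which.max(Mod(Theta[, i])), i]
    if (Mod(s) > 0) {
      Theta[, i] <- Theta[, i] * Conj(s) / Mod(s)
      Theta_bar[, i] <- Theta_bar[, i] * Conj(s) / Mod(s)
    }
  }
  kap <- tryCatch(kappa(Theta_bar, exact = FALSE), error = function(e) Inf)
  defective <- !is.finite(kap) || kap > 1e10
  if (defective) warning("near-defective propagator (eigenvector condition ",
                         format(kap, digits = 3), ")")
  if (all(Im(mu) == 0)) {
    mu <- Re(mu); lambda <- as.complex(lambda)
    Theta <- Re(Theta); Theta_bar <- Re(Theta_bar)
  }
  list(mu = mu, lambda = lambda, Theta_bar = Theta_bar, Theta = Theta,
       defective = defective)
}

#' Optimal modal amplitudes
#'
#' Solves for the amplitudes `alpha` that best reconstruct the differential
#' data matrix `D = H1 - H0` as `Theta diag(alpha) Gamma`, with `Gamma` the
#' Vandermonde matrix of the discrete eigenvalues. Using `D` rather than
#' `H0`/`H1` removes the inhomogeneous offset from the fit. The solution is
#' the closed-form normal-equation system `L alpha = q` with
#' `L = (Theta* Theta) o conj(Gamma Gamma*)` and
#' `q = conj(diag(Gamma V S Theta_bar))` written via the SVD factors of
#' `D`; evaluated at full rank this is exactly the linear least-squares
#' minimizer of the Frobenius reconstruction error.
#'
#' @param window a [assemble_window()] result (supplies `D`).
#' @param mu discrete eigenvalues (length nu).
#' @param Theta dominant eigenmodes in species space (n x nu).
#' @return complex (or real) amplitude vector `alpha`; conjugate-pair modes
#'   receive conjugate amplitudes for real data.
#' @export
optimal_amplitudes <- function(window, mu, Theta) {
  stopifnot(inherits(window, "sliding_window"))
  D <- window$D
  if (max(abs(D)) == 0) stop("differential data matrix is identically zero")
  nu <- length(mu)
  N <- window$N
  Gamma <- t(vapply(seq_len(nu), function(i) mu[i]^(0:(N - 1)), complex(N)))
  L <- (Conj(t(Theta)) %*% Theta) * Conj(Gamma %*% Conj(t(Gamma)))
  q <- Conj(diag(Conj(t(Theta)) %*% D %*% Conj(t(Gamma))))
  alpha <- tryCatch(solve(L, q), error = function(e) {
    warning("ill-conditioned amplitude system; using least-squares solve")
    qr.solve(L, q)
  })
  if (all(Im(mu) == 0) && is.complex(alpha)) alpha <- Re(alpha)
  alpha
}

#' Modal and pooling matrices
#'
#' Scales the dominant eigenmodes by their optimal amplitudes
#' (`Phi = Theta diag(alpha)`) and defines the pooling matrix as the
#' Moore-Penrose inverse `P = pinv(Phi)`. The rows of `P` are the pooling
#' maps; `P Phi = I` expresses the reciprocal orthogonality between pooling
#' maps and eigenmodes. For a single mode, `P` is the normalized transpose
#' of the mode itself.
#'
#' @param Theta dominant eigenmodes (n x nu).
#' @param alpha amplitudes (length nu).
#' @return list with `Phi`, `P` and `rank_deficient` (TRUE when `Phi` lost
#'   column rank, in which case `P Phi != I`).
#' @export
modal_and_pooling <- function(Theta, alpha) {
  Theta <- as.matrix(Theta)
  nu <- length(alpha)
  stopifnot(ncol(Theta) == nu)
  Phi <- Theta %*% diag(alpha, nu)
  sv <- svd(Phi)
  tol <- max(dim(Phi)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  P <- sv$v[, seq_len(r), drop = FALSE] %*%
    (Conj(t(sv$u[, seq_len(r), drop = FALSE])) / sv$d[seq_len(r)])
  rank_deficient <- r < nu
  if (rank_deficient) warning("rank-deficient modal matrix: P Phi != I")
  list(Phi = Phi, P = P, rank_deficient = rank_deficient)
}

#' Decompose one sliding window
#'
#' Runs the full window pipeline: effective rank of `H0`, closed-form
#' propagator and inhomogeneity, dominant spectrum, optimal amplitudes,
#' modal and pooling matrices.
#'
#' @param window a [assemble_window()] result.
#' @param config a [dma_config()].
#' @return a list of class `window_modes`, or `NULL` for a degenerate
#'   (zero-signal) window.
#' @export
decompose_window <- function(window, config = dma_config()) {
  stopifnot(inherits(window, "sliding_window"))
  rk <- effective_rank(window$H0, config$eps_svd)
  if (rk$nu == 0L) return(NULL)
  fit <- solve_fhat_omega(window, nu = rk$nu,
                          cond_threshold = config$svd_cond_threshold)
  spec <- dominant_spectrum(fit$F_hat, window$dt, U = fit$U)
  alpha <- optimal_amplitudes(window, spec$mu, spec$Theta)
  mp <- modal_and_pooling(spec$Theta, alpha)
  structure(
    list(t1 = window$t1, t2 = window$t2, dt = window$dt, t_ref = window$t_ref,
         N = window$N, nu = rk$nu, sigma = rk$sigma,
         U = fit$U, F_hat = fit$F_hat, omega_hat = fit$omega_hat,
         Xbar0 = fit$Xbar0, Xbar10 = fit$Xbar10,
         mu = spec$mu, lambda = spec$lambda,
         Theta_bar = spec$Theta_bar, Theta = spec$Theta, alpha = alpha,
         Phi = mp$Phi, P = mp$P, species = window$species,
         residual_norm = fit$residual_norm,
         omega_norm = sqrt(sum(fit$omega_hat^2)),
         regularized = fit$regularized, defective = spec$defective,
         rank_deficient = mp$rank_deficient),
    class = "window_modes")
}

#' @export
print.window_modes <- function(x, ...) {
  cat(sprintf("<window_modes> [%g, %g]  nu = %d\n", x$t1, x$t2, x$nu))
  cat("  lambda:", paste(format(x$lambda, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized pooling maps of a window
#'
#' Rows of the pooling matrix scaled to unit maximum absolute coefficient
#' (sign chosen so the largest-magnitude coefficient is positive). Complex
#' rows from conjugate mode pairs are reported through their real part.
#'
#' @param wm a `window_modes` object (or any matrix of pooling rows).
#' @return a numeric matrix (nu x n) of normalized pooling maps.
#' @export
pooling_maps <- function(wm) {
  P <- if (inherits(wm, "window_modes")) wm$P else as.matrix(wm)
  Pr <- if (is.complex(P)) Re(P) else P
  out <- t(apply(Pr, 1, function(p) {
    s <- p[which.max(abs(p))]
    if (abs(s) > 0) p / s else p
  }))
  if (inherits(wm, "window_modes")) colnames(out) <- wm$species
  out
}
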