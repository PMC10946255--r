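#' Analysis configuration
#'
#' Collects every tunable threshold and sweep-geometry parameter of the
#' pipeline in one object.
#'
#' Threshold defaults, and why:
#' * `eps_svd` (0.05): a decay mode is counted as active in a window when its
#'   singular value exceeds 5% of the leading one. In a hierarchical network
#'   whose consecutive timescales are separated by about two orders of
#'   magnitude, a not-yet-active slower mode leaks roughly
#'   `|lambda_next| / |lambda_lead|` (about 1%) of the leading signal into
#'   the window, while a genuinely active mode in a transitory regime
#'   contributes tens of percent; 5% sits between the two regimes on a log
#'   scale.
#' * `eps_lambda` (0.3 decades): eigenvalues two orders of magnitude apart
#'   must always open a new interval; same-decade estimation jitter must not.
#' * `eps_rho` (0.05): pairwise correlations within 0.05 of +/-1 count as
#'   coherent.
#' * `eps_p` (0.05), `eps_inf` (1e-3): settledness tolerances for pool
#'   timescales and the total relaxation time.
#'
#' @param eps_svd relative singular-value threshold for the dynamic
#'   dimensionality.
#' @param eps_p pool-timescale settledness tolerance.
#' @param eps_rho coherence tolerance on `| |rho| - 1 |`.
#' @param eps_lambda interval-detection tolerance on shifts of
#'   `log10 |Re lambda|` between consecutive windows.
#' @param eps_inf total-relaxation-time tolerance (relative to each
#'   species' peak deviation).
#' @param window_width_factor window width as a fraction of its center time.
#' @param windows_per_decade sliding-window ladder density (geometric ratio
#'   `10^(1/windows_per_decade)` between centers).
#' @param N_samples number of snapshot columns per window (N; N+1 samples).
#' @param t_ref_rule linearization reference: `"left"` or `"midpoint"`.
#' @param perturbation named relative concentration bumps applied to the
#'   steady state before simulating; entries for species absent from the
#'   network are ignored. The default bumps the pathway's first and last
#'   metabolites by distinct positive amounts, plus the high-energy
#'   cofactor where one exists (an energy-load disturbance). Distinct
#'   same-sign magnitudes keep the disturbance clear of the symmetric and
#'   antisymmetric invariant subspaces that arise when boundary metabolites
#'   have near-equal steady concentrations, so every pool -- including the
#'   slowest conserved aggregate -- is excited.
#' @param seed integer seed for any stochastic component.
#' @param rtol,atol stiff-solver tolerances.
#' @param points_per_decade density of the simulated log-time output grid.
#' @param svd_cond_threshold covariance condition number above which the
#'   window solve is Tikhonov-regularized.
#' @param coeff_floor relative pooling-coefficient floor below which a
#'   species is not considered a member of a pool.
#' @param t_center_min optional explicit first window center.
#' @return a list of class `dma_config`.
#' @export
dma_config <- function(eps_svd = 0.05, eps_p = 0.05, eps_rho = 0.05,
                       eps_lambda = 0.3, eps_inf = 1e-3,
                       window_width_factor = 0.5, windows_per_decade = 8L,
                       N_samples = 40L,
                       t_ref_rule = c("left", "midpoint"),
                       perturbation = c(x1 = 0.2, x4 = 0.1, x5 = 0.1, x6 = -0.1),
                       seed = 1L, rtol = 1e-9, atol = 1e-12,
                       points_per_decade = 96L,
                       svd_cond_threshold = 1e12, coeff_floor = 0.05,
                       t_center_min = NULL) {
  t_ref_rule <- match.arg(t_ref_rule)
  cfg <- list(eps_svd = eps_svd, eps_p = eps_p, eps_rho = eps_rho,
              eps_lambda = eps_lambda, eps_inf = eps_inf,
              window_width_factor = window_width_factor,
              windows_per_decade = as.integer(windows_per_decade),
              N_samples = as.integer(N_samples), t_ref_rule = t_ref_rule,
              perturbation = perturbation, seed = as.integer(seed),
              rtol = rtol, atol = atol,
              points_per_decade = as.integer(points_per_decade),
              svd_cond_threshold = svd_cond_threshold,
              coeff_floor = coeff_floor, t_center_min = t_center_min)
  for (nm in c("eps_svd", "eps_p", "eps_rho", "eps_lambda", "eps_inf",
               "coeff_floor"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("'", nm, "' must lie in (0, 1)")
  if (cfg$N_samples < 4) stop("'N_samples' must be >= 4")
  if (cfg$window_width_factor <= 0 || cfg$window_width_factor >= 2)
    stop("'window_width_factor' must lie in (0, 2)")
  structure(cfg, class = "dma_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [dma_config()]; unknown keys raise an error
#' naming the offending key.
#'
#' @param path YAML config file.
#' @return a [dma_config()].
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(dma_config))
  bad <- setdiff(names(doc), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(doc$perturbation)) doc$perturbation <- unlist(doc$perturbation)
  do.call(dma_config, doc)
}
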