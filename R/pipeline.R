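#' Default simulation grid for a relaxation experiment
#'
#' Builds a logarithmic output time grid from the Jacobian spectrum at the
#' steady state: from about three decades below the fastest decay time to
#' well past the expected total relaxation time of the slowest mode.
#'
#' @param state a `deviation_state` (supplies the Jacobian).
#' @param config a [dma_config()].
#' @return numeric time grid starting at 0.
#' @export
relaxation_time_grid <- function(state, config = dma_config()) {
  ev <- eigen(state$jacobian, only.values = TRUE)$values
  rates <- abs(Re(ev))
  rates <- rates[rates > 0]
  t_min <- 1e-3 / max(rates)
  t_max <- 20 / min(rates)
  n_dec <- log10(t_max / t_min)
  c(0, 10^seq(log10(t_min), log10(t_max),
              length.out = ceiling(n_dec * config$points_per_decade) + 1))
}

.dma_core <- function(traj, config, x_ss = NULL) {
  sweep_tbl <- sweep_windows(traj, config)
  intervals <- detect_intervals(sweep_tbl, eps_lambda = config$eps_lambda)
  pools <- interval_pools(intervals, traj, config, x_ss = x_ss)
  structures <- purrr::map(seq_len(nrow(intervals)), function(k)
    coherent_structures(intervals[k, ], traj,
                        eps_rho = config$eps_rho,
                        coeff_floor = config$coeff_floor)) |>
    dplyr::bind_rows()
  list(windows = sweep_tbl, intervals = intervals, pools = pools,
       structures = structures, T_inf = attr(sweep_tbl, "T_inf"))
}

#' Run the full model-driven analysis pipeline
#'
#' Executes the complete chain: steady state, concentration perturbation,
#' stiff simulation of the relaxation, sliding-window decomposition sweep,
#' interval detection, pool extraction and coherence analysis.
#'
#' @param network a [reaction_network()] or the path of a model file.
#' @param config a [dma_config()] or the path of a YAML config file.
#' @param out_dir optional output directory; when given, the trajectory
#'   table, segmentation and coherence reports, run log and a MANIFEST are
#'   written there.
#' @return an object of class `dma_fit`: a list with `network`, `state`,
#'   `trajectory`, `windows`, `intervals`, `pools`, `structures`, `T_inf`
#'   and `config`.
#' @export
run_pipeline <- function(network, config = dma_config(), out_dir = NULL) {
  if (is.character(network)) network <- read_network(network)
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(network, "reaction_network"),
            inherits(config, "dma_config"))
  pert <- config$perturbation
  pert <- pert[names(pert) %in% network$species_names]
  if (length(pert) == 0)
    stop("no perturbation applies to this network's species")

  state <- find_steady_state(network)
  x0 <- perturb_state(state, pert)
  traj <- simulate_network(network, x0, relaxation_time_grid(state, config),
                           rtol = config$rtol, atol = config$atol)
  core <- .dma_core(traj, config, x_ss = state$x_ss)
  fit <- structure(c(list(network = network, state = state, trajectory = traj,
                          config = config), core),
                   class = "dma_fit")
  if (!is.null(out_dir)) write_dma_reports(fit, out_dir)
  fit
}

#' Analyze a concentration trajectory without a kinetic model
#'
#' The model-free entry point: runs the sliding-window sweep, interval
#' detection, pooling and coherence analysis directly on measured or
#' externally simulated time-series data. Deviations are taken with respect
#' to the trajectory tail.
#'
#' @param traj trajectory tibble or the path of a delimited trajectory
#'   table (first column `time`).
#' @param config a [dma_config()] or path of a YAML config file.
#' @param out_dir optional output directory for reports.
#' @return a `dma_fit` (without `network`/`state`).
#' @export
analyze_trajectory <- function(traj, config = dma_config(), out_dir = NULL) {
  if (is.character(traj)) traj <- read_trajectory(traj)
  if (is.character(config)) config <- read_config(config)
  .validate_trajectory(traj)
  core <- .dma_core(traj, config)
  fit <- structure(c(list(network = NULL, state = NULL, trajectory = traj,
                          config = config), core),
                   class = "dma_fit")
  if (!is.null(out_dir)) write_dma_reports(fit, out_dir)
  fit
}

#' @export
print.dma_fit <- function(x, ...) {
  cat("<dma_fit>\n")
  cat("  windows:  ", nrow(x$windows), "\n")
  cat("  intervals:", nrow(x$intervals), "\n")
  cat("  T_inf:    ", format(x$T_inf, digits = 4), "\n")
  inv <- x$intervals
  for (k in seq_len(nrow(inv)))
    cat(sprintf("  %2d [%10.3g, %10.3g] nu=%d %s\n", inv$interval[k],
                inv$t_start[k], inv$t_end[k], inv$nu[k],
                inv$transition_kind[k]))
  invisible(x)
}

# report serialization ---------------------------------------------------

.fmt_complex <- function(z) {
  if (is.complex(z)) sprintf("%.17g%+.17gi", Re(z), Im(z))
  else sprintf("%.17g", z)
}

#' Write analysis reports
#'
#' Writes the trajectory table, a segmentation report (one YAML record per
#' interval: bounds, dimensionality, eigenvalues, pooling rows, transition
#' kind), a coherence report, a pool table, a run log with all effective
#' parameters, and a MANIFEST marking completeness.
#'
#' @param fit a `dma_fit`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dma_reports <- function(fit, out_dir) {
  stopifnot(inherits(fit, "dma_fit"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  add <- function(f) manifest <<- c(manifest, f)

  write_trajectory(fit$trajectory, file.path(out_dir, "trajectory.tsv"))
  add("trajectory.tsv")

  con <- file(file.path(out_dir, "segmentation.yaml"), "w")
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("T_inf: ", sprintf("%.17g", fit$T_inf))
  w("intervals:")
  for (k in seq_len(nrow(fit$intervals))) {
    iv <- fit$intervals[k, ]
    w("  - interval: ", iv$interval)
    w("    t_start: ", sprintf("%.17g", iv$t_start))
    w("    t_end: ", sprintf("%.17g", iv$t_end))
    w("    nu: ", iv$nu)
    w("    transition: ", iv$transition_kind)
    w("    lambda: [", paste(.fmt_complex(iv$lambda[[1]]), collapse = ", "), "]")
    w("    pooling:")
    Pm <- iv$pooling[[1]]
    for (i in seq_len(nrow(Pm)))
      w("      - [", paste(sprintf("%.17g", Pm[i, ]), collapse = ", "), "]")
  }
  close(con)
  add("segmentation.yaml")

  con <- file(file.path(out_dir, "coherence.yaml"), "w")
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("structures:")
  if (nrow(fit$structures) == 0) w("  []")
  for (k in seq_len(nrow(fit$structures))) {
    s <- fit$structures[k, ]
    w("  - interval: ", s$interval)
    w("    members: [", paste(s$members[[1]], collapse = ", "), "]")
    w("    signs: [", paste(s$signs[[1]], collapse = ", "), "]")
    w("    min_abs_rho: ", sprintf("%.17g", s$min_abs_rho))
  }
  close(con)
  add("coherence.yaml")

  pools <- fit$pools
  con <- file(file.path(out_dir, "pools.tsv"), "w")
  species <- .traj_species(fit$trajectory)
  cat(paste(c("interval", "pool", "timescale", "scale", "resolved", species),
            collapse = "\t"), "\n", sep = "", file = con)
  for (k in seq_len(nrow(pools)))
    cat(paste(c(pools$interval[k], pools$pool[k],
                sprintf("%.17g", pools$timescale[k]),
                sprintf("%.17g", pools$scale[k]), pools$resolved[k],
                sprintf("%.17g", pools$coefficients[[k]])), collapse = "\t"),
        "\n", sep = "", file = con)
  close(con)
  add("pools.tsv")

  con <- file(file.path(out_dir, "run_log.yaml"), "w")
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("config:")
  for (nm in names(fit$config)) {
    val <- fit$config[[nm]]
    if (is.null(val)) next
    if (length(val) > 1 || !is.null(names(val)))
      w("  ", nm, ": {",
        paste(sprintf("%s: %.17g", names(val), as.numeric(val)),
              collapse = ", "), "}")
    else if (is.numeric(val)) w("  ", nm, ": ", sprintf("%.17g", val))
    else w("  ", nm, ": ", as.character(val))
  }
  w("windows:")
  for (k in seq_len(nrow(fit$windows)))
    w("  - {t1: ", sprintf("%.17g", fit$windows$t1[k]),
      ", t2: ", sprintf("%.17g", fit$windows$t2[k]),
      ", nu: ", fit$windows$nu[k],
      ", omega_norm: ", sprintf("%.17g", fit$windows$omega_norm[k]),
      ", residual: ", sprintf("%.17g", fit$windows$residual_norm[k]), "}")
  close(con)
  add("run_log.yaml")

  writeLines(c("complete: true", paste0("- ", manifest)),
             file.path(out_dir, "MANIFEST"))
  invisible(out_dir)
}
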