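#' Total relaxation time of a trajectory
#'
#' The earliest grid time after which every species' deviation from its
#' settled value stays below `eps_inf` relative to that species' peak
#' deviation. The settled state is estimated from the trajectory tail (its
#' final sample), so the operation is purely data-driven.
#'
#' @param traj trajectory tibble.
#' @param eps_inf relative settledness tolerance.
#' @param x_ss optional known steady state (named vector); defaults to the
#'   final trajectory sample.
#' @return the relaxation time (scalar). The attribute `resolved` is `FALSE`
#'   when the criterion is never met, in which case the trajectory end time
#'   is returned.
#' @export
total_relaxation_time <- function(traj, eps_inf = 1e-3, x_ss = NULL) {
  .validate_trajectory(traj)
  X <- .traj_matrix(traj)
  ref <- if (is.null(x_ss)) X[nrow(X), ] else x_ss[colnames(X)]
  Chi <- abs(sweep(X, 2, ref))
  peak <- apply(Chi, 2, max)
  active <- peak > 0
  if (!any(active)) {
    out <- traj$time[1]
    attr(out, "resolved") <- TRUE
    return(out)
  }
  R <- sweep(Chi[, active, drop = FALSE], 2, peak[active], "/")
  ok <- apply(R, 1, max) < eps_inf
  # with a tail-estimated settled state the last sample always satisfies the
  # criterion trivially; the trajectory only counts as resolved if its tail
  # has actually stopped moving
  i_mid <- which.min(abs(traj$time - traj$time[nrow(X)] / 2))
  tail_moved <- abs(X[nrow(X), ] - X[i_mid, ]) / pmax(peak, .Machine$double.xmin)
  tail_settled <- all(tail_moved[active] < eps_inf)
  # settled from some row onward
  settled_from <- rev(cumprod(rev(ok))) > 0
  if (!any(settled_from) || !tail_settled) {
    out <- traj$time[nrow(X)]
    attr(out, "resolved") <- FALSE
    return(out)
  }
  out <- traj$time[which(settled_from)[1]]
  attr(out, "resolved") <- TRUE
  out
}

#' Scalar pool trajectory
#'
#' Projects a trajectory onto a pooling map: `pi(t) = p^T x(t)`, or
#' `p^T chi(t)` in deviation form (deviations taken with respect to the
#' trajectory tail unless a steady state is supplied).
#'
#' @param p pooling-map coefficient vector (length = number of species,
#'   optionally named).
#' @param traj trajectory tibble.
#' @param use_deviations project deviations `chi = x - x_ss` instead of
#'   concentrations.
#' @param x_ss optional steady state for the deviation form.
#' @return tibble with columns `time` and `pi`.
#' @export
pool_trajectory <- function(p, traj, use_deviations = FALSE, x_ss = NULL) {
  .validate_trajectory(traj)
  X <- .traj_matrix(traj)
  if (length(p) != ncol(X))
    stop("pooling map length ", length(p), " != number of species ", ncol(X))
  if (!is.null(names(p))) p <- p[colnames(X)]
  if (use_deviations) {
    ref <- if (is.null(x_ss)) X[nrow(X), ] else x_ss[colnames(X)]
    X <- sweep(X, 2, ref)
  }
  tibble::tibble(time = traj$time, pi = as.numeric(X %*% as.numeric(p)))
}

#' Pool timescale
#'
#' The smallest time `T` such that `|pi(t) - pi(inf)| < eps_p * C` for all
#' `t >= T`, with `pi(inf)` the value at the final trajectory time and `C`
#' the peak excursion `max_t |pi(t) - pi(inf)|` (the concentration scale of
#' the pool).
#'
#' @param time time grid.
#' @param pi_t scalar pool trajectory on that grid.
#' @param eps_p settledness tolerance.
#' @param scale optional explicit concentration scale `C`.
#' @return list with `timescale`, `scale`, and `resolved` (`FALSE` when the
#'   tail of the pool has not settled).
#' @export
pool_timescale <- function(time, pi_t, eps_p = 0.05, scale = NULL) {
  stopifnot(length(time) == length(pi_t), eps_p > 0)
  pinf <- pi_t[length(pi_t)]
  dev <- abs(pi_t - pinf)
  C <- if (is.null(scale)) max(dev) else scale
  if (C == 0) return(list(timescale = time[1], scale = 0, resolved = TRUE))
  half <- which.min(abs(time - time[length(time)] / 2))
  resolved <- abs(pi_t[length(pi_t)] - pi_t[half]) <= eps_p * C
  ok <- dev < eps_p * C
  settled_from <- rev(cumprod(rev(ok))) > 0
  Tp <- if (any(settled_from)) time[which(settled_from)[1]] else time[length(time)]
  list(timescale = Tp, scale = C, resolved = resolved && any(settled_from))
}

#' Sweep the window decomposition along a trajectory
#'
#' Places sliding windows on a logarithmic time ladder (geometric ratio
#' `10^(1/windows_per_decade)` between centers, width
#' `window_width_factor * t_center`) from the earliest resolvable center up
#' to the total relaxation time, and decomposes each window. Degenerate
#' (zero-signal) windows are skipped.
#'
#' @param traj trajectory tibble covering the relaxation.
#' @param config a [dma_config()].
#' @return a tibble with one row per window: `window`, `t_center`, `t1`,
#'   `t2`, `nu`, `lambda` (list), `omega_norm`, `residual_norm` and the full
#'   `modes` object (list column). The attribute `T_inf` records the total
#'   relaxation time used.
#' @export
sweep_windows <- function(traj, config = dma_config()) {
  .validate_trajectory(traj)
  w <- config$window_width_factor
  T_inf <- as.numeric(total_relaxation_time(traj, config$eps_inf))
  t_end <- traj$time[nrow(traj)]
  tpos <- traj$time[traj$time > 0]
  t_c_min <- if (!is.null(config$t_center_min)) config$t_center_min
             else tpos[2] / (1 - w / 2)
  t_c_max <- min(T_inf, t_end / (1 + w / 2))
  if (t_c_min >= t_c_max)
    stop("trajectory is too short to place any analysis window")
  ratio <- 10^(1 / config$windows_per_decade)
  n_win <- floor(log(t_c_max / t_c_min) / log(ratio))
  centers <- t_c_min * ratio^(0:n_win)

  rows <- purrr::map(centers, function(tc) {
    t1 <- tc * (1 - w / 2)
    t2 <- tc * (1 + w / 2)
    win <- assemble_window(traj, t1, t2, N = config$N_samples,
                           t_ref_rule = config$t_ref_rule)
    wm <- decompose_window(win, config)
    if (is.null(wm)) return(NULL)
    tibble::tibble(t_center = tc, t1 = t1, t2 = t2, nu = wm$nu,
                   lambda = list(wm$lambda), omega_norm = wm$omega_norm,
                   residual_norm = wm$residual_norm, modes = list(wm))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("all windows were degenerate")
  out <- dplyr::mutate(out, window = dplyr::row_number(), .before = 1)
  attr(out, "T_inf") <- T_inf
  out
}

# log10 |Re lambda| with a floor to keep zero real parts finite
.log_rate <- function(lambda) log10(pmax(abs(Re(lambda)), 1e-300))

#' Detect characteristic time intervals
#'
#' Partitions the relaxation into contiguous intervals by walking the window
#' sweep: a new interval opens when the dynamic dimensionality `nu` changes
#' between consecutive windows (`dimensionality_change`), or when `nu` is
#' unchanged but the matched dominant decay rates shift by more than
#' `eps_lambda` in `log10 |Re lambda|` (`spectrum_change`). A spectrum
#' change is only recorded when the preceding pair of windows agreed (the
#' eigenvalue set was settled): immediately after a dimensionality change
#' the reduced-rank eigenvalue estimate still carries a decaying imprint of
#' the mode that just dropped out, and that settling tail belongs to the
#' new interval, not to a further transition. Boundaries are placed at the
#' geometric midpoint between the flanking window centers, and the
#' intervals tile `[0, T_inf]`.
#'
#' @param sweep_result a [sweep_windows()] tibble.
#' @param eps_lambda tolerance in decades on matched decay-rate shifts.
#' @param T_inf total relaxation time (defaults to the sweep attribute).
#' @return a tibble with one row per interval: `interval`, `t_start`,
#'   `t_end`, `nu`, `transition_kind` (how the interval opened), `lambda`
#'   (list), `pooling` (list of normalized pooling-map matrices) and
#'   `modes` (representative `window_modes`, list column).
#' @export
detect_intervals <- function(sweep_result, eps_lambda = 0.3, T_inf = NULL) {
  stopifnot(is.data.frame(sweep_result), nrow(sweep_result) >= 2)
  if (is.null(T_inf)) T_inf <- attr(sweep_result, "T_inf")
  if (is.null(T_inf)) T_inf <- sweep_result$t2[nrow(sweep_result)]
  n <- nrow(sweep_result)
  kind <- character(0)
  breaks <- integer(0)
  pair_settled <- function(i) {
    if (i < 2) return(TRUE)
    if (sweep_result$nu[i] != sweep_result$nu[i - 1]) return(FALSE)
    shift <- abs(.log_rate(sweep_result$lambda[[i]]) -
                   .log_rate(sweep_result$lambda[[i - 1]]))
    all(shift <= eps_lambda)
  }
  for (i in 2:n) {
    prev <- sweep_result$lambda[[i - 1]]
    cur <- sweep_result$lambda[[i]]
    if (sweep_result$nu[i] != sweep_result$nu[i - 1]) {
      breaks <- c(breaks, i)
      kind <- c(kind, "dimensionality_change")
    } else {
      # both sorted slowest-first; match rank-to-rank
      shift <- abs(.log_rate(cur) - .log_rate(prev))
      if (any(shift > eps_lambda) && pair_settled(i - 1)) {
        breaks <- c(breaks, i)
        kind <- c(kind, "spectrum_change")
      }
    }
  }
  starts <- c(1L, breaks)
  ends <- c(breaks - 1L, n)
  t_bounds <- c(0, sqrt(sweep_result$t_center[breaks - 1L] *
                          sweep_result$t_center[breaks]), T_inf)
  rows <- purrr::map(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    rep_idx <- idx[ceiling(length(idx) / 2)]
    wm <- sweep_result$modes[[rep_idx]]
    tibble::tibble(
      interval = k, t_start = t_bounds[k], t_end = t_bounds[k + 1],
      nu = sweep_result$nu[rep_idx],
      transition_kind = if (k == 1) "start" else kind[k - 1],
      n_windows = length(idx),
      lambda = list(wm$lambda),
      pooling = list(pooling_maps(wm)),
      modes = list(wm))
  })
  dplyr::bind_rows(rows)
}

#' Pool table for detected intervals
#'
#' Expands the pooling maps of every interval into one row per pool:
#' normalized coefficients, the scalar pool trajectory's timescale and
#' concentration scale, and a resolved flag.
#'
#' @param intervals a [detect_intervals()] tibble.
#' @param traj the analyzed trajectory.
#' @param config a [dma_config()].
#' @param x_ss optional steady state for the deviation form.
#' @return tibble with columns `interval`, `pool`, `timescale`, `scale`,
#'   `resolved`, `coefficients` (list of named numeric vectors).
#' @export
interval_pools <- function(intervals, traj, config = dma_config(), x_ss = NULL) {
  rows <- purrr::map(seq_len(nrow(intervals)), function(k) {
    Pm <- intervals$pooling[[k]]
    purrr::map(seq_len(nrow(Pm)), function(i) {
      p <- Pm[i, ]
      pit <- pool_trajectory(p, traj, use_deviations = TRUE, x_ss = x_ss)
      ts <- pool_timescale(pit$time, pit$pi, eps_p = config$eps_p)
      tibble::tibble(interval = intervals$interval[k], pool = i,
                     timescale = ts$timescale, scale = ts$scale,
                     resolved = ts$resolved, coefficients = list(p))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
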