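#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the interval table of a fitted decomposition
#'
#' One row per (interval, mode): interval bounds, dynamic dimensionality,
#' transition kind, and the mode's continuous eigenvalue split into decay
#' rate and oscillation frequency (for conjugate pairs, the decay time is
#' `1/|Re lambda|` and the period `2 pi / |Im lambda|`).
#'
#' @param x a `dma_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy dma_fit
#' @export
tidy.dma_fit <- function(x, ...) {
  purrr::map(seq_len(nrow(x$intervals)), function(k) {
    iv <- x$intervals[k, ]
    lam <- iv$lambda[[1]]
    tibble::tibble(
      interval = iv$interval, t_start = iv$t_start, t_end = iv$t_end,
      nu = iv$nu, transition_kind = iv$transition_kind,
      mode = seq_along(lam),
      decay_rate = -Re(lam),
      frequency = abs(Im(lam)),
      decay_time = 1 / pmax(abs(Re(lam)), .Machine$double.xmin),
      period = ifelse(Im(lam) != 0, 2 * pi / abs(Im(lam)), Inf))
  }) |> dplyr::bind_rows()
}

#' One-line summary of a fitted decomposition
#'
#' @param x a `dma_fit`.
#' @param ... unused.
#' @return a one-row tibble with `n_windows`, `n_intervals`,
#'   `n_structures`, `T_inf`, `max_pooling_identity_dev` (worst deviation
#'   of `P Phi` from the identity over all windows) and
#'   `max_omega_norm`.
#' @method glance dma_fit
#' @export
glance.dma_fit <- function(x, ...) {
  dev <- vapply(x$windows$modes, function(wm)
    verify_reciprocal_orthogonality(wm$P, wm$Phi)$max_identity_deviation,
    numeric(1))
  tibble::tibble(
    n_windows = nrow(x$windows),
    n_intervals = nrow(x$intervals),
    n_structures = nrow(x$structures),
    T_inf = x$T_inf,
    max_pooling_identity_dev = max(dev),
    max_omega_norm = max(x$windows$omega_norm))
}

#' Plot a fitted decomposition
#'
#' `type = "trajectory"`: absolute concentration deviations on log-log axes
#' with interval boundaries; `type = "dimensionality"`: the dynamic
#' dimensionality staircase along the window ladder; `type = "pools"`:
#' normalized pooling-map coefficients per interval.
#'
#' @param object a `dma_fit`.
#' @param type one of `"trajectory"`, `"dimensionality"`, `"pools"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dma_fit
#' @export
autoplot.dma_fit <- function(object,
                             type = c("trajectory", "dimensionality", "pools"),
                             ...) {
  type <- match.arg(type)
  bounds <- object$intervals$t_end[-nrow(object$intervals)]
  if (type == "trajectory") {
    traj <- object$trajectory
    ref <- if (!is.null(object$state)) object$state$x_ss
           else .traj_matrix(traj)[nrow(traj), ]
    X <- abs(sweep(.traj_matrix(traj), 2, ref))
    df <- tibble::as_tibble(as.data.frame(X))
    df$time <- traj$time
    long <- tidyr::pivot_longer(df, -"time", names_to = "species",
                                values_to = "deviation")
    long <- dplyr::filter(long, .data$time > 0, .data$deviation > 0)
    ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$deviation,
                                       color = .data$species)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                          color = "grey40") +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "time", y = "|x - x_ss|")
  } else if (type == "dimensionality") {
    ggplot2::ggplot(object$windows,
                    ggplot2::aes(.data$t_center, .data$nu)) +
      ggplot2::geom_step() +
      ggplot2::geom_vline(xintercept = bounds, linetype = "dashed",
                          color = "grey40") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "window center time", y = "dynamic dimensionality")
  } else {
    rows <- purrr::map(seq_len(nrow(object$intervals)), function(k) {
      Pm <- object$intervals$pooling[[k]]
      tibble::tibble(interval = object$intervals$interval[k],
                     pool = rep(seq_len(nrow(Pm)), each = ncol(Pm)),
                     species = rep(colnames(Pm), nrow(Pm)),
                     coefficient = as.numeric(t(Pm)))
    }) |> dplyr::bind_rows()
    ggplot2::ggplot(rows, ggplot2::aes(.data$species, .data$coefficient,
                                       fill = factor(.data$pool))) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~interval) +
      ggplot2::labs(fill = "pool")
  }
}

#' @importFrom rlang .data
NULL
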