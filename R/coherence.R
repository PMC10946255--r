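#' Time-averaged correlation of two concentration trajectories
#'
#' Pearson-type correlation of two time-dependent signals over `[t1, t2]`,
#' with expectations defined as time-average integrals
#' `E(f) = 1/(t2 - t1) * integral of f` evaluated by trapezoidal quadrature
#' on the native grid.
#'
#' @param traj trajectory tibble.
#' @param species_i,species_j species column names (or numeric indices).
#' @param t1,t2 integration bounds (default: whole trajectory).
#' @param use_deviations correlate deviations from the trajectory tail
#'   instead of raw concentrations (affects nothing but numerical scale:
#'   correlation is shift-invariant).
#' @return the correlation in `[-1, 1]`, or `NA` (flagged undefined) when
#'   either signal has zero variance on the interval.
#' @export
trajectory_correlation <- function(traj, species_i, species_j,
                                   t1 = NULL, t2 = NULL,
                                   use_deviations = FALSE) {
  .validate_trajectory(traj)
  species <- .traj_species(traj)
  if (is.numeric(species_i)) species_i <- species[species_i]
  if (is.numeric(species_j)) species_j <- species[species_j]
  if (is.null(t1)) t1 <- traj$time[1]
  if (is.null(t2)) t2 <- traj$time[nrow(traj)]
  sel <- traj$time >= t1 & traj$time <= t2
  if (sum(sel) < 3) stop("fewer than 3 samples in [t1, t2]")
  tt <- traj$time[sel]
  xi <- traj[[species_i]][sel]
  xj <- traj[[species_j]][sel]
  if (use_deviations) {
    xi <- xi - traj[[species_i]][nrow(traj)]
    xj <- xj - traj[[species_j]][nrow(traj)]
  }
  .time_correlation(tt, xi, xj)
}

# trapezoidal time-average
.trapz_mean <- function(tt, f) {
  dt <- diff(tt)
  sum((f[-1] + f[-length(f)]) / 2 * dt) / (tt[length(tt)] - tt[1])
}

.time_correlation <- function(tt, xi, xj) {
  Ei <- .trapz_mean(tt, xi)
  Ej <- .trapz_mean(tt, xj)
  vi <- .trapz_mean(tt, xi^2) - Ei^2
  vj <- .trapz_mean(tt, xj^2) - Ej^2
  if (vi <= 0 || vj <= 0) return(NA_real_)
  rho <- (.trapz_mean(tt, xi * xj) - Ei * Ej) / sqrt(vi * vj)
  max(-1, min(1, rho))
}

#' Coherent structures within a time interval
#'
#' A coherent structure is a subset of pooled metabolites whose pairwise
#' concentration correlations stay within `eps_rho` of +/-1 over the
#' interval, with a transitively consistent sign pattern (negative as well
#' as positive coherence is admitted, so `| |rho| - 1 | < eps_rho` is the
#' pairwise criterion and the sign of each pair is recorded).
#'
#' Candidate members are the species whose pooling-map coefficient magnitude
#' exceeds `coeff_floor` relative to the largest coefficient in any pooling
#' row of the interval. Structures are grown greedily inside the connected
#' components of the thresholded `|rho|` graph: starting from the
#' strongest-correlated pair, members are added while every pair in the set
#' still meets the criterion.
#'
#' @param interval one row of a [detect_intervals()] tibble (or a list with
#'   `t_start`, `t_end`, `pooling`, `interval`).
#' @param traj trajectory tibble.
#' @param eps_rho coherence tolerance.
#' @param coeff_floor relative pooling-coefficient floor for candidacy.
#' @return tibble with one row per structure: `interval`, `structure`,
#'   `members` (list of species names), `signs` (list: +/-1 per member,
#'   relative to the first member), `min_abs_rho`, `rho` (list: the pairwise
#'   correlation matrix).
#' @export
coherent_structures <- function(interval, traj, eps_rho = 0.05,
                                coeff_floor = 0.05) {
  .validate_trajectory(traj)
  if (is.data.frame(interval)) interval <- as.list(interval[1, ])
  Pm <- interval$pooling
  if (is.list(Pm) && !is.matrix(Pm)) Pm <- Pm[[1]]
  species <- colnames(Pm)
  if (is.null(species)) species <- .traj_species(traj)

  weight <- apply(abs(Pm), 2, max)
  cand <- species[weight >= coeff_floor * max(weight)]
  empty <- tibble::tibble(interval = integer(), structure = integer(),
                          members = list(), signs = list(),
                          min_abs_rho = numeric(), rho = list())
  if (length(cand) < 2) return(empty)

  t1 <- max(interval$t_start, traj$time[1])
  t2 <- min(interval$t_end, traj$time[nrow(traj)])
  nc <- length(cand)
  rho <- matrix(NA_real_, nc, nc, dimnames = list(cand, cand))
  for (i in seq_len(nc)) {
    rho[i, i] <- 1
    for (j in seq_len(nc)) if (j > i) {
      r <- trajectory_correlation(traj, cand[i], cand[j], t1, t2)
      rho[i, j] <- r
      rho[j, i] <- r
    }
  }
  coh <- !is.na(rho) & abs(abs(rho) - 1) < eps_rho
  diag(coh) <- FALSE

  structures <- list()
  remaining <- seq_len(nc)
  repeat {
    pairs <- which(coh[remaining, remaining, drop = FALSE], arr.ind = TRUE)
    if (nrow(pairs) == 0) break
    # seed with the strongest remaining coherent pair
    absr <- abs(rho[remaining, remaining, drop = FALSE])
    absr[!coh[remaining, remaining, drop = FALSE]] <- -Inf
    seed <- which(absr == max(absr), arr.ind = TRUE)[1, ]
    set <- remaining[c(seed[1], seed[2])]
    repeat {
      cand_add <- setdiff(remaining, set)
      ok_add <- cand_add[vapply(cand_add, function(a)
        all(coh[a, set]), logical(1))]
      if (length(ok_add) == 0) break
      scores <- vapply(ok_add, function(a) min(abs(rho[a, set])), numeric(1))
      set <- c(set, ok_add[which.max(scores)])
    }
    # sign pattern relative to the first member; verify transitivity
    signs <- sign(rho[set[1], set])
    signs[1] <- 1
    consistent <- all(outer(signs, signs) * sign(rho[set, set]) >= 0,
                      na.rm = TRUE)
    if (consistent)
      structures[[length(structures) + 1]] <-
        list(members = cand[set], signs = signs,
             min_abs_rho = min(abs(rho[set, set])),
             rho = rho[set, set, drop = FALSE])
    remaining <- setdiff(remaining, set)
    if (length(remaining) < 2) break
  }
  if (length(structures) == 0) return(empty)
  dplyr::bind_rows(purrr::imap(structures, function(s, k)
    tibble::tibble(interval = interval$interval %||% NA_integer_,
                   structure = k, members = list(s$members),
                   signs = list(s$signs), min_abs_rho = s$min_abs_rho,
                   rho = list(s$rho))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
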