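# shared fixtures built in code

# wrap paired snapshot matrices in a sliding_window shell (dt = 1 grid)
fake_window <- function(H0, H1, dt = 1) {
  structure(list(t1 = 0, t2 = ncol(H0) * dt, N = ncol(H0), dt = dt,
                 t_ref = 0, x_ref = rep(0, nrow(H0)),
                 H0 = H0, H1 = H1, D = H1 - H0,
                 species = paste0("s", seq_len(nrow(H0)))),
            class = "sliding_window")
}

# trajectory tibble from a function of time
traj_from_fun <- function(tt, ...) {
  funs <- list(...)
  out <- tibble::tibble(time = tt)
  for (nm in names(funs)) out[[nm]] <- funs[[nm]](tt)
  out
}

# exact deviation trajectory of a linear network: chi(t) = Exp(Jt) chi0,
# sampled on the given grid (matrix-exponential oracle, no ODE solver)
linear_deviation_traj <- function(J, chi0, x_ss, tt, species) {
  X <- t(vapply(tt, function(t)
    x_ss + as.numeric(Matrix::expm(J * t) %*% chi0), numeric(length(chi0))))
  colnames(X) <- species
  dplyr::bind_cols(tibble::tibble(time = tt), tibble::as_tibble(X))
}

# cached expensive end-to-end fits (built once per test run)
toy1_fit_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- run_pipeline(build_toy_model_1())
    val
  }
})

toy2_fit_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- run_pipeline(build_toy_model_2())
    val
  }
})
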