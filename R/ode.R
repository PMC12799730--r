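#' Time derivatives of the seven species
#'
#' Mass-action kinetics of the translation network. Charging converts
#' uncharged to charged tRNA at `k_charge * T_ui`; elongation from class `i`
#' consumes charged tRNA at `k_speed * R_bi * T_ci`. Free ribosomes are
#' depleted by initiation (`k_bind_eff * N * R_f`) and replenished by
#' termination (`k_speed * (R_b1*T_c1 + R_b2*T_c2) / L`). An elongation event
#' on class `i` terminates with probability `1/L`; otherwise the ribosome
#' re-lands on an optimal codon with probability `f_op`, so the bound classes
#' gain initiation flux split by composition, lose termination flux, and
#' exchange the remaining conversion flux. Both ribosome and per-species tRNA
#' totals are conserved exactly (the derivative sums vanish identically), and
#' the stationary point of this system is precisely the [steady_state()]
#' solution.
#'
#' @param state A state (one-row tibble, named vector, or `codon_steady`).
#' @param params A `codon_params` object.
#' @return Named numeric vector of derivatives for
#'   `T_c1, T_c2, T_u1, T_u2, R_f, R_b1, R_b2` (molecules/s).
#' @export
ode_rhs <- function(state, params) {
  v <- as_state_vector(state)
  ks <- params$k_speed
  f <- params$f_op
  L <- params$L
  x1 <- v[["R_b1"]] * v[["T_c1"]]
  x2 <- v[["R_b2"]] * v[["T_c2"]]
  init_flux <- params$k_bind_eff * params$N * v[["R_f"]]
  dTc1 <- params$k_charge * v[["T_u1"]] - ks * x1
  dTc2 <- params$k_charge * v[["T_u2"]] - ks * x2
  dRf <- ks * (x1 + x2) / L - init_flux
  keep <- 1 - 1 / L
  dRb1 <- init_flux * f + keep * ks * x2 * f -
    ks * x1 * (1 / L + keep * (1 - f))
  dRb2 <- init_flux * (1 - f) + keep * ks * x1 * (1 - f) -
    ks * x2 * (1 / L + keep * f)
  c(T_c1 = dTc1, T_c2 = dTc2, T_u1 = -dTc1, T_u2 = -dTc2,
    R_f = dRf, R_b1 = dRb1, R_b2 = dRb2)
}

#' Deterministic time course
#'
#' Integrates the mean-field kinetics with [deSolve::ode()] (lsoda) from a
#' given initial condition, recording the state at each requested time and
#' accumulating the produced protein (the integral of the termination flux).
#'
#' @param params A `codon_params` object.
#' @param times Non-decreasing vector of output times (seconds) starting at
#'   the initial time.
#' @param init Initial state; defaults to [initial_state()] (all tRNAs
#'   charged, all ribosomes free). Must satisfy the conserved totals.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `codon_trajectory` with columns `time`, the 7
#'   species, and cumulative `protein`.
#' @examples
#' p <- load_reference_params("baseline")
#' tc <- simulate_deterministic(p, times = seq(0, 100, 1))
#' @export
simulate_deterministic <- function(params, times, init = initial_state(params),
                                   rtol = 1e-10, atol = 1e-8) {
  validate_params(params)
  v <- check_state_consistent(init, params)
  if (length(times) < 1 || is.unsorted(times)) {
    stop("times must be a non-decreasing vector", call. = FALSE)
  }
  if (length(times) == 1) {
    out <- tibble::as_tibble(as.list(v))
    out <- tibble::add_column(out, time = times, .before = 1)
    out$protein <- 0
    return(structure(out, class = c("codon_trajectory", class(out))))
  }
  deriv <- function(t, y, parms) {
    d <- ode_rhs(y[species_names()], params)
    protein_flux <- params$k_speed *
      (y[["R_b1"]] * y[["T_c1"]] + y[["R_b2"]] * y[["T_c2"]]) / params$L
    list(c(d, protein = protein_flux))
  }
  sol <- deSolve::ode(
    y = c(v, protein = 0), times = times, func = deriv, parms = NULL,
    rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    stop(sprintf("ODE integration failed; last good time %.6g s",
                 max(sol[, "time"])), call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  check_trajectory_conservation(out, params)
  structure(out, class = c("codon_trajectory", class(out)))
}

check_trajectory_conservation <- function(traj, params, rel_tol = 1e-8) {
  dev <- max(
    abs(traj$T_c1 + traj$T_u1 - params$T1_tot) / max(params$T1_tot, 1),
    abs(traj$T_c2 + traj$T_u2 - params$T2_tot) / max(params$T2_tot, 1),
    abs(traj$R_f + traj$R_b1 + traj$R_b2 - params$R_tot) / params$R_tot
  )
  if (dev > rel_tol) {
    stop(sprintf("conservation violated along trajectory (relative %.2e)", dev),
         call. = FALSE)
  }
  invisible(dev)
}
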