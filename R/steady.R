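#' Solve the steady state of the two-codon system
#'
#' Finds the unique stationary point of the translation network: charging of
#' each tRNA pool balances its consumption by elongation, ribosome initiation
#' balances termination, and the two bound-ribosome classes exchange at rates
#' proportional to the codon composition.
#'
#' The solve exploits an exact reduction to one unknown. Writing
#' `x_i = R_bi * T_ci` for the per-class elongation flux (divided by
#' `k_speed`), the codon-exchange balance forces `x1 = f_op * S` and
#' `x2 = (1 - f_op) * S` where `S = x1 + x2`. The charging balances then give
#' `T_ci = Ti_tot - x_i * k_speed / k_charge`, and the initiation/termination
#' balance becomes a scalar equation `g(S) = 0` with `g` strictly decreasing
#' on its domain, so the root is unique and bracketed. It is located with
#' [stats::uniroot()] and polished by Newton steps to machine precision. The
#' conservation laws and the per-class balances hold exactly by construction;
#' only the initiation/termination residual is numerical.
#'
#' Boundary compositions `f_op = 0` or `1` dispatch to the analytic one-codon
#' solution [one_codon_steady()] unless `use_closed_form = FALSE`.
#'
#' @param params A `codon_params` object.
#' @param tol Maximum acceptable relative residual of the stationarity
#'   conditions (default `1e-10`).
#' @param use_closed_form Dispatch `f_op` exactly 0 or 1 to the closed-form
#'   one-codon solution (default `TRUE`).
#' @return An object of class `codon_steady`: a list with elements `state`
#'   (one-row tibble of the 7 species), `params`, `P_r` (protein expression
#'   rate, molecules/s), `flux` (the solved `S`), and `residuals` (named
#'   relative residuals of the four balance conditions).
#' @examples
#' p <- load_reference_params("baseline")
#' ss <- steady_state(p)
#' glance(ss)
#' @export
steady_state <- function(params, tol = 1e-10, use_closed_form = TRUE) {
  validate_params(params)
  if (use_closed_form && (params$f_op == 0 || params$f_op == 1)) {
    return(one_codon_steady(params, tol = tol))
  }
  share <- c(params$f_op, 1 - params$f_op)
  Ti <- c(params$T1_tot, params$T2_tot)
  ks <- params$k_speed
  kc <- params$k_charge
  kbN <- params$k_bind_eff * params$N

  # singular flux where a charged pool would be exhausted
  S_max <- Inf
  for (i in 1:2) {
    if (share[i] > 0) S_max <- min(S_max, Ti[i] * kc / (ks * share[i]))
  }
  g <- function(S) {
    x <- share * S
    Tc <- Ti - x * ks / kc
    Rb <- ifelse(share > 0, x / Tc, 0)
    kbN * (params$R_tot - sum(Rb)) - ks * S / params$L
  }
  gprime <- function(S) {
    x <- share * S
    Tc <- Ti - x * ks / kc
    # d(Rb_i)/dS = share_i * Ti / Tc^2
    dRb <- ifelse(share > 0, share * Ti / Tc^2, 0)
    -kbN * sum(dRb) - ks / params$L
  }
  hi <- S_max * (1 - 1e-12)
  root <- stats::uniroot(g, lower = 0, upper = hi, tol = S_max * 1e-12)
  # safeguarded Newton polish: keep the bracket [a, b] with g(a) > 0 > g(b),
  # bisect whenever a Newton step leaves it, stop on a relative residual at
  # machine precision
  a <- 0; b <- hi
  S <- root$root
  rel_scale <- function(S) {
    max(kbN * params$R_tot, ks * S / params$L, .Machine$double.xmin)
  }
  for (i in 1:100) {
    gS <- g(S)
    if (abs(gS) <= 1e-15 * rel_scale(S)) break
    if (gS > 0) a <- S else b <- S
    S_new <- S - gS / gprime(S)
    if (!is.finite(S_new) || S_new <= a || S_new >= b) S_new <- (a + b) / 2
    if (S_new == S) break
    S <- S_new
  }
  build_steady(S, params, tol)
}

# assemble the codon_steady object from the solved flux S and check residuals
build_steady <- function(S, params, tol) {
  share <- c(params$f_op, 1 - params$f_op)
  Ti <- c(params$T1_tot, params$T2_tot)
  x <- share * S
  # T_u from the charging balance directly: avoids cancellation when the
  # uncharged pool is a tiny fraction of the total
  Tu <- x * params$k_speed / params$k_charge
  Tc <- Ti - Tu
  Rb <- ifelse(share > 0, x / Tc, 0)
  Rf <- params$R_tot - sum(Rb)
  state <- tibble::tibble(
    T_c1 = Tc[1], T_c2 = Tc[2],
    T_u1 = Tu[1], T_u2 = Tu[2],
    R_f = Rf, R_b1 = Rb[1], R_b2 = Rb[2]
  )
  res <- steady_residuals(state, params)
  if (max(abs(res)) > tol) {
    stop(sprintf(
      "steady-state solve did not converge: max relative residual %.3e > %.3e (%s)",
      max(abs(res)), tol,
      paste(sprintf("%s=%.2e", names(res), res), collapse = ", ")
    ), call. = FALSE)
  }
  if (any(unlist(state) < 0)) {
    stop("steady-state solve produced negative species counts", call. = FALSE)
  }
  structure(
    list(
      state = state, params = params,
      P_r = protein_rate(state, params),
      flux = S, residuals = res
    ),
    class = "codon_steady"
  )
}

#' Relative residuals of the stationarity conditions
#'
#' Evaluates the four steady-state balances (initiation/termination, the two
#' charging balances, and the codon-exchange balance). Each residual is
#' scaled by the natural flux scale of its equation — the flux the pathway
#' would carry at its conserved totals (e.g. `k_bind_eff * N * R_tot` for
#' initiation, `k_charge * Ti_tot` for charging) or the magnitude of its
#' terms, whichever is larger — so the scaling stays meaningful in regimes
#' where one species is driven to a vanishing count.
#'
#' @param state A state (one-row tibble, named vector, or `codon_steady`).
#' @param params A `codon_params` object.
#' @return Named numeric vector `c(binding, charge1, charge2, exchange)`.
#' @export
steady_residuals <- function(state, params) {
  v <- as_state_vector(state)
  ks <- params$k_speed
  x1 <- v[["R_b1"]] * v[["T_c1"]]
  x2 <- v[["R_b2"]] * v[["T_c2"]]
  rel <- function(lhs, rhs, floor) {
    scale <- max(abs(lhs), abs(rhs), floor, .Machine$double.xmin)
    (lhs - rhs) / scale
  }
  kbN <- params$k_bind_eff * params$N
  c(
    binding = rel(kbN * v[["R_f"]], ks * (x1 + x2) / params$L,
                  kbN * params$R_tot),
    charge1 = rel(params$k_charge * v[["T_u1"]], ks * x1,
                  params$k_charge * params$T1_tot),
    charge2 = rel(params$k_charge * v[["T_u2"]], ks * x2,
                  params$k_charge * params$T2_tot),
    exchange = rel(x1 * (1 - params$f_op), x2 * params$f_op,
                   ks * .Machine$double.xmin)
  )
}

#' Closed-form steady state for single-codon-class transcripts
#'
#' For `f_op` exactly 0 or 1 the system collapses to one charging balance and
#' one binding balance, a quadratic in the active elongation flux; the unused
#' codon class has zero ribosome occupancy and a fully charged tRNA pool.
#' Serves as the analytic oracle for the boundary cases of the full solver.
#'
#' @inheritParams steady_state
#' @return A `codon_steady` object (see [steady_state()]).
#' @export
one_codon_steady <- function(params, tol = 1e-10) {
  validate_params(params)
  if (params$f_op != 0 && params$f_op != 1) {
    stop("one_codon_steady() requires f_op exactly 0 or 1", call. = FALSE)
  }
  Ta <- if (params$f_op == 1) params$T1_tot else params$T2_tot
  ks <- params$k_speed
  kc <- params$k_charge
  kbN <- params$k_bind_eff * params$N
  L <- params$L
  # kbN (R_tot - x / (Ta - x ks/kc)) = ks x / L, as a quadratic a x^2 + b x + c = 0
  a <- ks^2 / (kc * L)
  b <- -(ks * Ta / L + kbN * params$R_tot * ks / kc + kbN)
  c0 <- kbN * params$R_tot * Ta
  disc <- b^2 - 4 * a * c0
  # numerically stable smaller root (the physical one: x < Ta*kc/ks)
  x <- 2 * c0 / (-b + sqrt(disc))
  build_steady(x, params, tol)
}

#' Protein expression rate from a state
#'
#' The rate at which ribosomes run off transcript ends, i.e. the translation
#' termination flux `k_speed * (R_b1*T_c1 + R_b2*T_c2) / L`, in protein
#' molecules per second.
#'
#' @param state A state (one-row tibble, named vector, or `codon_steady`).
#' @param params A `codon_params` object.
#' @return A non-negative number (molecules/s).
#' @export
protein_rate <- function(state, params) {
  v <- as_state_vector(state)
  params$k_speed *
    (v[["R_b1"]] * v[["T_c1"]] + v[["R_b2"]] * v[["T_c2"]]) / params$L
}

#' Derived steady-state observables
#'
#' Summarizes a (steady) state as the translation properties used to compare
#' the model against bacterial measurements: protein expression rate, charged
#' fractions, active-ribosome fraction, the per-active-ribosome translation
#' speed `k_speed * (R_b1*T_c1 + R_b2*T_c2) / (R_b1 + R_b2)` in codons/s, and
#' ribosome density per 100 nucleotides, `100 * (R_b1+R_b2) / (N * 3L)`.
#'
#' @param state A state (one-row tibble, named vector, or `codon_steady`).
#' @param params A `codon_params` object; may be omitted when `state` is a
#'   `codon_steady`.
#' @return A one-row tibble with columns `P_r`, `charged_frac_1`,
#'   `charged_frac_2`, `charged_frac_total`, `active_ribosome_frac`,
#'   `per_ribosome_speed`, `ribosome_density`.
#' @export
steady_summary <- function(state, params = NULL) {
  if (inherits(state, "codon_steady") && is.null(params)) {
    params <- state$params
  }
  if (is.null(params)) stop("params must be supplied", call. = FALSE)
  v <- as_state_vector(state)
  active <- v[["R_b1"]] + v[["R_b2"]]
  weighted <- v[["R_b1"]] * v[["T_c1"]] + v[["R_b2"]] * v[["T_c2"]]
  T_tot <- params$T1_tot + params$T2_tot
  tibble::tibble(
    P_r = params$k_speed * weighted / params$L,
    charged_frac_1 = if (params$T1_tot > 0) v[["T_c1"]] / params$T1_tot else 1,
    charged_frac_2 = if (params$T2_tot > 0) v[["T_c2"]] / params$T2_tot else 1,
    charged_frac_total = (v[["T_c1"]] + v[["T_c2"]]) / T_tot,
    active_ribosome_frac = active / params$R_tot,
    per_ribosome_speed = if (active > 0) params$k_speed * weighted / active else 0,
    ribosome_density = 100 * active / (params$N * params$L * 3)
  )
}

#' @export
print.codon_steady <- function(x, ...) {
  cat("Two-codon steady state (f_op =", x$params$f_op, ")\n")
  print(x$state)
  cat(sprintf("P_r = %.6g molecules/s; max |relative residual| = %.2e\n",
              x$P_r, max(abs(x$residuals))))
  invisible(x)
}

#' @export
tidy.codon_steady <- function(x, ...) {
  tibble::tibble(
    species = species_names(),
    count = as.numeric(x$state[1, species_names()])
  )
}

#' @export
glance.codon_steady <- function(x, ...) {
  out <- steady_summary(x)
  out$max_abs_residual <- max(abs(x$residuals))
  out
}

#' Protein expression rate in the infinite-charging limit
#'
#' When charging outpaces elongation (`k_charge` effectively infinite) both
#' tRNA pools remain fully charged (`T_ci = Ti_tot`). The per-active-ribosome
#' speed is then the `f_op`-weighted harmonic mean of `k_speed*T1_tot` and
#' `k_speed*T2_tot`, and the expression rate follows from the
#' initiation/termination balance alone. With equal tRNA pools the result is
#' independent of `f_op`.
#'
#' @param params A `codon_params` object (`k_charge` is ignored, treated as
#'   infinite).
#' @return A list with `P_r` (molecules/s), `per_ribosome_speed` (codons/s),
#'   and `state` (one-row tibble of the limiting species counts).
#' @export
infinite_charging_rate <- function(params) {
  validate_params(params)
  f <- params$f_op
  ks <- params$k_speed
  kbN <- params$k_bind_eff * params$N
  # R_bi = share_i * S / Ti_tot; initiation balance fixes S
  w <- 0
  if (f > 0) w <- w + f / params$T1_tot
  if (f < 1) w <- w + (1 - f) / params$T2_tot
  S <- kbN * params$R_tot / (kbN * w + ks / params$L)
  Rb1 <- if (f > 0) f * S / params$T1_tot else 0
  Rb2 <- if (f < 1) (1 - f) * S / params$T2_tot else 0
  state <- tibble::tibble(
    T_c1 = params$T1_tot, T_c2 = params$T2_tot, T_u1 = 0, T_u2 = 0,
    R_f = params$R_tot - Rb1 - Rb2, R_b1 = Rb1, R_b2 = Rb2
  )
  list(
    P_r = ks * S / params$L,
    per_ribosome_speed = ks * S / (Rb1 + Rb2),
    state = state
  )
}

#' Convert a molar binding constant to the effective per-molecule constant
#'
#' `k_bind_eff = k_bind_molar / (N_A * volume)`, where `N_A` is the Avogadro
#' constant. The model's mass-action initiation term `k_bind_eff * N * R_f`
#' needs a per-molecule constant; measured association constants are molar.
#'
#' @param k_bind_molar Association rate constant (M^-1 s^-1), positive.
#' @param volume Reaction volume in liters, positive.
#' @return Effective binding constant (per molecule per second).
#' @examples
#' molar_to_effective_bind(2.5e6, 8e-16)
#' @export
molar_to_effective_bind <- function(k_bind_molar, volume) {
  if (!is.numeric(k_bind_molar) || any(k_bind_molar <= 0)) {
    stop("k_bind_molar must be > 0", call. = FALSE)
  }
  if (!is.numeric(volume) || any(volume <= 0)) {
    stop("volume must be > 0", call. = FALSE)
  }
  avogadro <- 6.02214076e23
  k_bind_molar / (avogadro * volume)
}

#' Calibrate charging and binding constants to observed translation properties
#'
#' Finds `(k_charge, k_bind_eff)` such that the steady state of the template
#' system reproduces a target total charged-tRNA fraction and a target
#' active-ribosome fraction. Uses nested bracketed 1-D root finds: for a
#' trial `k_charge`, the active fraction is strictly increasing in
#' `k_bind_eff`, so the inner [stats::uniroot()] (with geometric bracket
#' expansion) pins `k_bind_eff`; the charged fraction at that inner solution
#' is then strictly increasing in `k_charge`, and the outer root find pins
#' `k_charge`.
#'
#' @param params_template A `codon_params` object; its `k_charge` and
#'   `k_bind_eff` entries are ignored and replaced.
#' @param target_charged_frac,target_active_frac Targets, strictly in (0, 1).
#' @param tol Absolute tolerance on the reproduced fractions (default `1e-9`).
#' @return A list with `k_charge`, `k_bind_eff`, `params` (the template with
#'   the calibrated constants), and `achieved` (named vector of the
#'   reproduced fractions).
#' @examples
#' p <- load_reference_params("baseline")
#' cal <- calibrate_rates(p, 0.88, 0.88)
#' cal$k_charge
#' @export
calibrate_rates <- function(params_template, target_charged_frac,
                            target_active_frac, tol = 1e-9) {
  validate_params(params_template)
  for (tgt in c(target_charged_frac, target_active_frac)) {
    if (!is.numeric(tgt) || length(tgt) != 1 || tgt <= 0 || tgt >= 1) {
      stop("calibration targets must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  obs <- function(kc, kb) {
    p <- update_params(params_template, k_charge = kc, k_bind_eff = kb)
    s <- steady_state(p)
    sm <- steady_summary(s)
    c(charged = sm$charged_frac_total, active = sm$active_ribosome_frac)
  }
  inner_kb <- function(kc) {
    h <- function(kb) obs(kc, kb)[["active"]] - target_active_frac
    lo <- 1e-12; hi <- 1e-2
    while (h(hi) < 0 && hi < 1e8) hi <- hi * 10
    if (h(hi) < 0) {
      stop(sprintf(
        "infeasible target_active_frac %.6g: max achievable %.6g at k_bind_eff = %g",
        target_active_frac, obs(kc, hi)[["active"]] , hi), call. = FALSE)
    }
    while (h(lo) > 0 && lo > 1e-30) lo <- lo / 10
    stats::uniroot(h, lower = lo, upper = hi, tol = tol * 1e-3)$root
  }
  outer <- function(kc) {
    kb <- inner_kb(kc)
    obs(kc, kb)[["charged"]] - target_charged_frac
  }
  lo <- 1e-3; hi <- 1e3
  while (outer(hi) < 0 && hi < 1e9) hi <- hi * 10
  while (outer(lo) > 0 && lo > 1e-9) lo <- lo / 10
  if (outer(hi) < 0 || outer(lo) > 0) {
    stop(sprintf(
      "infeasible target_charged_frac %.6g: achievable range is [%.6g, %.6g] over k_charge in [%g, %g]",
      target_charged_frac,
      target_charged_frac + outer(lo), target_charged_frac + outer(hi),
      lo, hi), call. = FALSE)
  }
  kc <- stats::uniroot(outer, lower = lo, upper = hi, tol = tol * 1e-3)$root
  kb <- inner_kb(kc)
  achieved <- obs(kc, kb)
  if (max(abs(achieved - c(target_charged_frac, target_active_frac))) > 1e-6) {
    stop("calibration failed to reproduce targets to 1e-6", call. = FALSE)
  }
  list(
    k_charge = kc, k_bind_eff = kb,
    params = update_params(params_template, k_charge = kc, k_bind_eff = kb),
    achieved = achieved
  )
}
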