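#' Parameterize the two-codon translation system
#'
#' Constructs and validates the complete parameterization of the two-codon
#' model: a homogeneous pool of `N` transcripts of length `L` codons, a
#' fraction `f_op` of which belong to the "optimal" codon class, translated by
#' `R_tot` ribosomes drawing on two tRNA pools (`T1_tot` preferred, `T2_tot`
#' non-preferred) that are dynamically re-aminoacylated at rate constant
#' `k_charge`.
#'
#' Rate constant conventions:
#' * `k_charge` (s^-1) multiplies the uncharged tRNA count of each species;
#'   both species share the same constant.
#' * `k_speed` (per charged tRNA per bound ribosome per second) multiplies
#'   `R_b * T_c`; the biologically meaningful per-ribosome translation speed in
#'   codons/s is `k_speed * T_c`.
#' * `k_bind_eff` (per free ribosome per binding site per second) multiplies
#'   `N * R_f`. Use [molar_to_effective_bind()] to convert a molar association
#'   constant for a given reaction volume, or [calibrate_rates()] to fix it
#'   against observed translation properties.
#'
#' @param T1_tot,T2_tot Counts of preferred / non-preferred tRNAs (molecules).
#' @param R_tot Total ribosomes (molecules).
#' @param N Transcript count; each transcript carries one ribosome binding
#'   site, so `N` is also the number of binding sites.
#' @param L Transcript length in codons.
#' @param k_charge tRNA charging rate constant (s^-1), shared by both species.
#' @param k_speed Ribosome elongation rate constant (per charged tRNA per
#'   bound ribosome per second).
#' @param k_bind_eff Effective ribosome binding rate constant (per free
#'   ribosome per binding site per second).
#' @param f_op Fraction of optimal codons, in `[0, 1]`.
#'
#' @return An object of class `codon_params` (a validated named list).
#' @seealso [load_reference_params()] for the packaged reference sets,
#'   [steady_state()], [simulate_ssa()].
#' @examples
#' p <- two_codon_params(
#'   T1_tot = 1250, T2_tot = 1250, R_tot = 500, N = 100, L = 300,
#'   k_charge = 32.27, k_speed = 0.02, k_bind_eff = 5.38e-3, f_op = 0.5
#' )
#' fraction_preferred(p)
#' @export
two_codon_params <- function(T1_tot, T2_tot, R_tot, N, L,
                             k_charge, k_speed, k_bind_eff, f_op = 0.5) {
  p <- list(
    T1_tot = T1_tot, T2_tot = T2_tot, R_tot = R_tot, N = N, L = L,
    k_charge = k_charge, k_speed = k_speed, k_bind_eff = k_bind_eff,
    f_op = f_op
  )
  validate_params(p)
  structure(p, class = "codon_params")
}

validate_params <- function(p) {
  fields <- c("T1_tot", "T2_tot", "R_tot", "N", "L",
              "k_charge", "k_speed", "k_bind_eff", "f_op")
  missing <- setdiff(fields, names(p))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  if (p$T1_tot < 0 || p$T2_tot < 0) stop("tRNA totals must be >= 0", call. = FALSE)
  if (p$T1_tot + p$T2_tot <= 0) stop("total tRNA count must be > 0", call. = FALSE)
  if (p$R_tot <= 0) stop("R_tot must be > 0", call. = FALSE)
  if (p$N < 1) stop("N must be >= 1", call. = FALSE)
  if (p$L < 1) stop("L must be >= 1", call. = FALSE)
  for (f in c("k_charge", "k_speed", "k_bind_eff")) {
    if (p[[f]] <= 0) stop("rate constant '", f, "' must be > 0", call. = FALSE)
  }
  if (p$f_op < 0 || p$f_op > 1) stop("f_op must lie in [0, 1]", call. = FALSE)
  # a codon class with no cognate tRNA can never be translated
  if (p$T2_tot == 0 && p$f_op < 1) {
    stop("T2_tot = 0 requires f_op = 1 (non-optimal codons would stall)",
         call. = FALSE)
  }
  if (p$T1_tot == 0 && p$f_op > 0) {
    stop("T1_tot = 0 requires f_op = 0 (optimal codons would stall)",
         call. = FALSE)
  }
  invisible(p)
}

#' Fraction of preferred tRNAs
#'
#' Derived, read-only quantity `T1_tot / (T1_tot + T2_tot)`.
#'
#' @param params A `codon_params` object.
#' @return A number in `[0, 1]`.
#' @export
fraction_preferred <- function(params) {
  validate_params(params)
  params$T1_tot / (params$T1_tot + params$T2_tot)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params A `codon_params` object.
#' @param ... Named fields to replace (e.g. `f_op = 0.7`, `k_charge = 3`).
#' @return A new `codon_params` object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(unclass(params), repl)
  validate_params(p)
  structure(p, class = "codon_params")
}

#' @export
print.codon_params <- function(x, ...) {
  cat("Two-codon translation model parameters\n")
  cat(sprintf("  tRNA totals     : %g preferred + %g non-preferred (fraction %.3g)\n",
              x$T1_tot, x$T2_tot, fraction_preferred(x)))
  cat(sprintf("  ribosomes       : %g total\n", x$R_tot))
  cat(sprintf("  transcripts     : %g of length %g codons, f_op = %g\n",
              x$N, x$L, x$f_op))
  cat(sprintf("  rate constants  : k_charge = %g /s, k_speed = %g, k_bind_eff = %g\n",
              x$k_charge, x$k_speed, x$k_bind_eff))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.codon_params <- function(x, ...) {
  tibble::tibble(
    parameter = names(unclass(x)),
    value = unlist(unclass(x), use.names = FALSE)
  )
}

species_names <- function() {
  c("T_c1", "T_c2", "T_u1", "T_u2", "R_f", "R_b1", "R_b2")
}

# coerce a state given as codon_steady, one-row data frame, or named vector
# into a named numeric vector of the 7 species
as_state_vector <- function(state) {
  if (inherits(state, "codon_steady")) state <- state$state
  if (is.data.frame(state)) {
    if (nrow(state) != 1) stop("state must be a single row", call. = FALSE)
    state <- unlist(state[species_names()])
  }
  if (!all(species_names() %in% names(state))) {
    stop("state must contain the fields ",
         paste(species_names(), collapse = ", "), call. = FALSE)
  }
  v <- as.numeric(state[species_names()])
  names(v) <- species_names()
  if (any(v < -1e-9)) stop("state has negative species counts", call. = FALSE)
  v
}

check_state_consistent <- function(state, params, tol = 1e-6) {
  v <- as_state_vector(state)
  t1 <- v[["T_c1"]] + v[["T_u1"]]
  t2 <- v[["T_c2"]] + v[["T_u2"]]
  rr <- v[["R_f"]] + v[["R_b1"]] + v[["R_b2"]]
  scale1 <- max(params$T1_tot, 1)
  scale2 <- max(params$T2_tot, 1)
  if (abs(t1 - params$T1_tot) > tol * scale1 ||
      abs(t2 - params$T2_tot) > tol * scale2 ||
      abs(rr - params$R_tot) > tol * params$R_tot) {
    stop("state is inconsistent with the conserved totals in params",
         call. = FALSE)
  }
  invisible(v)
}

#' Default initial condition
#'
#' The conventional starting state for time courses and stochastic runs:
#' every tRNA charged, every ribosome free.
#'
#' @param params A `codon_params` object.
#' @return A one-row tibble with the 7 species counts.
#' @export
initial_state <- function(params) {
  validate_params(params)
  tibble::tibble(
    T_c1 = params$T1_tot, T_c2 = params$T2_tot,
    T_u1 = 0, T_u2 = 0,
    R_f = params$R_tot, R_b1 = 0, R_b2 = 0
  )
}
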