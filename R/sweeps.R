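#' Sweep the steady state over codon usage
#'
#' Solves one steady state per grid value of `f_op` and collects the
#' expression rate and species counts. Individual solver failures are
#' recorded per point (`converged = FALSE`) without aborting the sweep.
#'
#' @param params A `codon_params` object (its own `f_op` is ignored).
#' @param fop Grid of `f_op` values in `[0, 1]`.
#' @return A tibble of class `codon_sweep` with columns `f_op`, `P_r`, the 7
#'   species, and `converged`, sorted by `f_op`; attributes `k_charge` and
#'   `fraction_preferred` carry the sweep metadata.
#' @examples
#' p <- load_reference_params("ratio07", k_charge = 3)
#' sw <- sweep_fop(p, fop = seq(0, 1, 0.05))
#' @export
sweep_fop <- function(params, fop = seq(0, 1, by = 0.01)) {
  validate_params(params)
  if (any(fop < 0 | fop > 1)) stop("f_op grid must lie in [0, 1]", call. = FALSE)
  fop <- sort(fop)
  rows <- purrr::map(fop, function(f) {
    res <- tryCatch(steady_state(update_params(params, f_op = f)),
                    error = function(e) NULL)
    if (is.null(res)) {
      out <- tibble::as_tibble(stats::setNames(
        as.list(rep(NA_real_, 7)), species_names()))
      out$P_r <- NA_real_
      out$converged <- FALSE
    } else {
      out <- res$state
      out$P_r <- res$P_r
      out$converged <- TRUE
    }
    tibble::add_column(out, f_op = f, .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::relocate("f_op", "P_r")
  if (!any(out$converged)) {
    stop("steady-state solve failed at every grid point", call. = FALSE)
  }
  structure(out, class = c("codon_sweep", class(out)),
            k_charge = params$k_charge,
            fraction_preferred = fraction_preferred(params))
}

#' Locate the expression-maximizing fraction of optimal codons
#'
#' Coarse grid scan of `P_r(f_op)` followed by golden-section refinement on
#' the interval bracketing the grid argmax. Ties on the grid break toward the
#' smaller `f_op` (the first maximum). When the whole curve is flat (relative
#' range below `flat_tol`, e.g. equal tRNA pools at high charging rates) the
#' maximum is reported as undefined (`f_op_max = NA`) with `flat = TRUE`
#' rather than an arbitrary argmax. If any steady state near the bracket
#' fails, the coarse-grid argmax is returned with `refined = FALSE`.
#'
#' @param params A `codon_params` object.
#' @param coarse_step Grid step for the scan (must be `<= 0.05`).
#' @param refine_tol Width of the final golden-section interval.
#' @param flat_tol Relative `P_r` range below which the curve is declared
#'   flat.
#' @return A one-row tibble with `f_op_max` (refined argmax), `f_op_grid_max`
#'   (raw grid argmax), `P_r_max`, `flat`, and `refined`.
#' @export
find_fop_max <- function(params, coarse_step = 0.01, refine_tol = 1e-3,
                         flat_tol = 1e-9) {
  validate_params(params)
  if (coarse_step > 0.05) stop("coarse_step must be <= 0.05", call. = FALSE)
  grid <- seq(0, 1, by = coarse_step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  sw <- sweep_fop(params, fop = grid)
  ok <- sw[sw$converged, ]
  pr_range <- (max(ok$P_r) - min(ok$P_r)) / max(ok$P_r)
  if (pr_range < flat_tol) {
    return(tibble::tibble(f_op_max = NA_real_, f_op_grid_max = NA_real_,
                          P_r_max = max(ok$P_r), flat = TRUE, refined = FALSE))
  }
  i <- which.max(ok$P_r) # first maximum: ties toward smaller f_op
  f_grid <- ok$f_op[i]
  lo <- if (i > 1) ok$f_op[i - 1] else ok$f_op[1]
  hi <- if (i < nrow(ok)) ok$f_op[i + 1] else ok$f_op[nrow(ok)]
  pr_at <- function(f) steady_state(update_params(params, f_op = f))$P_r
  refined <- tryCatch({
    gs <- golden_max(pr_at, lo, hi, tol = refine_tol)
    # include the bracket endpoints: a maximum at the domain boundary should
    # be reported exactly as 0 or 1
    cand_f <- c(gs$x, lo, hi)
    cand_p <- c(gs$value, pr_at(lo), pr_at(hi))
    best <- order(-cand_p, cand_f)[1]
    list(f = cand_f[best], p = cand_p[best])
  }, error = function(e) NULL)
  if (is.null(refined)) {
    tibble::tibble(f_op_max = f_grid, f_op_grid_max = f_grid,
                   P_r_max = ok$P_r[i], flat = FALSE, refined = FALSE)
  } else {
    tibble::tibble(f_op_max = refined$f, f_op_grid_max = f_grid,
                   P_r_max = refined$p, flat = FALSE, refined = TRUE)
  }
}

# golden-section maximization on [lo, hi]
golden_max <- function(fn, lo, hi, tol = 1e-3) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- fn(x1); f2 <- fn(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- fn(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- fn(x1)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = fn(x))
}

#' Map the expression maximum across charging rates and tRNA ratios
#'
#' For each combination of preferred-tRNA fraction and `k_charge`, locates
#' the expression-maximizing codon usage with [find_fop_max()]. The total
#' tRNA pool is held at `params_template$T1_tot + params_template$T2_tot`
#' and split according to each fraction.
#'
#' @param params_template A `codon_params` object providing all shared
#'   fields.
#' @param fractions Preferred-tRNA fractions to scan.
#' @param k_charge Charging-rate grid; default 20 log-spaced points across
#'   the reference 3--300 /s range.
#' @param ... Passed to [find_fop_max()].
#' @return A tibble with columns `fraction_preferred`, `k_charge`,
#'   `f_op_max`, `flat`, `refined`, class `codon_fopmax_map`.
#' @export
sweep_fop_max <- function(params_template,
                          fractions = c(0.5, 0.7, 0.9),
                          k_charge = exp(seq(log(3), log(300), length.out = 20)),
                          ...) {
  validate_params(params_template)
  T_tot <- params_template$T1_tot + params_template$T2_tot
  grid <- tidyr::expand_grid(fraction_preferred = fractions,
                             k_charge = k_charge)
  res <- purrr::pmap(grid, function(fraction_preferred, k_charge) {
    p <- update_params(params_template,
                       T1_tot = fraction_preferred * T_tot,
                       T2_tot = (1 - fraction_preferred) * T_tot,
                       k_charge = k_charge)
    find_fop_max(p, ...)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  structure(out, class = c("codon_fopmax_map", class(out)))
}

#' Verify the total-tRNA scaling law
#'
#' Rescales both tRNA totals by each factor `alpha` while dividing `k_charge`
#' and `k_speed` by the same factor, re-solves the steady state across an
#' `f_op` grid, and reports the deviation of the expression rate from the
#' unscaled system. The model predicts exact invariance.
#'
#' @param params A `codon_params` object (the `alpha = 1` system).
#' @param alphas Positive scale factors.
#' @param fop `f_op` grid over which invariance is checked.
#' @return A list of class `codon_scaling` with `max_rel_deviation` and
#'   `table` (tibble of `alpha`, `f_op`, `P_r`, `rel_deviation`).
#' @examples
#' p <- load_reference_params("baseline")
#' scaling_deviation(p, alphas = c(0.1, 1, 10))$max_rel_deviation
#' @export
scaling_deviation <- function(params, alphas = c(0.1, 1, 10),
                              fop = c(0, 0.25, 0.5, 0.75, 1)) {
  validate_params(params)
  if (any(alphas <= 0)) stop("alphas must be > 0", call. = FALSE)
  base <- purrr::map_dbl(fop, function(f) {
    steady_state(update_params(params, f_op = f))$P_r
  })
  tab <- purrr::map(alphas, function(a) {
    pr <- purrr::map_dbl(fop, function(f) {
      p <- update_params(params,
                         T1_tot = params$T1_tot * a,
                         T2_tot = params$T2_tot * a,
                         k_charge = params$k_charge / a,
                         k_speed = params$k_speed / a,
                         f_op = f)
      steady_state(p)$P_r
    })
    tibble::tibble(alpha = a, f_op = fop, P_r = pr,
                   rel_deviation = abs(pr - base) / base)
  }) |> dplyr::bind_rows()
  structure(list(max_rel_deviation = max(tab$rel_deviation), table = tab),
            class = "codon_scaling")
}

#' @export
print.codon_scaling <- function(x, ...) {
  cat(sprintf(
    "tRNA scaling-law check: max relative P_r deviation %.3e over alpha in {%s}\n",
    x$max_rel_deviation, paste(unique(x$table$alpha), collapse = ", ")))
  invisible(x)
}

#' Effective codon usage of a mixed transcript pool
#'
#' Codon-mass-weighted average of the per-class optimal-codon fractions:
#' `sum(copies * L * f_op) / sum(copies * L)`. Under the mean-field argument
#' a heterogeneous pool behaves like a homogeneous one with this `f_op`,
#' `N = sum(copies)` transcripts, and the mass-weighted mean length.
#'
#' @param classes A data frame with columns `copies`, `L`, `f_op` (one row
#'   per transcript class).
#' @return The effective fraction of optimal codons.
#' @examples
#' effective_fop(data.frame(copies = c(50, 50), L = 300, f_op = c(0.4, 1.0)))
#' @export
effective_fop <- function(classes) {
  need <- c("copies", "L", "f_op")
  if (!is.data.frame(classes) || nrow(classes) == 0) {
    stop("classes must be a non-empty data frame", call. = FALSE)
  }
  if (!all(need %in% names(classes))) {
    stop("classes must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(classes$copies < 0) || any(classes$f_op < 0 | classes$f_op > 1)) {
    stop("copies must be >= 0 and f_op in [0, 1]", call. = FALSE)
  }
  mass <- sum(classes$copies * classes$L)
  if (mass <= 0) stop("total translated codon mass must be > 0", call. = FALSE)
  sum(classes$copies * classes$L * classes$f_op) / mass
}

#' Homogeneous surrogate parameters for a mixed transcript pool
#'
#' Builds the `codon_params` whose homogeneous system represents the mixture:
#' `f_op` from [effective_fop()], `N = sum(copies)`, `L` the codon-mass
#' weighted mean length.
#'
#' @param classes As in [effective_fop()].
#' @param params_template A `codon_params` supplying all other fields.
#' @return A `codon_params` object.
#' @export
mixed_transcript_params <- function(classes, params_template) {
  f_eff <- effective_fop(classes)
  n_tot <- sum(classes$copies)
  L_eff <- sum(classes$copies * classes$L^2) / sum(classes$copies * classes$L)
  update_params(params_template, f_op = f_eff, N = n_tot, L = L_eff)
}
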