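#' Constants of the burst-size to growth-rate conversion
#'
#' Parameters of the phage growth model: an infected cell lyses after
#' `lysis_time` minutes releasing `burst = p / virion_size` virions, where
#' `p` is the major-capsid protein count at lysis; `adsorption` is the
#' product of the adsorption rate constant and host cell density (per
#' minute). Note: `lysis_time` is unrelated to the transcript length `L` of
#' the translation model; the symbols collide in the literature, so the two
#' live in separate parameter objects here.
#'
#' @param lysis_time Minutes from infection to lysis (default 12).
#' @param virion_size Capsid proteins per virion (default 400).
#' @param adsorption Adsorption-rate x cell-density product, per minute
#'   (default 1).
#' @return An object of class `phage_fitness_params`.
#' @export
phage_fitness_params <- function(lysis_time = 12, virion_size = 400,
                                 adsorption = 1) {
  for (v in c(lysis_time, virion_size, adsorption)) {
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      stop("all phage fitness parameters must be positive numbers",
           call. = FALSE)
    }
  }
  structure(list(lysis_time = lysis_time, virion_size = virion_size,
                 adsorption = adsorption),
            class = "phage_fitness_params")
}

#' Intrinsic phage growth rate from capsid protein abundance
#'
#' Solves `r = kC * ((p / virion_size) * exp(-lysis_time * r) - 1)` for the
#' intrinsic growth rate `r` (per minute), where `kC` is the adsorption-rate
#' x cell-density product and `p / virion_size` is the burst size. The right
#' side is strictly decreasing in `r` while the left side increases, so the
#' root is unique; it is bracketed by `[-kC, max(kC*(b-1), 0) + 1]` (the
#' lower end is the exact root for `b = 0`), expanded geometrically if
#' needed, solved with [stats::uniroot()], and polished by Newton steps so
#' the defining equation's residual is below 1e-12.
#'
#' @param p Capsid protein count(s), `>= 0` (vectorized).
#' @param fp A [phage_fitness_params()] object.
#' @return Growth rate(s) `r` in per minute. `r = 0` when the burst size is
#'   exactly 1, negative below, positive above.
#' @examples
#' growth_rate(400) # burst size 1 -> zero growth
#' growth_rate(4000)
#' @export
growth_rate <- function(p, fp = phage_fitness_params()) {
  if (!inherits(fp, "phage_fitness_params")) {
    stop("fp must be a phage_fitness_params object", call. = FALSE)
  }
  if (!is.numeric(p) || any(p < 0)) stop("p must be >= 0", call. = FALSE)
  kC <- fp$adsorption
  lt <- fp$lysis_time
  vapply(p, function(pi) {
    b <- pi / fp$virion_size
    if (b == 0) return(-kC)
    if (b == 1) return(0)
    h <- function(r) kC * (b * exp(-lt * r) - 1) - r
    lo <- -kC
    hi <- max(kC * (b - 1), 0) + 1
    it <- 0
    while (h(hi) > 0) {
      hi <- hi * 2
      it <- it + 1
      if (it > 200) {
        stop(sprintf(
          "growth_rate: no sign change up to r = %g (p = %g, burst = %g)",
          hi, pi, b), call. = FALSE)
      }
    }
    r <- stats::uniroot(h, lower = lo, upper = hi, tol = 1e-12)$root
    for (i in 1:4) { # Newton polish: h'(r) = -kC*lt*b*exp(-lt r) - 1
      r <- r - h(r) / (-kC * lt * b * exp(-lt * r) - 1)
    }
    r
  }, numeric(1))
}

#' Convert an intrinsic growth rate to doublings per hour
#'
#' `d = log2(exp(60 * r)) = 60 * r / ln 2` for `r` in per minute.
#'
#' @param r Growth rate(s), per minute.
#' @return Doublings per hour (same sign as `r`, linear in `r`).
#' @export
doublings_per_hour <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("r must be finite", call. = FALSE)
  }
  60 * r / log(2)
}

#' Normalize fitness values to a reference condition
#'
#' Divides each doublings-per-hour value by the value of the reference
#' condition (e.g. wild type).
#'
#' @param d_values A data frame with columns `condition` and `d`.
#' @param reference The condition to normalize by; must be present with a
#'   nonzero `d`.
#' @return The input tibble with an added `relative` column.
#' @export
relative_fitness <- function(d_values, reference) {
  if (!is.data.frame(d_values) ||
      !all(c("condition", "d") %in% names(d_values))) {
    stop("d_values must have columns 'condition' and 'd'", call. = FALSE)
  }
  i <- match(reference, d_values$condition)
  if (is.na(i)) stop("reference condition '", reference, "' not found",
                     call. = FALSE)
  ref <- d_values$d[i]
  if (ref == 0) stop("reference fitness is zero; cannot normalize",
                     call. = FALSE)
  out <- tibble::as_tibble(d_values)
  out$relative <- out$d / ref
  out
}

#' Fitness table from capsid protein counts
#'
#' Convenience pipeline: burst size, growth rate, doublings per hour, and
#' (optionally) fitness relative to a reference condition, for a table of
#' simulated capsid abundances.
#'
#' @param counts A data frame with columns `condition` and `p` (capsid
#'   protein count).
#' @param fp A [phage_fitness_params()] object.
#' @param reference Optional condition to normalize by.
#' @return A tibble with `condition`, `p`, `burst_size`, `r`, `d`, and
#'   `relative` when a reference is given.
#' @export
fitness_table <- function(counts, fp = phage_fitness_params(),
                          reference = NULL) {
  if (!is.data.frame(counts) || !all(c("condition", "p") %in% names(counts))) {
    stop("counts must have columns 'condition' and 'p'", call. = FALSE)
  }
  out <- tibble::as_tibble(counts) |>
    dplyr::mutate(
      burst_size = .data$p / fp$virion_size,
      r = growth_rate(.data$p, fp),
      d = doublings_per_hour(.data$r)
    )
  if (!is.null(reference)) {
    out <- relative_fitness(out, reference)
  }
  out
}
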