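#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an expression-rate sweep
#'
#' Expression rate against the fraction of optimal codons, with a dashed
#' vertical line at the fraction of preferred tRNAs (where the low-charging
#' maximum sits).
#'
#' @param object A `codon_sweep` from [sweep_fop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_sweep <- function(object, ...) {
  frac <- attr(object, "fraction_preferred")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_op, y = .data$P_r)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = frac, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = "fraction of optimal codons",
      y = "protein expression rate (molecules/s)",
      title = sprintf("k_charge = %g /s, fraction preferred = %g",
                      attr(object, "k_charge"), frac)
    ) +
    ggplot2::theme_minimal()
}

#' Plot charged-tRNA pools across codon usage
#'
#' Steady-state charged abundances of the preferred and non-preferred tRNA
#' as a function of `f_op`; at limiting charging rates the two pools cross
#' near the expression maximum.
#'
#' @param sweep A `codon_sweep` from [sweep_fop()].
#' @return A ggplot object.
#' @export
plot_charged_trna <- function(sweep) {
  long <- sweep |>
    dplyr::select("f_op", "T_c1", "T_c2") |>
    tidyr::pivot_longer(-"f_op", names_to = "species", values_to = "count") |>
    dplyr::mutate(species = dplyr::recode(.data$species,
      T_c1 = "charged preferred", T_c2 = "charged non-preferred"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$f_op, y = .data$count,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "fraction of optimal codons",
                  y = "charged tRNA (molecules)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot stochastic or deterministic trajectories
#'
#' Species counts over time, one facet per species; stochastic replicates
#' are overlaid as separate lines.
#'
#' @param object A `codon_ssa` or `codon_trajectory` tibble.
#' @param species Which columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_ssa <- function(object,
                               species = c("T_c1", "T_c2", "R_f", "R_b1",
                                           "R_b2", "protein"),
                               ...) {
  df <- tibble::as_tibble(object)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  long <- df |>
    dplyr::select("replicate", "time", dplyr::all_of(species)) |>
    tidyr::pivot_longer(-c("replicate", "time"),
                        names_to = "species", values_to = "count") |>
    dplyr::mutate(species = factor(.data$species, levels = species))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$count,
                                     group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "molecules") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.codon_trajectory <- function(object, ...) {
  autoplot.codon_ssa(object, ...)
}

#' Plot the expression-maximum map
#'
#' `f_op^max` against `k_charge` (log scale), one curve per preferred-tRNA
#' fraction, with each fraction marked as a horizontal guide: curves rise
#' from their tRNA fraction toward 1 as charging gets faster.
#'
#' @param map A `codon_fopmax_map` from [sweep_fop_max()].
#' @return A ggplot object.
#' @export
plot_fop_max <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(x = .data$k_charge, y = .data$f_op_max,
                                    colour = factor(.data$fraction_preferred))) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$fraction_preferred),
                        data = dplyr::distinct(map, .data$fraction_preferred),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "k_charge (1/s)", y = "expression-maximizing f_op",
                  colour = "fraction preferred") +
    ggplot2::theme_minimal()
}
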