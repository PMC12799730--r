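#' Stochastic simulation of the mean-field two-codon network
#'
#' Exact (direct-method) Gillespie simulation over five reaction channels:
#' charging of each tRNA species (`k_charge * T_ui`), ribosome binding
#' (`k_bind_eff * N * R_f`, the new ribosome landing on an optimal codon with
#' probability `f_op`), and elongation from each codon class
#' (`k_speed * R_bi * T_ci`, consuming one charged tRNA; the ribosome
#' terminates with probability `1/L` — incrementing the protein count and
#' freeing the ribosome — otherwise it re-lands on an optimal codon with
#' probability `f_op`). Long-run time averages converge to the
#' [steady_state()] solution.
#'
#' Replicate `i` is seeded with `seed + i - 1`, so identical arguments give
#' bit-identical trajectories.
#'
#' @param params A `codon_params` object with integer species totals.
#' @param t_max Simulated time (seconds).
#' @param record_interval Spacing of the recording grid (seconds).
#' @param replicates Number of independent replicates.
#' @param seed Base RNG seed.
#' @param init Initial state (integer counts); defaults to [initial_state()].
#' @return A tibble of class `codon_ssa` with columns `replicate`, `time`,
#'   the 7 species, and cumulative `protein`.
#' @examples
#' p <- load_reference_params("baseline")
#' traj <- simulate_ssa(p, t_max = 50, record_interval = 1, replicates = 2, seed = 1)
#' @export
simulate_ssa <- function(params, t_max, record_interval = 1, replicates = 1,
                         seed = 1, init = initial_state(params)) {
  validate_params(params)
  check_ssa_config(t_max, record_interval, replicates, seed)
  v <- check_state_consistent(init, params)
  iv <- as.integer(round(v))
  if (max(abs(iv - v)) > 1e-9) {
    stop("SSA initial state must have integer species counts", call. = FALSE)
  }
  runs <- purrr::map(seq_len(replicates), function(i) {
    set.seed(seed + i - 1)
    m <- ssa_meanfield_cpp(
      iv, params$k_charge, params$k_speed, params$k_bind_eff,
      params$f_op, as.integer(params$L), as.integer(params$N),
      t_max, record_interval
    )
    out <- tibble::as_tibble(as.data.frame(m))
    tibble::add_column(out, replicate = i, .before = 1)
  })
  out <- dplyr::bind_rows(runs)
  structure(out, class = c("codon_ssa", class(out)))
}

check_ssa_config <- function(t_max, record_interval, replicates, seed) {
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (!is.numeric(record_interval) || record_interval <= 0) {
    stop("record_interval must be > 0", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop("replicates must be >= 1", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  invisible(TRUE)
}

#' Codon-resolved stochastic simulation
#'
#' Like [simulate_ssa()] but every ribosome is tracked on an explicit codon
#' sequence: its elongation propensity is `k_speed * T_c` of the codon class
#' under it, and termination happens when it steps past codon `L`. This
#' relaxes the mean-field assumption that only the codon composition — not
#' the spatial arrangement — matters, and is used to test that assumption.
#' Optional steric exclusion (ribosome `footprint` in codons, 0 = off, the
#' default, to match the mean-field model) is handled by thinning, which
#' preserves exactness.
#'
#' @inheritParams simulate_ssa
#' @param transcripts A list of `codon_transcript` objects (one per
#'   transcript, each of length `params$L`; see [generate_transcript()]), or
#'   a single transcript recycled to `params$N` copies.
#' @param footprint Steric footprint in codons (0 disables exclusion).
#' @return A tibble of class `codon_ssa` (with `R_b1`/`R_b2` the counts of
#'   ribosomes currently on optimal / non-optimal codons).
#' @export
simulate_ssa_codon <- function(params, transcripts, t_max,
                               record_interval = 1, replicates = 1, seed = 1,
                               footprint = 0) {
  validate_params(params)
  check_ssa_config(t_max, record_interval, replicates, seed)
  if (inherits(transcripts, "codon_transcript")) {
    transcripts <- rep(list(transcripts), params$N)
  }
  if (length(transcripts) != params$N) {
    stop("need params$N transcripts (or one to recycle)", call. = FALSE)
  }
  lens <- vapply(transcripts, length, integer(1))
  if (any(lens != params$L)) {
    stop("every transcript must have length params$L", call. = FALSE)
  }
  seqs <- do.call(rbind, lapply(transcripts, as.integer))
  iv <- as.integer(c(params$T1_tot, params$T2_tot, 0, 0, params$R_tot))
  runs <- purrr::map(seq_len(replicates), function(i) {
    set.seed(seed + i - 1)
    m <- ssa_codon_cpp(
      seqs, iv, params$k_charge, params$k_speed, params$k_bind_eff,
      as.integer(footprint), t_max, record_interval
    )
    out <- tibble::as_tibble(as.data.frame(m))
    tibble::add_column(out, replicate = i, .before = 1)
  })
  out <- dplyr::bind_rows(runs)
  structure(out, class = c("codon_ssa", class(out)))
}

#' Stationary means and standard errors from replicate trajectories
#'
#' Discards records up to `burn_in`, averages each species (and the protein
#' production rate, computed as the protein increment over the retained
#' window divided by its duration) within each replicate, and reports the
#' across-replicate mean and standard error.
#'
#' @param trajectories A `codon_ssa` (or any tibble with `replicate`, `time`,
#'   species columns and `protein`).
#' @param burn_in Time (seconds) to discard; default half of the trajectory.
#' @return A tibble with columns `quantity`, `mean`, `se`, `n_replicates`.
#'   Quantities are the 7 species plus `protein_rate`.
#' @export
ssa_summary <- function(trajectories, burn_in = NULL) {
  need <- c("replicate", "time", species_names(), "protein")
  if (!all(need %in% names(trajectories))) {
    stop("trajectories must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_rep <- dplyr::n_distinct(trajectories$replicate)
  if (n_rep < 2) {
    stop("need at least 2 replicates to estimate standard errors",
         call. = FALSE)
  }
  t_max <- max(trajectories$time)
  if (is.null(burn_in)) burn_in <- t_max / 2
  if (burn_in >= t_max) stop("burn_in must be < max(time)", call. = FALSE)
  per_rep <- trajectories |>
    dplyr::filter(.data$time >= burn_in) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(species_names()), mean),
      protein_rate = (dplyr::last(.data$protein) - dplyr::first(.data$protein)) /
        (dplyr::last(.data$time) - dplyr::first(.data$time)),
      .groups = "drop"
    )
  per_rep |>
    tidyr::pivot_longer(-"replicate",
                        names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$quantity, c(species_names(), "protein_rate")))
}
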