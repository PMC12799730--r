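test_that("homogeneous all-optimal transcripts reproduce the mean-field model", {
  # at f_op = 1 every codon is optimal in both simulators, so the
  # codon-resolved run must agree statistically with the mean-field SSA
  # and with the numeric steady state
  p <- base_params(f_op = 1)
  ss <- steady_state(p)
  tr <- generate_transcript(p$L, 1, seed = 1)
  est <- ssa_summary(
    simulate_ssa_codon(p, tr, t_max = 500, replicates = 4, seed = 2),
    burn_in = 250
  )
  for (sp in c("T_c1", "R_b1", "R_f")) {
    row <- est[est$quantity == sp, ]
    expect_lt(abs(row$mean - ss$state[[sp]]), 3 * max(row$se, 0.5))
  }
  expect_true(all(est$mean[est$quantity %in% c("R_b2", "T_u2")] == 0))
})

test_that("randomized mixed transcripts match the mean-field steady state", {
  p <- base_params()
  ss <- steady_state(p)
  trs <- lapply(seq_len(p$N), function(i) {
    generate_transcript(p$L, 0.5, seed = 1000 + i)
  })
  est <- ssa_summary(
    simulate_ssa_codon(p, trs, t_max = 500, replicates = 4, seed = 1),
    burn_in = 250
  )
  for (sp in c("T_c1", "T_c2", "R_f", "R_b1", "R_b2")) {
    row <- est[est$quantity == sp, ]
    expect_lt(abs(row$mean - ss$state[[sp]]), 3 * max(row$se, 0.5))
  }
  pr <- est[est$quantity == "protein_rate", ]
  expect_lt(abs(pr$mean - ss$P_r), 3 * pr$se)
})

test_that("codon arrangement at fixed composition barely shifts expression", {
  # alternating vs fully blocked placement, identical 50:50 composition:
  # quantifies the spatial-arrangement sensitivity the composition-only
  # (mean-field) description ignores
  p <- base_params()
  alternating <- structure(rep(c(1L, 2L), p$L / 2), class = "codon_transcript",
                           f_op_requested = 0.5, f_op_realized = 0.5)
  blocked <- structure(c(rep(1L, p$L / 2), rep(2L, p$L / 2)),
                       class = "codon_transcript",
                       f_op_requested = 0.5, f_op_realized = 0.5)
  est_a <- ssa_summary(
    simulate_ssa_codon(p, alternating, t_max = 400, replicates = 4, seed = 2),
    burn_in = 200
  )
  est_b <- ssa_summary(
    simulate_ssa_codon(p, blocked, t_max = 400, replicates = 4, seed = 2),
    burn_in = 200
  )
  ra <- est_a[est_a$quantity == "protein_rate", ]
  rb <- est_b[est_b$quantity == "protein_rate", ]
  expect_gt(ra$se, 0)
  expect_gt(rb$se, 0)
  expect_lt(abs(ra$mean - rb$mean), 4 * sqrt(ra$se^2 + rb$se^2))
})

test_that("conservation and determinism hold in the codon-resolved simulator", {
  p <- base_params()
  tr <- generate_transcript(p$L, 0.5, seed = 3)
  a <- simulate_ssa_codon(p, tr, t_max = 40, replicates = 2, seed = 11)
  b <- simulate_ssa_codon(p, tr, t_max = 40, replicates = 2, seed = 11)
  expect_identical(a, b)
  expect_conserved(a, p, tol = 0)
})

test_that("steric exclusion caps the ribosome load", {
  p <- base_params()
  tr <- generate_transcript(p$L, 0.5, seed = 4)
  free_run <- simulate_ssa_codon(p, tr, t_max = 150, replicates = 2, seed = 5)
  packed <- simulate_ssa_codon(p, tr, t_max = 150, replicates = 2, seed = 5,
                               footprint = 10)
  # with a 10-codon footprint at most L/10 ribosomes fit per transcript
  expect_true(all(packed$R_b1 + packed$R_b2 <= p$N * p$L / 10))
  late <- function(x) mean((x$R_b1 + x$R_b2)[x$time > 75])
  expect_lte(late(packed), late(free_run) + 1e-9)
  expect_conserved(packed, p, tol = 0)
})
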