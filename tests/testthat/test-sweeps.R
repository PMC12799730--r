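test_that("a one-point sweep equals the direct solve", {
  p <- ratio_params(0.7, k_charge = 10)
  sw <- sweep_fop(p, fop = 0.6)
  ss <- steady_state(update_params(p, f_op = 0.6))
  expect_equal(nrow(sw), 1)
  expect_equal(sw$P_r, ss$P_r, tolerance = 1e-12)
  expect_equal(sw$T_c1, ss$state$T_c1, tolerance = 1e-12)
})

test_that("equal tRNA pools make expression insensitive to codon usage at fast charging", {
  # the residual f_op dependence decays like 1/k_charge: a ~1% bow remains
  # at the top of the reference charging range and vanishes in the limit
  p <- base_params(k_charge = 300)
  sw <- sweep_fop(p, fop = seq(0, 1, 0.05))
  expect_lt((max(sw$P_r) - min(sw$P_r)) / max(sw$P_r), 0.02)
  # symmetry P_r(f) = P_r(1 - f) holds exactly
  expect_equal(sw$P_r, rev(sw$P_r), tolerance = 1e-12)
  # deep in the fast-charging limit the curve is flat below the detection
  # threshold and the maximum is reported as undefined
  fm <- find_fop_max(base_params(k_charge = 1e10), coarse_step = 0.05)
  expect_true(fm$flat)
  expect_true(is.na(fm$f_op_max))
})

test_that("limiting charging depletes the overused charged tRNA pool", {
  sw <- sweep_fop(ratio_params(0.7, k_charge = 3), fop = seq(0, 1, 0.02))
  expect_true(all(diff(sw$T_c1) < 1e-9))  # preferred drains as f_op grows
  expect_true(all(diff(sw$T_c2) > -1e-9)) # non-preferred recovers
  expect_true(all(sw$P_r >= 0))
  expect_true(!is.unsorted(sw$f_op))
})

test_that("charged pools cross near the expression maximum at low charging", {
  p <- ratio_params(0.7, k_charge = 3)
  fm <- find_fop_max(p)
  sw <- sweep_fop(p, fop = seq(0, 1, 0.01))
  d <- sw$T_c1 - sw$T_c2
  crossings <- sw$f_op[which(diff(sign(d)) != 0)]
  expect_length(crossings, 1)
  expect_gt(crossings, fm$f_op_max - 0.1)
  expect_lt(crossings, fm$f_op_max + 0.1)
})

test_that("the expression maximum moves from the tRNA ratio toward one", {
  # symmetric pools: maximum pinned at 1/2 by symmetry at any charging rate
  for (kc in c(3, 30)) {
    fm <- find_fop_max(base_params(k_charge = kc), coarse_step = 0.02)
    expect_equal(fm$f_op_max, 0.5, tolerance = 0.02)
  }
  # skewed pools, charging much slower than elongation turnover: the
  # maximum approaches the preferred-tRNA fraction
  fm_low <- find_fop_max(ratio_params(0.7, k_charge = 0.3))
  expect_equal(fm_low$f_op_max, 0.7, tolerance = 0.02)
  # fast charging: fully optimal usage wins
  fm_high <- find_fop_max(ratio_params(0.9, k_charge = 300))
  expect_equal(fm_high$f_op_max, 1.0, tolerance = 0.02)
  expect_true(all(c(fm_low$f_op_max, fm_high$f_op_max) >= 0 &
                  c(fm_low$f_op_max, fm_high$f_op_max) <= 1))
})

test_that("species-swap symmetry mirrors the expression maximum", {
  fm_07 <- find_fop_max(ratio_params(0.7, k_charge = 10), coarse_step = 0.02)
  fm_03 <- find_fop_max(ratio_params(0.3, k_charge = 10), coarse_step = 0.02)
  expect_equal(fm_03$f_op_max, 1 - fm_07$f_op_max, tolerance = 2e-3)
})

test_that("f_op^max is non-decreasing in k_charge and ordered by skew", {
  map <- sweep_fop_max(
    base_params(),
    fractions = c(0.5, 0.7, 0.9),
    k_charge = exp(seq(log(3), log(300), length.out = 6)),
    coarse_step = 0.02, refine_tol = 1e-3
  )
  for (fr in c(0.7, 0.9)) {
    cur <- map[map$fraction_preferred == fr, ]
    expect_true(all(diff(cur$f_op_max) > -2e-3))
    expect_true(all(cur$f_op_max >= fr - 0.02))
    expect_equal(cur$f_op_max[nrow(cur)], 1, tolerance = 0.02)
  }
  flat_row <- map[map$fraction_preferred == 0.5, ]
  # symmetric case: either pinned at 0.5 or flagged flat at high charging
  expect_true(all(flat_row$flat | abs(flat_row$f_op_max - 0.5) < 0.02))
  # the more skewed pool leaves its floor at a lower charging rate
  leaves <- function(fr) {
    cur <- map[map$fraction_preferred == fr, ]
    idx <- which(cur$f_op_max > fr + 0.05)
    if (length(idx) == 0) Inf else cur$k_charge[min(idx)]
  }
  expect_lt(leaves(0.9), leaves(0.7) + 1e-9)
})

test_that("rescaling tRNA totals with compensated rates leaves expression unchanged", {
  sc <- scaling_deviation(base_params(), alphas = c(0.1, 1, 10))
  expect_lt(sc$max_rel_deviation, 1e-8)
  expect_equal(sc$table$rel_deviation[sc$table$alpha == 1],
               rep(0, 5))
  # property over random parameterizations and scale factors
  set.seed(23)
  for (i in 1:8) {
    p <- random_params()
    a <- 10^runif(1, -1, 1)
    base <- steady_state(p)$P_r
    scaled <- steady_state(update_params(
      p, T1_tot = p$T1_tot * a, T2_tot = p$T2_tot * a,
      k_charge = p$k_charge / a, k_speed = p$k_speed / a
    ))$P_r
    expect_equal(scaled, base, tolerance = 1e-10)
  }
})

test_that("stochastic means respect the scaling law", {
  p <- base_params()
  est1 <- ssa_summary(simulate_ssa(p, t_max = 400, replicates = 4, seed = 6),
                      burn_in = 200)
  p10 <- update_params(p, T1_tot = 12500, T2_tot = 12500,
                       k_charge = p$k_charge / 10, k_speed = p$k_speed / 10)
  est10 <- ssa_summary(simulate_ssa(p10, t_max = 400, replicates = 4, seed = 6),
                       burn_in = 200)
  r1 <- est1[est1$quantity == "protein_rate", ]
  r10 <- est10[est10$quantity == "protein_rate", ]
  expect_lt(abs(r1$mean - r10$mean), 3 * sqrt(r1$se^2 + r10$se^2))
})

test_that("effective codon usage is the codon-mass weighted mean", {
  expect_equal(
    effective_fop(data.frame(copies = c(50, 50), L = 300, f_op = c(0.4, 1))),
    0.7
  )
  expect_equal(effective_fop(data.frame(copies = 10, L = 120, f_op = 0.37)),
               0.37)
  # unequal lengths weight by copies * L
  expect_equal(
    effective_fop(data.frame(copies = c(1, 1), L = c(100, 300),
                             f_op = c(0, 1))),
    0.75
  )
  expect_error(effective_fop(data.frame()), "non-empty")
  expect_error(effective_fop(data.frame(copies = 0, L = 300, f_op = 0.5)),
               "mass")
})

test_that("a mixed transcript pool behaves like its effective-f_op surrogate", {
  p <- base_params()
  classes <- data.frame(copies = c(50, 50), L = 300, f_op = c(0.4, 1))
  surrogate <- mixed_transcript_params(classes, p)
  expect_equal(surrogate$f_op, 0.7)
  expect_equal(surrogate$N, 100)
  expect_equal(surrogate$L, 300)
  ss <- steady_state(surrogate)
  trs <- c(lapply(1:50, function(i) generate_transcript(300, 0.4, seed = i)),
           lapply(1:50, function(i) generate_transcript(300, 1, seed = 100 + i)))
  est <- ssa_summary(
    simulate_ssa_codon(p, trs, t_max = 400, replicates = 4, seed = 3),
    burn_in = 200
  )
  pr <- est[est$quantity == "protein_rate", ]
  expect_lt(abs(pr$mean - ss$P_r), 3 * pr$se)
})
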