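test_that("calibrated baseline reproduces the reference translation properties", {
  # closed-form calibration in helper-params.R is the independent oracle
  p <- base_params()
  sm <- steady_summary(steady_state(p))
  expect_equal(sm$charged_frac_total, 0.88, tolerance = 1e-10)
  expect_equal(sm$active_ribosome_frac, 0.88, tolerance = 1e-10)
  expect_equal(sm$ribosome_density, 0.4888889, tolerance = 1e-6)
  expect_equal(sm$P_r, 484000 * 0.02 / 300, tolerance = 1e-10)
  expect_equal(sm$per_ribosome_speed, 22, tolerance = 1e-10)
})

test_that("calibrate_rates recovers the analytic constants and round-trips", {
  cal <- calibrate_rates(base_params(k_charge = 1, k_bind_eff = 1e-3),
                         target_charged_frac = 0.88,
                         target_active_frac = 0.88)
  expect_equal(cal$k_charge, kc_cal, tolerance = 1e-6)
  expect_equal(cal$k_bind_eff, kb_cal, tolerance = 1e-6)
  sm <- steady_summary(steady_state(cal$params))
  expect_equal(sm$charged_frac_total, 0.88, tolerance = 1e-6)
  expect_equal(sm$active_ribosome_frac, 0.88, tolerance = 1e-6)
  # asymmetric template round-trip
  cal2 <- calibrate_rates(ratio_params(0.7, f_op = 0.6),
                          target_charged_frac = 0.9,
                          target_active_frac = 0.75)
  sm2 <- steady_summary(steady_state(cal2$params))
  expect_equal(sm2$charged_frac_total, 0.9, tolerance = 1e-6)
  expect_equal(sm2$active_ribosome_frac, 0.75, tolerance = 1e-6)
})

test_that("calibration targets at the boundary are rejected", {
  expect_error(calibrate_rates(base_params(), 0.88, 1), "strictly in")
  expect_error(calibrate_rates(base_params(), 1, 0.88), "strictly in")
})

test_that("steady states satisfy all balances and conservation laws", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_params()
    ss <- steady_state(p)
    expect_lt(max(abs(ss$residuals)), 1e-10)
    expect_true(all(unlist(ss$state) >= 0))
    st <- ss$state
    expect_equal(st$T_c1 + st$T_u1, p$T1_tot, tolerance = 1e-12)
    expect_equal(st$T_c2 + st$T_u2, p$T2_tot, tolerance = 1e-12)
    expect_equal(st$R_f + st$R_b1 + st$R_b2, p$R_tot, tolerance = 1e-12)
    # codon-exchange balance
    expect_equal(st$R_b1 * st$T_c1 * (1 - p$f_op),
                 st$R_b2 * st$T_c2 * p$f_op, tolerance = 1e-10)
  }
})

test_that("protein_rate is the termination flux", {
  p <- base_params()
  # direct arithmetic: 0.02 * (220*1100 + 220*1100) / 300
  st <- c(T_c1 = 1100, T_c2 = 1100, T_u1 = 150, T_u2 = 150,
          R_f = 60, R_b1 = 220, R_b2 = 220)
  expect_equal(protein_rate(st, p), 9680 / 300, tolerance = 1e-12)
  idle <- c(T_c1 = 1250, T_c2 = 1250, T_u1 = 0, T_u2 = 0,
            R_f = 500, R_b1 = 0, R_b2 = 0)
  expect_equal(protein_rate(idle, p), 0)
})

test_that("single-codon transcripts leave the unused class untouched", {
  p0 <- base_params(f_op = 0)
  ss0 <- steady_state(p0)
  expect_equal(ss0$state$R_b1, 0)
  expect_equal(ss0$state$T_u1, 0)
  expect_equal(ss0$state$T_c1, p0$T1_tot)
  p1 <- base_params(f_op = 1)
  ss1 <- steady_state(p1)
  expect_equal(ss1$state$R_b2, 0)
  expect_equal(ss1$state$T_c2, p1$T2_tot)
})

test_that("closed-form one-codon solution matches the full solver", {
  set.seed(7)
  for (i in 1:5) {
    p <- random_params()
    for (f in c(0, 1)) {
      pf <- update_params(p, f_op = f)
      cf <- one_codon_steady(pf)
      full <- steady_state(pf, use_closed_form = FALSE)
      expect_equal(unlist(cf$state), unlist(full$state), tolerance = 1e-10)
    }
  }
  # mirror symmetry: f_op = 0 with swapped tRNA pools equals f_op = 1
  p <- ratio_params(0.7)
  s1 <- one_codon_steady(update_params(p, f_op = 1))
  s0 <- one_codon_steady(base_params(T1_tot = 750, T2_tot = 1750, f_op = 0))
  expect_equal(s0$state$T_c2, s1$state$T_c1, tolerance = 1e-12)
  expect_equal(s0$state$R_b2, s1$state$R_b1, tolerance = 1e-12)
  expect_equal(s0$P_r, s1$P_r, tolerance = 1e-12)
})

test_that("infinite-charging limit: harmonic-mean speed and k_charge -> Inf agreement", {
  # equal pools: expression independent of codon usage
  p <- base_params()
  prs <- sapply(c(0, 0.3, 0.5, 0.8, 1), function(f) {
    infinite_charging_rate(update_params(p, f_op = f))$P_r
  })
  expect_lt(diff(range(prs)) / max(prs), 1e-12)
  # matches the full solver at a very large charging rate
  p7 <- ratio_params(0.7, f_op = 0.7)
  lim <- infinite_charging_rate(p7)
  num <- steady_state(update_params(p7, k_charge = 1e6))
  expect_equal(lim$P_r, num$P_r, tolerance = 1e-4)
  # f_op = 1: per-ribosome speed is k_speed * T1_tot
  lim1 <- infinite_charging_rate(update_params(p7, f_op = 1))
  expect_equal(lim1$per_ribosome_speed, 0.02 * 1750, tolerance = 1e-12)
})

test_that("expression rate is non-decreasing in the charging rate", {
  for (frac in c(0.5, 0.7, 0.9)) {
    p <- ratio_params(frac, f_op = 0.8)
    prs <- sapply(exp(seq(log(3), log(300), length.out = 12)), function(kc) {
      steady_state(update_params(p, k_charge = kc))$P_r
    })
    expect_true(all(diff(prs) > -1e-9 * max(prs)))
  }
})

test_that("molar binding constants convert through Avogadro x volume", {
  # 2.5e6 / (6.02214076e23 * 8e-16)
  expect_equal(molar_to_effective_bind(2.5e6, 8e-16), 5.189185e-3,
               tolerance = 1e-6)
  # volume such that N_A * V = 2.5e6 gives exactly 1
  expect_equal(molar_to_effective_bind(2.5e6, 2.5e6 / 6.02214076e23), 1)
  expect_equal(molar_to_effective_bind(2.5e6, 1.6e-15),
               molar_to_effective_bind(2.5e6, 8e-16) / 2)
  expect_error(molar_to_effective_bind(-1, 1e-15), "> 0")
  expect_error(molar_to_effective_bind(2.5e6, 0), "> 0")
})

test_that("glance() reports the steady summary with residual diagnostics", {
  g <- glance(steady_state(base_params()))
  expect_true(all(c("P_r", "charged_frac_total", "active_ribosome_frac",
                    "per_ribosome_speed", "ribosome_density",
                    "max_abs_residual") %in% names(g)))
  expect_lt(g$max_abs_residual, 1e-10)
  expect_true(all(g$charged_frac_total >= 0 & g$charged_frac_total <= 1))
})
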