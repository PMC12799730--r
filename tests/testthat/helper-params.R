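# Calibrated baseline constants, derived analytically (independent of
# calibrate_rates) from the 88% charged / 88% active targets on the
# symmetric reference system (1250/1250 tRNAs, 500 ribosomes, 100
# transcripts x 300 codons, k_speed 0.02):
#   uncharged tRNA per species = 0.12 * 1250 = 150  =>  x_i * ks / kc = 150
#   bound ribosomes per class  = 220 = x_i / (0.88 * 1250)  =>  x_i = 242000
#   total flux S = 484000, kc = S * ks / 300, and the initiation balance
#   kb * N * R_f = ks * S / L with R_f = 60 fixes kb.
kc_cal <- 484000 * 0.02 / 300            # 32.26667 /s
kb_cal <- (0.02 * 484000 / 300) / (100 * 60)  # 5.377778e-3 per molecule /s

base_params <- function(...) {
  p <- two_codon_params(
    T1_tot = 1250, T2_tot = 1250, R_tot = 500, N = 100, L = 300,
    k_charge = kc_cal, k_speed = 0.02, k_bind_eff = kb_cal, f_op = 0.5
  )
  update_params(p, ...)
}

ratio_params <- function(frac, ...) {
  base_params(T1_tot = round(frac * 2500), T2_tot = round((1 - frac) * 2500),
              ...)
}

# valid random parameterization for property-style tests
random_params <- function() {
  two_codon_params(
    T1_tot = round(stats::runif(1, 200, 3000)),
    T2_tot = round(stats::runif(1, 200, 3000)),
    R_tot = round(stats::runif(1, 100, 1000)),
    N = round(stats::runif(1, 20, 200)),
    L = round(stats::runif(1, 50, 500)),
    k_charge = 10^stats::runif(1, -0.5, 2.5),
    k_speed = 10^stats::runif(1, -2.5, -1),
    k_bind_eff = 10^stats::runif(1, -4, -1),
    f_op = stats::runif(1, 0.05, 0.95)
  )
}

expect_conserved <- function(traj, params, tol = 0) {
  expect_true(all(abs(traj$T_c1 + traj$T_u1 - params$T1_tot) <= tol))
  expect_true(all(abs(traj$T_c2 + traj$T_u2 - params$T2_tot) <= tol))
  expect_true(all(abs(traj$R_f + traj$R_b1 + traj$R_b2 - params$R_tot) <= tol))
}
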