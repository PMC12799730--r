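# Reference parameterization of the two-codon translation model.
# Species counts and rate constants shared by the packaged parameter sets;
# the charging and effective binding constants of the calibrated baseline are
# derived at load time by calibrate_rates() against the calibration targets
# below, and the molar binding constant is retained for unit conversion.
T_tot: 2500            # total tRNA molecules
R_tot: 500             # total ribosomes
"N": 100               # transcripts (= ribosome binding sites)
L: 300                 # transcript length, codons
k_speed: 0.02          # elongation constant (per charged tRNA per bound ribosome /s)
k_charge_range: [3, 300]     # charging-rate range explored (/s)
k_bind_molar: 2.5e6          # ribosome binding constant (M^-1 s^-1)
calibration_targets:
  charged_frac: 0.88   # fraction of charged tRNAs
  active_frac: 0.88    # fraction of actively translating ribosomes
ratios:                # preferred-tRNA fraction of each packaged set
  baseline: 0.5
  ratio07: 0.7
  ratio09: 0.9
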