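# Generator presets for the six constant-temperature treatments.
# Calibration: stage-duration means and completion fractions from the
# rearing-table means and n(N) transition counts; sex ratio from adult
# counts; individual-level duration SDs recovered as SE * sqrt(n);
# lifetime-fecundity overdispersion (negative-binomial size) matched the
# same way, truncated to near-Poisson where the implied variance fell
# below the mean. All durations in days, fecundity in eggs/female.
"21C":
  label: "21C"
  "n": 82
  egg_mean: 7.00
  egg_sd: 0.0
  larva_mean: 24.60
  larva_sd: 3.95
  pupa_mean: 5.86
  pupa_sd: 1.00
  egg_surv: 0.3171
  larva_surv: 0.3846
  pupa_surv: 0.7000
  p_female: 0.2857
  adult_mean_f: 4.50
  adult_sd_f: 0.54
  adult_mean_m: 6.20
  adult_sd_m: 2.21
  apop_mean: 1.00
  ovi_days_mean: 1.00
  fecundity_mean: 7.00
  fecundity_size: 50
"24C":
  label: "24C"
  "n": 94
  egg_mean: 6.00
  egg_sd: 0.0
  larva_mean: 14.78
  larva_sd: 1.68
  pupa_mean: 5.67
  pupa_sd: 0.80
  egg_surv: 0.5957
  larva_surv: 0.6429
  pupa_surv: 0.9167
  p_female: 0.5455
  adult_mean_f: 4.28
  adult_sd_f: 0.81
  adult_mean_m: 7.20
  adult_sd_m: 2.09
  apop_mean: 2.06
  ovi_days_mean: 2.29
  fecundity_mean: 349.28
  fecundity_size: 3.27
"27C":
  label: "27C"
  "n": 167
  egg_mean: 4.17
  egg_sd: 0.33
  larva_mean: 16.71
  larva_sd: 1.97
  pupa_mean: 6.02
  pupa_sd: 0.91
  egg_surv: 0.7425
  larva_surv: 0.6452
  pupa_surv: 0.7250
  p_female: 0.5000
  adult_mean_f: 4.34
  adult_sd_f: 1.24
  adult_mean_m: 4.17
  adult_sd_m: 1.29
  apop_mean: 2.03
  ovi_days_mean: 2.28
  fecundity_mean: 293.83
  fecundity_size: 1.73
"30C":
  label: "30C"
  "n": 141
  egg_mean: 3.19
  egg_sd: 0.39
  larva_mean: 13.28
  larva_sd: 2.56
  pupa_mean: 3.71
  pupa_sd: 0.89
  egg_surv: 0.6667
  larva_surv: 0.4149
  pupa_surv: 0.8974
  p_female: 0.4000
  adult_mean_f: 3.50
  adult_sd_f: 1.01
  adult_mean_m: 3.14
  adult_sd_m: 0.64
  apop_mean: 2.00
  ovi_days_mean: 1.75
  fecundity_mean: 164.86
  fecundity_size: 0.96
"33C":
  label: "33C"
  "n": 80
  egg_mean: 3.00
  egg_sd: 0.0
  larva_mean: 11.60
  larva_sd: 1.20
  pupa_mean: 3.85
  pupa_sd: 0.58
  egg_surv: 0.4875
  larva_surv: 0.6410
  pupa_surv: 0.8000
  p_female: 0.3500
  adult_mean_f: 3.14
  adult_sd_f: 0.37
  adult_mean_m: 3.15
  adult_sd_m: 0.54
  apop_mean: 2.00
  ovi_days_mean: 1.00
  fecundity_mean: 3.00
  fecundity_size: 0.52
"36C":
  label: "36C"
  "n": 125
  egg_mean: 2.00
  egg_sd: 0.0
  larva_mean: 5.00
  larva_sd: 1.16
  pupa_mean: 5.00
  pupa_sd: 1.26
  egg_surv: 0.5920
  larva_surv: 0.0541
  pupa_surv: 1.0000
  p_female: 0.5000
  adult_mean_f: 3.00
  adult_sd_f: 1.06
  adult_mean_m: 2.00
  adult_sd_m: 0.96
  apop_mean: 1.50
  ovi_days_mean: 1.00
  fecundity_mean: 7.00
  fecundity_size: 50
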