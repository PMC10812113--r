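settings:
  cycle_length_weeks: 3.0
  horizon_years: 10.0
  annual_discount_rate: 0.05
  wtp_per_qaly: 37304.346
  half_cycle_correction: yes
  discounting: continuous
time_unit: month
conventions:
  vial_policy: round_up_vials
  ae_application: per_cycle
  subsequent_max_cycles: 6.0
patient:
  weight_kg: 60.0
  bsa_m2: 1.72
  crcl: 70.0
prices:
  serplulimab:
    pack_mg: 100.0
    price: 812.209
  etoposide:
    pack_mg: 100.0
    price: 5.661
  carboplatin:
    pack_mg: 100.0
    price: 24.215
utilities:
  pfs: 0.673
  pd: 0.473
other_costs:
  subsequent_per_cycle: 854.05
  followup_per_cycle: 55.6
  bsc_per_cycle: 359.524
ae_costs:
  anemia: 531.723
  wbc_decrease: 461.253
  neutropenia: 84.21
  thrombocytopenia: 1054.0
ae_disutilities:
  anemia: 0.073
  wbc_decrease: 0.2
  neutropenia: 0.2
  thrombocytopenia: 0.19
arms:
  serplulimab:
    os:
      family: loglogistic
      shape: 1.937
      rate: 0.00363
    pfs:
      family: loglogistic
      shape: 2.1
      rate: 0.0129
    ae_incidence:
      anemia: 0.054
      wbc_decrease: 0.085
      neutropenia: 0.141
      thrombocytopenia: 0.062
    subsequent_uptake: 0.442
    has_serplulimab: yes
    chemo_max_cycles: 4.0
    maintenance_max_cycles: 8.0
  chemotherapy:
    os:
      family: loglogistic
      shape: 1.924
      rate: 0.00645
    pfs:
      family: loglogistic
      shape: 2.52
      rate: 0.0152
    ae_incidence:
      anemia: 0.056
      wbc_decrease: 0.087
      neutropenia: 0.138
      thrombocytopenia: 0.082
    subsequent_uptake: 0.434
    has_serplulimab: no
    chemo_max_cycles: 4.0
    maintenance_max_cycles: .inf
metadata:
  label: serplulimab + chemotherapy vs chemotherapy, ES-SCLC, first line
  perspective: Chinese healthcare system
  currency: USD
  exchange_rate_rmb_per_usd: 6.73
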