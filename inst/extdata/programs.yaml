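# Calibrated screening-program parameter sets for the cost-effectiveness
# and harms engines. Means and 95% CIs are the published program-level
# values (2023 USD); distributions are moment-matched to them at run time.
# qaly_per_death for the comparator programs is the benchmark-derived
# discounted QALY gain per death averted (cost per life saved / ICER);
# for the lung programs it is derived from the QALY weight, discount rate
# and a discounted life-year stream back-solved once from the lung ICER
# anchor (see the icer_anchor block).
lung_14:
  label: "Lung LDCT, age-based 40-85 (14.4% participation)"
  eligible_population: 155.5e6
  participation: 0.144
  annual_screen_volume: 13.2e6
  stage1_detection: 0.30
  base_participation: 0.144
  base_stage1_detection: 0.30
  cost_mean: 2.1e9
  cost_ci: [1.5e9, 2.8e9]
  lives_cancer_mean: 20500
  lives_cancer_ci: [12000, 29000]
  lives_all_cause_mean: 103000
  lives_all_cause_ci: [70000, 140000]
  all_cause_reduction: 0.067
  qaly_weight_mean: 0.85
  qaly_weight_sd: 0.05
  discount_rate: 0.03
  icer_anchor: {cost: 2.1e9, lives: 20500, icer: 85000}
  treatment_cost_stage1: [53000, 67000]
  treatment_cost_stage4: [380000, 520000]
  harms:
    false_positive: {mean: 0.147, ci: [0.107, 0.192]}
    invasive_procedure: {mean: 0.012, ci: [0.007, 0.018]}
    complication: {mean: 4.0e-5, ci: [2.0e-5, 8.0e-5]}
lung_70:
  label: "Lung LDCT, age-based 40-85 (70% participation)"
  eligible_population: 155.5e6
  participation: 0.70
  annual_screen_volume: 64.1e6
  stage1_detection: 0.30
  base_participation: 0.70
  base_stage1_detection: 0.30
  cost_mean: 12.8e9
  cost_ci: [8.8e9, 16.8e9]
  lives_cancer_mean: 99700
  lives_cancer_ci: [55300, 144100]
  lives_all_cause_mean: 500600
  lives_all_cause_ci: [339900, 661300]
  all_cause_reduction: 0.067
  qaly_weight_mean: 0.85
  qaly_weight_sd: 0.05
  discount_rate: 0.03
  icer_anchor: {cost: 2.1e9, lives: 20500, icer: 85000}
  treatment_cost_stage1: [53000, 67000]
  treatment_cost_stage4: [380000, 520000]
  harms:
    false_positive: {mean: 0.147, ci: [0.107, 0.192]}
    invasive_procedure: {mean: 0.012, ci: [0.007, 0.018]}
    complication: {mean: 4.0e-5, ci: [2.0e-5, 8.0e-5]}
breast:
  label: "Breast mammography, ages 40-74 biennial (67% participation)"
  eligible_population: 65.7e6
  participation: 0.67
  annual_screen_volume: 44.0e6
  base_participation: 0.67
  cost_mean: 9.5e9
  cost_ci: [7.0e9, 12.0e9]
  lives_cancer_mean: 10700
  lives_cancer_ci: [8700, 12700]
  qaly_per_death: 17.8   # = 890k per life / 50k per QALY
  icer_mean: 50000
  harms:
    false_positive: {mean: 0.075, ci: [0.052, 0.098]}
    invasive_procedure: {mean: 7.5e-4, ci: [3.6e-4, 1.5e-3]}
    complication: {mean: 1.1e-5, ci: [4.5e-6, 2.3e-5]}
colorectal:
  label: "Colorectal, ages 45-75 (69% participation)"
  eligible_population: 105.0e6
  participation: 0.69
  annual_screen_volume: 72.4e6
  base_participation: 0.69
  cost_mean: 12.6e9
  cost_ci: [9.5e9, 16.0e9]
  lives_cancer_mean: 13700
  lives_cancer_ci: [11000, 16500]
  qaly_per_death: 36.8   # = 920k per life / 25k per QALY
  icer_mean: 25000
  harms:
    false_positive: {mean: 0.029, ci: [0.021, 0.044]}
    invasive_procedure: {mean: 5.8e-3, ci: [3.7e-3, 8.8e-3]}
    complication: {mean: 4.4e-5, ci: [2.5e-5, 6.6e-5]}
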