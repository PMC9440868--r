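# Dose-response model parameter fixtures for LDL-C lowering.
# Effects are stored as the magnitude of the proportional change from
# baseline (positive fraction lowered); published estimates are negative
# proportional changes and are negated on ingestion by model_parameters().
# se: standard error of the estimate where reported; fixed parameters carry
# se: 0.0. ci: reported 95% confidence interval, kept for bootstrap checks.

bempedoic_acid:
  monotherapy:
    baseline: 147.1            # mg/dL, typical pre-treatment LDL-C
    baseline_se: 1.1
    kout: 0.01                 # 1/h, fixed first-order LDL-C loss rate
    emax: 0.34                 # maximal fraction of baseline lowered
    emax_se: 0.01
    emax_ci: [0.32, 0.36]
    ed50: 44.0                 # mg, dose at half-maximal effect
    ed50_se: 3.8
    ed50_ci: [36.6, 51.3]
    hill: 1.0                  # fixed; sigmoid variant collapsed to simple Emax
    residual_proportional: 0.084
    residual_additive: 11.4    # mg/dL
    residual_additive_se: 0.6
    iiv_baseline: 0.230        # CV fraction, log-normal
    iiv_emax: 0.362            # CV fraction, log-normal multiplier on emax
  combination:
    emax: 0.34
    ed50: 43.96
    hill: 1.0

statin_shared:
  emax: 0.787                  # common maximal fraction lowered, all statins
  hill: 0.451                  # common Hill coefficient
  gamma: -1.35                 # interaction coefficient with bempedoic acid
  kout: 0.01

statins:
  atorvastatin:
    ed50: 13.1
    max_label_dose: 80
    dose_grid: [10, 20, 40, 80]
    baseline: 177.9            # on pooled combination-study population
    iiv_baseline: 0.271
    residual_proportional: 0.161
    residual_additive: 8.8
  simvastatin:
    ed50: 30.5
    max_label_dose: 80
    dose_grid: [10, 20, 40]
    baseline: 160.4
    iiv_baseline: 0.255
    residual_proportional: 0.135
    residual_additive: 13.3
  rosuvastatin:
    ed50: 4.4
    max_label_dose: 40
    dose_grid: [10, 20, 40]
    baseline: 171.9
    iiv_baseline: 0.304
    residual_proportional: 0.151
    residual_additive: 11.7
  pravastatin:
    ed50: 97.3
    max_label_dose: 80
    dose_grid: [10, 20, 40, 80]
    baseline: 156.7
    iiv_baseline: 0.242
    residual_proportional: 0.100
    residual_additive: 17.9
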