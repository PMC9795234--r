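# Default run configuration: sampling moments for an uncomplicated
# hypertensive population, constraint overrides (bounds as [lower, upper])
# and optimizer budgets.
seed: 1
sampling:
  SBP: [160, 10]       # mmHg
  DBP: [100, 10]       # mmHg
  HR: [75, 10]         # beats/min
  BMI: [29, 5]         # kg/m2
  weight: [80, 20]     # kg
  male_fraction: 0.5
constraints:
  SVR: [700, 1600]     # dyn s/cm5
  LVEDP: [3, 12]       # mmHg
optimizer:
  budget: 3                    # SRES generations per generation stage
  calibration_generations: 8   # SRES generations per drug calibration
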