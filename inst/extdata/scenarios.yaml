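# Simulation scenario presets.
# Durations/means in hours; rates in transcript units per hour.
# sd_additive is a fraction of the expected mean protein signal.
paper-calibrated:
  mean_on: 4.0
  refractory: 3.0
  mean_excess_off: 3.5
  rate_on: 10
  rate_off: 0
  coupling: independent
  duration: 30
  dt: 1
  stagger: 0.5
  cv_multiplicative: 0.05
  sd_additive: 0.01
telegraph-no-refractory:
  mean_on: 4.0
  refractory: 0.0
  mean_excess_off: 6.5
  rate_on: 10
  rate_off: 0
  coupling: independent
  duration: 30
  dt: 0.5
  stagger: 0.0
  cv_multiplicative: 0.05
  sd_additive: 0.01
shared-stimulus:
  mean_on: 4.0
  refractory: 3.0
  mean_excess_off: 3.5
  rate_on: 10
  rate_off: 0
  coupling: shared
  initial_state: "on"
  duration: 21
  dt: 1
  stagger: 0.5
  cv_multiplicative: 0.05
  sd_additive: 0.01
paper-calibrated-21h:
  mean_on: 4.0
  refractory: 3.0
  mean_excess_off: 3.5
  rate_on: 10
  rate_off: 0
  coupling: independent
  duration: 21
  dt: 1
  stagger: 0.5
  cv_multiplicative: 0.05
  sd_additive: 0.01
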