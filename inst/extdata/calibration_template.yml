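# Transfer calibration template.
#
# Transcribe the published regressions appropriate to your taxon and
# region. Each stage records the regression AS PUBLISHED plus its
# direction; the package inverts exactly where needed.
#
# Units: slopes/intercepts of phosphate_water in permil VSMOW;
# water_temperature in degrees C and permil VSMOW. Standard errors and the
# residual standard error (resid_se) are in the published response units;
# cov is the slope-intercept covariance (optional, default 0).

phosphate_water:
  # direction: phosphate_to_water  (water = slope * phosphate + intercept)
  #        or: water_to_phosphate  (phosphate = slope * water + intercept)
  direction: water_to_phosphate
  slope: 0.94          # <- replace with your published value
  intercept: 23.3
  slope_se: 0.02
  intercept_se: 0.25
  resid_se: 0.3
  cov: 0

water_temperature:
  # direction: water_to_temperature (T = slope * water + intercept)
  #        or: temperature_to_water (water = slope * T + intercept)
  direction: temperature_to_water
  slope: 0.58
  intercept: -13.6
  slope_se: 0.015
  intercept_se: 0.2
  resid_se: 0.35
  cov: 0

# Optional season-specific water -> temperature regressions. When absent,
# the annual map above is applied to the seasonal extremes (the default).
# water_temperature_seasonal:
#   warm:
#     direction: water_to_temperature
#     slope: 1.8
#     intercept: 24.0
#   cold:
#     direction: water_to_temperature
#     slope: 1.6
#     intercept: 22.0
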