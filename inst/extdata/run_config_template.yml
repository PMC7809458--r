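# Run configuration template for run_from_config().
# Paths are resolved relative to this file unless absolute.

enamel: enamel_d18O.csv        # required
sr: sr_ratios.csv              # optional
collagen: collagen.csv         # optional
calibration: calibration.yml   # required (see calibration_template.yml)

sr_baseline:                   # required when `sr` is given
  mean: 0.7106
  sd: 0.0004
  source: local plants

# damping geometry (mm); taxon-specific, no defaults are assumed
maturation_length: 12
sample_length: 1.5
damping: true
f_floor: 0.3

method: observed               # or: fitted
k: 2                           # sinusoidality threshold (amplitude / resid sd)
d18O_sd: 0.2                   # 1-sd uncertainty of each extreme (permil)
n_mc: 10000
seed: 1

output_dir: pipeline_out
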