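# Example run configuration: a hysteresis sweep on a small population.
# Omitted model parameters take the package defaults (see ?model_params).
experiment: hysteresis
seed: 1
N_pop: 5000
sigma: 10.0
rates:
- 0.005
- 0.010
- 0.015
- 0.020
- 0.025
max_steps: 500
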