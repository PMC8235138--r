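# Small multinomial simulation: Zipf truth, region and large-alphabet
# estimators, per-draw KL in bits.
generator:
  family: zipf
  m: 5
  s: 1.01
n_grid: [10, 20]
k: 50
estimators: [kt, good_turing, mixture_sg, nml_sg]
alpha: 0.05
metric: kl
unit: bits
master_seed: 1
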