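# Discriminating the plateau exponential dose-response model from an
# exponential-decay rival, specified entirely through expressions.
# Equivalent shortcut:  {fixture: toxicology, error: normal, pair: 2}
error: normal
space: {lower: 0, upper: 1250}
true_model:
  expr: a*(c - (c - 1)*exp(-(x/b)^d))
  par_names: [a, b, c, d]
  nominal: [4.282, 835.571, 0.739, 3.515]
rivals:
  - expr: a*exp(-x/b)
    parameters:
      a: {lower: 0, upper: .inf, sample_lower: 0.1, sample_upper: 10}
      b: {lower: 0, upper: .inf, sample_lower: 1, sample_upper: 5000}
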