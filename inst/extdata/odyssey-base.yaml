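# ODYSSEY-style base scenario: strong design priors (mean 18%, SD 2%),
# flat analysis priors, fixed 10% non-inferiority margin.
alpha: 0.05
margin:
  fixed: 0.10
experimental:
  design: {mean: 0.18, sd: 0.02, round_params: true}   # Beta(66, 302)
  analysis: {alpha: 1, beta: 1}
control:
  design: {alpha: 66, beta: 302}
  analysis: {alpha: 1, beta: 1}
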