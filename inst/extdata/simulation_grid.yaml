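# Full case grid of the type I error study: six RCB layouts and six
# split-plot layouts, each crossed with five values of the varied variance
# component (block variance for RCB, whole-plot error variance for the
# split-plot; all other variances are 1).
reps: 200000
alpha: 0.05
strategies: [exact, nobound, sas_default, r_lmer]
cases:
  - {model: rcb, a: 2, b: 2, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: rcb, a: 2, b: 4, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: rcb, a: 3, b: 2, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: rcb, a: 3, b: 4, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: rcb, a: 4, b: 4, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: rcb, a: 10, b: 3, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: splitplot, a: 2, b: 4, c: 12, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: splitplot, a: 3, b: 2, c: 12, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: splitplot, a: 3, b: 4, c: 12, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: splitplot, a: 3, b: 4, c: 5, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: splitplot, a: 4, b: 4, c: 12, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
  - {model: splitplot, a: 10, b: 3, c: 12, variance_grid: [0.1, 0.3, 0.5, 0.7, 0.9]}
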