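# Example bias-simulator scenario: recording drifts north-east over seven
# decades, so early and late decades sample disjoint portions of the domain.
domain: [0.0, 0.0, 12.0, 12.0]
periods:
  start_year: 1950
  end_year: 2019
  width: 10
taxa:
  sp_common: 0.6
  sp_scarce: 0.3
  sp_rare: 0.1
n_per_period: 120
spatial:
  mode: drifting_window
  frac: 0.09
  drift: [1.4, 1.4]
seed: 42
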