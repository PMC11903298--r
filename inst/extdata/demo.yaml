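# One-command synthetic demonstration run: a seven-year plantation
# landscape with a gradual injected palm decline, classified with a
# frozen k = 8 cluster model and analysed per certification cohort.
seed: 7
out_dir: results/demo
scene:
  width: 120
  height: 120
  cloud_fraction: 0.15
  n_captures: 3
  annual_loss: 0.04
years: [2017, 2018, 2019, 2020, 2021, 2022, 2023]
n_plantations: 12
compositing:
  tau: 0.12
  window: 15
kmeans:
  k: 8
  sample_size: 8000
coverage_mode: mature_plus_immature
model:
  include_year_dummies: true
  ref_year: 2018
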