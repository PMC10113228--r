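# Demo configuration: simulate a small two-site community and run the full
# emergence analysis end to end. Designed to finish in well under a minute.
output_dir: demo_output
seed: 20150101
day_max: 136
min_rows: 100
alpha: 0.05
simulate:
  start_date: "2015-01-01"
  n_days: 137
  species: ["M.myotis", "M.nattereri", "Plecotus"]
sites:
  - site_id: "Mayen-Mauerstollen"
    latitude: 50.33
    longitude: 7.22
  - site_id: "Kaub"
    latitude: 50.08
    longitude: 7.76
model:
  reference_site: "Mayen-Mauerstollen"
  k_st: 10
  k_doy: 20
  k_tensor: 5
  use_f3: true
  method: "UBRE"
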