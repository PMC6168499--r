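# Example gradspheroid run configuration. Units are stated per field;
# omitted fields fall back to the package defaults.
device:
  n_rows: 8          # array rows (one concentration each)
  n_cols: 30         # array columns along the channel
  well_size: 150     # um, square well side
  well_pitch: 155    # um, centre-to-centre
  side_volume_uL: 60       # drug/medium volume per side reservoir
  overflow_height_mm: 0.15 # central overflow-port height
compound:
  name: cisplatin
  molecular_weight: 300.05   # g/mol; sets D unless diffusion_coefficient given
  source_concentration_uM: 250
experiment:
  days: [4, 8]       # imaging days (brightfield; FDA/PI on the final day)
  drug_day: 5        # drug application day; baseline = last imaged day before
  incubation_hours: 12
  establishment_hours: 1
  mode: disaggregation   # or: shrinkage
  true_ec50_uM: 100      # ground truth for the synthetic experiment
  true_hill: 3
  second_application: false
  simulate_gradient: true  # false -> use row_doses_uM directly
analysis:
  exclude_edge_columns: 3
  min_area_um2: 400
  smoothing_px: 1.5
gradient:
  grid_spacing_um: 20      # transverse cell size
  grid_spacing_x_um: 50    # axial cell size
seed: 1
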