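# srbcolumn default run configuration: the study column.
# Undiluted feed solutes with the nominal 1.0 mmol/L ethanol dose; published
# kinetic constants; hard SRB gate at 2.0 mg/L DO; inert calcite packing.
column:
  length: 0.8          # m
  diameter: 0.1        # m
  hrt: 25              # h
  n_cells: 64
  sampling_depths: [0.0, 0.1, 0.2, 0.3, 0.4, 0.6, 0.8]
  temperature: 15      # degC
influent:
  ph: 7.21
  do: 9.17             # mg/L
  so4: 291
  tic: 32.7            # mg HCO3-/L
  zn: 15.8
  cu: 0.606
  cd: 0.0533
  ca: 64.8
  si: 24.3
  ethanol_mmol: 1.0
kinetics:
  k1: 0.24             # L/mmol per time unit
  k2: 0.036
  k3: 0.048
  k4: 0.0098
  k5: 5.0e-6           # 1/s
  time_unit: 3600      # s
  do_gate: 2.0         # mg/L
  gate_sharpness: 0
  calcite_area: 0.05   # m2/g
  calcite_mass: 0      # g per L pore water (0 = inert packing)
thermo: null           # null = bundled table
seed: 1
verbosity: 1
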