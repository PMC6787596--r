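pressure_a:
  name: A
  flow_min: 50.0
  flow_max: 900.0
  orifice_coeff_k: 0.004444444444
  v_offset: 0.2
  v_span: 4.8
  noise_sd: 0.0008
  adc_bits: 10
  v_ref: 5.0
pressure_b:
  name: B
  flow_min: 15.0
  flow_max: 100.0
  orifice_coeff_k: 0.36
  v_offset: 0.2
  v_span: 4.8
  noise_sd: 0.0008
  adc_bits: 10
  v_ref: 5.0
gas_no:
  analyte: 'NO'
  sensitivity: 20.0
  v_baseline: 0.5
  detection_floor: 0.03
  range_max: 0.2
  noise_sd: 0.002
gas_co:
  analyte: CO
  sensitivity: 0.4
  v_baseline: 0.5
  detection_floor: 2.0
  range_max: 10.0
  noise_sd: 0.002
sample_rate: 100.0
fusion_low_edge: 50.0
fusion_high_edge: 100.0
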