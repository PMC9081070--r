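# Default geometry of the modelled hand-held camera module:
# 39 x 39 x 5 mm CZT crystal at 600 V, 16 x 16 anode array with 2.46 mm
# pitch and 1.86 mm pads, with the medium-energy general-purpose collimator.
crystal:
  width_x: 39
  width_y: 39
  thickness: 5
  bias_voltage: 600
  permittivity_rel: 10.9
anodes:
  n_x: 16
  n_y: 16
  pitch: 2.46
  pad_size: 1.86
collimator:
  name: MEGP
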