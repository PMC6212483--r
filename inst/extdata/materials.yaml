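# Materials registry, format version 1.
# model: sellmeier  -> n^2 = 1 + sum_i B_i * L^2 / (L^2 - C_i), L = lambda in um
# model: cauchy     -> n = A0 + A1/L^2 + A2/L^4 + ...
# model: constant   -> n = value (non-dispersive)
# range: valid vacuum-wavelength interval in nm
format_version: 1
materials:
  polystyrene:
    model: sellmeier
    B: [1.4435]
    C: [0.020216]
    range: [400, 1100]
  water:
    model: sellmeier
    B: [0.5684027565, 0.1726177391, 0.02086189578, 0.1130748688]
    C: [0.005101829712, 0.01821153936, 0.02620722293, 10.69792721]
    range: [380, 1200]
  fused_silica:
    model: sellmeier
    B: [0.6961663, 0.4079426, 0.8974794]
    C: [0.004679148, 0.013512063, 97.934003]
    range: [250, 2300]
  streptavidin_layer:
    model: constant
    value: 1.50
    range: [300, 1200]
  pdms:
    model: constant
    value: 1.41
    range: [300, 1200]
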