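# Default clinical objective/constraint template for the baseline plan.
# Doses are total Gy(RBE); weights are the weighted-sum coefficients.
# Structures absent from a given phantom are dropped on load.
objectives:
  - {structure: CTV, function: squared_deviation, weight: 100, d_ref: 54}
  - {structure: CTV, function: dose_uniformity, weight: 100}
  - {structure: PTV, function: squared_deviation, weight: 100, d_ref: 54}
  - {structure: PTV, function: dose_uniformity, weight: 100}
  - {structure: PTV, function: min_dvh, weight: 250, d_ref: 52, volume: 97}
  - {structure: PTVminusCTV, function: squared_underdosing, weight: 250, d_min: 52.5}
  - {structure: PTVminusCTV, function: max_dvh, weight: 250, d_ref: 56, volume: 0}
  - {structure: Fringe3mmInPTV, function: max_dvh, weight: 25, d_ref: 50.25, volume: 0}
  - {structure: VentricularFringeInPTVminusGTV, function: squared_underdosing, weight: 150, d_min: 49}
  - {structure: VentricularFringeInPTVminusGTV, function: max_dvh, weight: 250, d_ref: 52.3, volume: 0}
  - {structure: VentricularFringeInPTVminusGTV, function: squared_deviation, weight: 250, d_ref: 51.3}
  - {structure: VentricularFringeInPTVminusGTV, function: dose_uniformity, weight: 250}
  - {structure: CochleaR, function: max_dvh, weight: 100, d_ref: 45, volume: 0}
  - {structure: InnerEarR, function: max_dvh, weight: 150, d_ref: 44, volume: 0}
constraints:
  - {structure: OpticNerveL, lower: 0, upper: 52}
  - {structure: OpticNerveR, lower: 0, upper: 52}
  - {structure: Chiasm, lower: 0, upper: 52}
  - {structure: Brainstem, lower: 0, upper: 53}
  - {structure: External, lower: 0, upper: 56}
  - {structure: PTV, lower: 0, upper: 59.4}
  - {structure: OpticalSystem2mm, lower: 0, upper: 52}
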