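# SYNTHETIC placeholder utility index configuration.
# The published preference-based valuation of the 9-item health state is
# not in the public domain; these coefficients are a stand-in with the
# right structure (additive decrements, zero at level 1, non-decreasing in
# level) and a scale that maps clinically relevant quality-of-life change
# to utility gains of order 0.01/year. Replace with real coefficients for
# substantive analyses.
selected_items: [item03, item04, item05, item06, item07, item08, item09, item10, item11]
base_value: 0.99
clamp_floor: 0.0
decrements:
  item03: [0.0, 0.005, 0.011, 0.018]
  item04: [0.0, 0.005, 0.011, 0.018]
  item05: [0.0, 0.005, 0.011, 0.018]
  item06: [0.0, 0.005, 0.011, 0.018]
  item07: [0.0, 0.005, 0.011, 0.018]
  item08: [0.0, 0.005, 0.011, 0.018]
  item09: [0.0, 0.005, 0.011, 0.018]
  item10: [0.0, 0.005, 0.011, 0.018]
  item11: [0.0, 0.005, 0.011, 0.018]
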