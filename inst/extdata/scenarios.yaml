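# Deterministic sensitivity scenarios: cost-side modifications applied
# identically to both arms. Components refer to cost_breakdown fields.
- id: pfmt_time_halved
  name: "One-way: participant's time for PFMT halved"
  modifications:
    - component: pfmt_time
      action: scale
      factor: 0.5
- id: laundry_cost_halved
  name: "One-way: cost for laundry halved"
  modifications:
    - component: laundry_loads
      action: scale
      factor: 0.5
- id: laundry_time_excluded
  name: "One-way: participant's time for laundry not included"
  modifications:
    - component: laundry_time
      action: exclude
- id: multiway
  name: "Multiway: PFMT time and laundry cost halved, laundry time excluded"
  modifications:
    - component: pfmt_time
      action: scale
      factor: 0.5
    - component: laundry_loads
      action: scale
      factor: 0.5
    - component: laundry_time
      action: exclude
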