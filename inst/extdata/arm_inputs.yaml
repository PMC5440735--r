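# Arm-level inputs for the group-mean analysis mode: mean annual resource
# amounts ("amount used"), mean annual component costs, and mean QALY gains
# per arm for the base-case deterministic analysis.
amounts_annual:
  app:
    pfmt_hours: 15.66
    laundry_hours: 1.30
    aids: 114.40
    laundry_loads: 10.40
  control:
    pfmt_hours: 9.91
    laundry_hours: 3.38
    aids: 169.60
    laundry_loads: 27.04
component_costs:
  app:
    assessment: 6.4
    treatment_delivery: 0.0
    pfmt_time: 463.7
    laundry_time: 38.5
    aids: 15.4
    laundry_loads: 23.0
  control:
    assessment: 6.4
    treatment_delivery: 0.0
    pfmt_time: 293.4
    laundry_time: 100.1
    aids: 22.7
    laundry_loads: 59.8
qaly_gains:
  app: 0.01006
  control: 0.00158
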