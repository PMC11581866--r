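# Example run configuration. Every key is optional; omitted keys take the
# package defaults. Units: pressures mmHg, volumes mL, rates mL/min,
# durations min unless noted.
subject:
  weight: 40                 # kg
  anesthetic: ketamine       # ketamine | isoflurane | propofol
  noise_sd: 2                # mmHg, additive noise on pressure channels
arc:
  target_map: 65             # resuscitation target
  pace: 6                    # desired MAP rise, mmHg/min
  cvp_threshold: 15          # safety rule engagement
  target_decrement: 2        # iterative target reductions
autobleed:
  target_map: 35             # hypotensive hold target
  tolerance: 2
  cpda_ratio: 7              # blood:anticoagulant volumetric ratio
protocol:
  hold_lactate_threshold_1: 4   # mmol/L, ends the first hold
  hold_max_duration: 90         # min
  hold_lactate_cap_2: 6         # mmol/L, shortens the second hold
seed: 1
out: runs/example
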