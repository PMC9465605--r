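{
  "physiology": {},
  "drug": { "preset": "EGFRvIII-TCB" },
  "doses": [ { "route": "IV", "dose_mgkg": 15 } ],
  "simulation": { "t_end": 48, "rtol": 1e-8, "atol": 1e-10, "body_weight": 0.310 }
}
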