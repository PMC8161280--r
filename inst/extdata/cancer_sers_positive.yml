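name: cancer_sers_positive
bands:
- {label: b382, center: 382, half_window: 10, sign: POSITIVE}
- {label: b394, center: 394, half_window: 10, sign: POSITIVE}
- {label: b600, center: 600, half_window: 10, sign: POSITIVE}
- {label: b713, center: 713, half_window: 10, sign: POSITIVE}
- {label: b854, center: 854, half_window: 10, sign: POSITIVE}
- {label: b1004, center: 1004, half_window: 10, sign: POSITIVE}
- {label: b1132, center: 1132, half_window: 10, sign: POSITIVE}
- {label: b1238, center: 1238, half_window: 10, sign: POSITIVE}
- {label: b1393, center: 1393, half_window: 10, sign: POSITIVE}
- {label: b1560, center: 1560, half_window: 10, sign: POSITIVE}
- {label: b1589, center: 1589, half_window: 10, sign: POSITIVE}
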