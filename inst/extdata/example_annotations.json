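[
  {
    "lesion_class": "microaneurysm",
    "vertices": [[40, 60], [40, 66], [46, 66], [46, 60]]
  },
  {
    "lesion_class": "hemorrhage",
    "vertices": [[120, 150], [118, 162], [128, 168], [134, 156], [127, 148]]
  },
  {
    "lesion_class": "hard_exudate",
    "vertices": [[80, 30], [80, 40], [90, 40], [90, 30]]
  }
]
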