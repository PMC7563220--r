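{
  "name": "combined",
  "mapping": {
    "sat": "fat",
    "visceral_fat": "fat",
    "muscle": "muscle",
    "bone_cortical": "bone_cortical",
    "bone_marrow": "bone_marrow",
    "bone_cancellous": "bone_cancellous",
    "small_intestine_wall": "small_intestine_wall",
    "small_intestine_lumen": "small_intestine_lumen",
    "large_intestine_wall": "large_intestine_wall",
    "large_intestine_lumen": "large_intestine_lumen",
    "bladder_wall": "bladder_wall",
    "urine": "urine",
    "gtv": "gtv",
    "fat": "fat"
  }
}
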