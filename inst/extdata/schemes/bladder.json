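{
  "name": "bladder",
  "mapping": {
    "sat": "fat",
    "visceral_fat": "fat",
    "muscle": "muscle",
    "bone_cortical": "bone_cortical",
    "bone_marrow": "bone_cortical",
    "bone_cancellous": "bone_cortical",
    "small_intestine_wall": "muscle",
    "small_intestine_lumen": "muscle",
    "large_intestine_wall": "muscle",
    "large_intestine_lumen": "muscle",
    "bladder_wall": "bladder_wall",
    "urine": "urine",
    "gtv": "gtv",
    "fat": "fat"
  }
}
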