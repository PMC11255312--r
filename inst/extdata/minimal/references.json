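{
  "salt_tolerant_genera": ["Halo", "Vibrio"],
  "reference_genomes": {
    "Euryarchaeota": [2.1, 2.5, 2.9]
  }
}
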