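{
  "mmad_um": 4,
  "gsd": 2,
  "n_particles": 100000,
  "seed": 20210101,
  "device_fraction": 0.1
}
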