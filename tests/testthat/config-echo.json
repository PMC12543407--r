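{
  "command": "frobnicate",
  "package_version": "0.1.0",
  "out": ".",
  "seed": 1,
  "n": 500,
  "noise_sd": 0.5,
  "endpoint": "MCI",
  "p": 0.5,
  "no_fix_ceiling": false
}
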