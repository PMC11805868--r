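{
  "LC": 2.3,
  "NE_mPFC": 0.4,
  "mPFC": 2.05,
  "NTS": 1.85,
  "NE_NAcc": 0.4,
  "NAcc": 1.55
}
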