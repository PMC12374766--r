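# Shipped compound what-if scenarios. An evidence value given as a list of
# categories is conditioned as an indicator likelihood over the set
# ("one of these"); single categories follow the configured mode
# (hard by default, soft with a weight if requested).
scenarios:
  - name: black_midwest
    evidence: {race: black, region: midwest}
  - name: black_south
    evidence: {race: black, region: south}
  - name: black_midwest_ge65
    evidence: {race: black, region: midwest, age: ge65}
  - name: hispanic_public_payer
    evidence:
      race: hispanic
      insurance: [medicare, medicaid]
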