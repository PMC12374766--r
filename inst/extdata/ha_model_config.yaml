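# Default cohort schema and DAG for the hereditary-angioedema
# mortality-risk network. Topology is configuration: replace edges freely
# (the loader re-checks acyclicity).
variables:
  age: [le17, 18-39, 40-64, ge65]
  race: [white, black, hispanic, other]
  income: [q1, q2, q3, q4]
  region: [northeast, midwest, south, west]
  insurance: [medicare, medicaid, private, other]
  hypertension: ["no", "yes"]
  autoimmune: ["no", "yes"]
  diabetes: ["no", "yes"]
  severity: [minor, moderate, major, extreme]
  mortality: [low, high]
outcome: mortality
edges:
  - age -> hypertension
  - age -> diabetes
  - age -> autoimmune
  - age -> severity
  - age -> mortality
  - race -> hypertension
  - race -> diabetes
  - race -> mortality
  - income -> mortality
  - region -> mortality
  - insurance -> mortality
  - hypertension -> severity
  - hypertension -> mortality
  - autoimmune -> severity
  - autoimmune -> mortality
  - diabetes -> severity
  - diabetes -> mortality
  - severity -> mortality
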