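# Synthetic four-screen pipeline configuration.
# Inputs are simulated; all thresholds are the screening defaults
# (1.8-fold change, FDR < 5%, target-gene t-test p <= 0.05).
seed: 17
simulate:
  n_genes: 250
  n_drugs: 30
  planted_de:
    - label: dorsalization
      conditions: [dNSC, dTAP]
      n_genes: 30
      log2_effect: 2.0
      prop_up: 0.5
    - label: ventralization
      conditions: [lNSC, lTAP]
      n_genes: 30
      log2_effect: 2.0
      prop_up: 0.5
    - label: oligodendrogenesis
      conditions: [OPC, mOL]
      n_genes: 30
      log2_effect: 2.0
      prop_up: 0.5
    - label: rejuvenation
      conditions: [aNSC]
      n_genes: 30
      log2_effect: 2.0
      prop_up: 0.5
  planted_mimics:
    dorsalization: {n_drugs: 2, strength: 0.9, sign: 1}
    ventralization: {n_drugs: 2, strength: 0.9, sign: 1}
    oligodendrogenesis: {n_drugs: 2, strength: 0.9, sign: 1}
    rejuvenation: {n_drugs: 2, strength: 0.9, sign: 1}
  graph_spec:
    n_nodes: 70
    n_edges: 180
cap_min: 10
cap_max: 40
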