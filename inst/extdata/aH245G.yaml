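# Example scenario: histidine 245 of the a-subunit replaced by glycine.
label: aH245G
substitutions:
  - {chain: A, resseq: 245, from: HIS, to: GLY}
source: {chain: A, resseq: [219, 119], role: polar}
sink: {chain: C, resseq: 61, role: polar}
regions:
  - name: W1
    anchor_a: {chain: A, resseq: 214, name: CA}
    anchor_b: {chain: C, resseq: 61, name: CA}
    radius: 3.5
  - name: W2/W3
    anchor_a: {chain: A, resseq: 245, name: CA}
    anchor_b: {chain: A, resseq: 214, name: CA}
    radius: 3.5
gate_residues:
  - {chain: A, resseq: 140}
  - {chain: A, resseq: 119}
md_metadata:
  temperature_K: 310
  ensemble: NPT
  production_ns: 150
  engine: NAMD 2.14
  force_field: CHARMM36
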