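# Binary classification grammar: condition "bound" carries two motifs
# with a 0-3 bp spacing constraint; condition "unbound" is pure
# background drawn from the human-genome nucleotide distribution.
task_type: multiclass
alphabet: DNA
window_length: 150
seed: 1
background:
  default: {A: 0.29565, C: 0.20435, G: 0.20435, T: 0.29565}
conditions:
  - {id: bound, label: dimer bound}
  - {id: unbound, label: no dimer}
elements:
  - id: motif_a
    type: pwm
    matrix:
      - [0.88, 0.04, 0.04, 0.04]
      - [0.04, 0.88, 0.04, 0.04]
      - [0.04, 0.04, 0.04, 0.88]
      - [0.88, 0.04, 0.04, 0.04]
      - [0.04, 0.04, 0.88, 0.04]
      - [0.04, 0.88, 0.04, 0.04]
  - id: motif_b
    type: kmer
    kmers: {TGACGTCA: 0.7, TGACGCCA: 0.3}
rules:
  - condition: bound
    probability: 1.0
    position: random
    elements: [motif_a, motif_b]
    spacing:
      - {a: motif_a, b: motif_b, min_gap: 0, max_gap: 3, order_fixed: true}
set_sizes: {training: 1000, validation: 200, test: 200}
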