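# SYNTHETIC illustrative Ramachandran mixture for an alanine guest residue
# in a GAG-like host-guest peptide: a chiral (asymmetric) ensemble dominated
# by pPII with beta-strand, transition-region, alpha-helical and a minor
# left-handed helical component. Plausible reconstruction for testing and
# demonstration, NOT fitted values.
symmetrize: false
components:
  - label: pPII
    weight: 0.60
    center: [-66, 145]
    widths: [11, 12]
  - label: abeta
    weight: 0.13
    center: [-155, 152]
    widths: [14, 13]
  - label: betat
    weight: 0.10
    center: [-110, 150]
    widths: [11, 12]
  - label: alphaR
    weight: 0.12
    center: [-65, -35]
    widths: [10, 9]
  - label: alphaL
    weight: 0.05
    center: [58, 40]
    widths: [10, 9]
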