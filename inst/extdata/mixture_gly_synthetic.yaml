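# SYNTHETIC illustrative Ramachandran mixture for a central glycine in a
# GGG-like host-guest peptide. Component locations sit in the canonical
# pPII / antiparallel-beta / beta-transition / alpha-helical regions;
# weights and widths are plausible reconstructions chosen for testing and
# demonstration, NOT fitted values (published fits reside in the primary
# spectroscopy literature and are not transcribed here). The right-handed
# half below is chirality-symmetrized on loading (glycine is achiral).
symmetrize: true
components:
  - label: pPII
    weight: 0.46
    center: [-66, 145]
    widths: [11, 13]
  - label: abeta
    weight: 0.24
    center: [-155, 152]
    widths: [14, 13]
  - label: betat
    weight: 0.16
    center: [-110, 150]
    widths: [11, 12]
  - label: alphaR
    weight: 0.14
    center: [-65, -35]
    widths: [10, 9]
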