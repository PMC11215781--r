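# Default two-oscillator amide I' exciton configuration for a tripeptide in
# D2O. Every number here is a CALIBRATION CHOICE, not a measured constant:
# local wavenumbers mimic the N- vs C-terminal amide I' split, the
# transition dipole magnitude/orientation and the Raman tensor anisotropy
# are typical literature-range values, and the bandwidth is a Gaussian
# sigma. Couplings are computed by transition-dipole coupling from the
# idealized peptide geometry unless a coupling function is supplied in code.
nu_local: [1648, 1672]
coupling: tdc
dipole_moment: 0.30
dipole_tilt_deg: 20
dipole_offset: 0.868
bandwidth: 6
raman_par: 1.0
raman_perp: 0.2
grid: {from: 1600, to: 1720, by: 1}
ir_scale: 1
vcd_scale: 1
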