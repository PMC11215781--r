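# Default Karplus parameter library for backbone couplings of host-guest
# peptides. The three-term phi-dependent sets follow the widely used
# Hu & Bax-style parameterizations; the psi-dependent one-bond 1J(N,CA) set
# is a low-order Fourier form with ILLUSTRATIVE coefficients (published fits
# vary). Coefficient sigmas are standard errors in Hz where the literature
# reports them; for 3J_C_Cp and 1J_N_CA no parameter uncertainties are
# available, so chi-square scores fall back on experimental errors alone.
# Edit freely: these are configuration data, not package constants.
observables:
  - observable: 3J_HN_HA
    angle: phi
    form: cos2
    offset_deg: -60
    coefficients: {A: 7.09, B: -1.42, C: 1.55}
    coefficient_sigmas: {A: 0.39, B: 0.13, C: 0.06}
  - observable: 3J_HN_Cp
    angle: phi
    form: cos2
    offset_deg: 180
    coefficients: {A: 4.29, B: -1.01, C: 0.00}
    coefficient_sigmas: {A: 0.31, B: 0.12, C: 0.08}
  - observable: 3J_HA_Cp
    angle: phi
    form: cos2
    offset_deg: 120
    coefficients: {A: 3.72, B: -2.18, C: 1.28}
    coefficient_sigmas: {A: 0.32, B: 0.17, C: 0.12}
  - observable: 3J_HN_CB
    angle: phi
    form: cos2
    offset_deg: 60
    coefficients: {A: 3.06, B: -0.74, C: 0.13}
    coefficient_sigmas: {A: 0.32, B: 0.11, C: 0.07}
  - observable: 3J_C_Cp
    angle: phi
    form: cos2
    offset_deg: 0
    coefficients: {A: 1.36, B: -0.93, C: 0.60}
  - observable: 1J_N_CA
    angle: psi
    form: trig
    offset_deg: 0
    coefficients: {C0: 9.51, A1: -1.70, B1: 0.25, A2: 0.98}
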