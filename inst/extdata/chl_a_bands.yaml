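# Frozen chlorophyll-a-like steady-state band system (glassy solvent).
# Band positions follow the measured excitation spectrum (Qy 0-0 at 670 nm =
# 14925 cm-1; Qx 0-0 near 625 nm = 16000 cm-1 with ~1100 cm-1 vibronic
# spacing; Soret/B bands in the 420-440 nm region). Widths and Huang-Rhys
# factors are stand-ins shaped to resemble the published lineshapes -- the
# source spectra never state them. TDM angles are measured from the emissive
# (Qy fluorescence) transition: the Qy absorption dipole sits 17 deg from it
# (giving the observed anisotropy plateau 0.4*P2(cos 17) = 0.349) and the
# x-polarized transitions at 90 deg, i.e. a Qx-Qy separation of 73 deg.
fixture_version: 1
bands:
  Qy:
    e00: 14925
    omega_vib: 1250
    huang_rhys: 0.30
    sigma: 170
    tdm_angle: 17
    amplitude: 1.0
    n_quanta: 4
  Qx:
    e00: 16000
    omega_vib: 1100
    huang_rhys: 0.70
    sigma: 250
    tdm_angle: 90
    amplitude: 0.18
    n_quanta: 3
  Bx:
    e00: 22989
    omega_vib: 1300
    huang_rhys: 0.50
    sigma: 450
    tdm_angle: 90
    amplitude: 0.90
    n_quanta: 3
  By:
    e00: 23529
    omega_vib: 1300
    huang_rhys: 0.50
    sigma: 450
    tdm_angle: 17
    amplitude: 0.85
    n_quanta: 3
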