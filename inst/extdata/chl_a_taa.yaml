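# Synthetic ground truth for polarized (parallel/perpendicular) TA of
# chlorophyll a in acetone after B-band excitation, used for transient
# absorption anisotropy decomposition. TDM angles are measured from the
# decomposition reference axis: the y-polarized Q species sits at 32 deg
# (so the frame angle beta = 32 deg removes it from the orthogonal
# component) and the x-polarized Qx ground-state bleach at 90 deg. The Qx
# bleach carries two sub-bands at 625/580 nm (16000/17100 cm-1) with an
# 1100 cm-1 vibronic spacing. The B compartment decays with the 110 fs
# transfer time and contributes an early weak excited-state absorption near
# 650 nm. Parallel topology: the bleaches exist from time zero.
fixture_version: 1
excitation_band: B
solvent: acetone
topology: parallel
lifetimes_fs: [110, 5.0e+6, 5.0e+6]
fixed: [false, true, true]
irf_fwhm_fs: 30
t0_fs: 0
axis: {from: 13800, to: 24800, points: 221}
delays: {early: {from: -100, to: 1000, by: 20}}
species:
  - name: B_excited
    tdm_angle: 0
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -1.00}
      - {center: 15385, sigma: 200, amplitude: 0.05}
  - name: Qy
    tdm_angle: 32
    gaussians:
      - {center: 14925, sigma: 250, amplitude: -0.85}
      - {center: 16175, sigma: 250, amplitude: -0.30}
  - name: Qx_gsb
    tdm_angle: 90
    gaussians:
      - {center: 16000, sigma: 300, amplitude: -0.32}
      - {center: 17100, sigma: 300, amplitude: -0.23}
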