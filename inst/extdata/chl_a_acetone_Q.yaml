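# Synthetic ground truth emulating magic-angle TA of chlorophyll a in
# acetone after direct Q-band excitation. Three sequential compartments: an
# ultrafast ~200 fs component with only subtle spectral change (no
# population-transfer signature), a small ~5 ps reorganisation component,
# and the fixed 5 ns excited-state lifetime.
fixture_version: 1
excitation_band: Q
solvent: acetone
topology: sequential
lifetimes_fs: [200, 5000, 5.0e+6]
fixed: [false, false, true]
irf_fwhm_fs: 30
t0_fs: 0
axis: {from: 13800, to: 24800, points: 72}
delays: {early: {from: -200, to: 1000, by: 25}, late: {from: 1200, to: 100000, points: 32}}
species:
  - name: Qy_hot
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -0.50}
      - {center: 14925, sigma: 252, amplitude: -0.90}
      - {center: 17500, sigma: 900, amplitude: 0.20}
  - name: Qy_warm
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -0.50}
      - {center: 14925, sigma: 240, amplitude: -0.96}
      - {center: 17500, sigma: 900, amplitude: 0.20}
  - name: Qy_relaxed
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -0.50}
      - {center: 14925, sigma: 235, amplitude: -1.00}
      - {center: 17450, sigma: 900, amplitude: 0.20}
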