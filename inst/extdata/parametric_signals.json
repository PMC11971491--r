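{
  "comment": "Parametric lipid and macromolecule components following the broad-resonance parameterization published with the TARQUIN analysis method. Amplitudes are in proton-equivalent units; fwhm_hz is the frequency-domain full width at half maximum at 3 Tesla. The inverted -CrCH2 singlet models the effect of water suppression on the creatine/phosphocreatine CH2 resonances.",
  "signals": [
    {"name": "-CrCH2", "components": [
      {"ppm": 3.913, "amplitude": -2.0, "fwhm_hz": 0.5, "shape": "lorentzian"}]},
    {"name": "Lip09", "components": [
      {"ppm": 0.89, "amplitude": 3.0, "fwhm_hz": 18, "shape": "lorentzian"}]},
    {"name": "Lip13a", "components": [
      {"ppm": 1.28, "amplitude": 2.0, "fwhm_hz": 18, "shape": "lorentzian"}]},
    {"name": "Lip13b", "components": [
      {"ppm": 1.28, "amplitude": 2.0, "fwhm_hz": 11, "shape": "lorentzian"}]},
    {"name": "Lip20", "components": [
      {"ppm": 2.04, "amplitude": 1.33, "fwhm_hz": 18, "shape": "lorentzian"},
      {"ppm": 2.25, "amplitude": 0.67, "fwhm_hz": 18, "shape": "lorentzian"},
      {"ppm": 2.80, "amplitude": 0.87, "fwhm_hz": 25, "shape": "lorentzian"}]},
    {"name": "MM09", "components": [
      {"ppm": 0.91, "amplitude": 3.0, "fwhm_hz": 18, "shape": "gaussian"}]},
    {"name": "MM12", "components": [
      {"ppm": 1.21, "amplitude": 2.0, "fwhm_hz": 19, "shape": "gaussian"}]},
    {"name": "MM14", "components": [
      {"ppm": 1.43, "amplitude": 2.0, "fwhm_hz": 22, "shape": "gaussian"}]},
    {"name": "MM17", "components": [
      {"ppm": 1.67, "amplitude": 2.0, "fwhm_hz": 19, "shape": "gaussian"}]},
    {"name": "MM20", "components": [
      {"ppm": 2.08, "amplitude": 1.33, "fwhm_hz": 19, "shape": "gaussian"},
      {"ppm": 2.25, "amplitude": 0.33, "fwhm_hz": 25, "shape": "gaussian"},
      {"ppm": 1.95, "amplitude": 0.33, "fwhm_hz": 19, "shape": "gaussian"},
      {"ppm": 3.00, "amplitude": 0.40, "fwhm_hz": 25, "shape": "gaussian"}]}
  ]
}
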