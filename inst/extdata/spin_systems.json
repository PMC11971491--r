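{
  "comment": "Spin parameters for the simulated metabolite basis. Chemical shifts (ppm) and scalar couplings (Hz) follow the published proton metabolite tables (Govindaraju et al. 2000, NMR Biomed). Each metabolite is split into independently simulated moieties; uncoupled equivalent groups are simulated as one spin with a 'scale' equal to the proton count. Couplings are listed as [spin_a, spin_b, J_hz] with 1-based indices. Glucose is represented by both anomers weighted by their equilibrium fractions.",
  "metabolites": [
    {"name": "Ala", "moieties": [
      {"scale": 1, "shifts_ppm": [3.7746, 1.4667, 1.4667, 1.4667],
       "j_hz": [[1,2,7.234],[1,3,7.234],[1,4,7.234]]}]},
    {"name": "Asp", "moieties": [
      {"scale": 1, "shifts_ppm": [3.8914, 2.8011, 2.6533],
       "j_hz": [[1,2,3.647],[1,3,9.107],[2,3,-17.426]]}]},
    {"name": "Cr", "moieties": [
      {"scale": 3, "shifts_ppm": [3.0270], "j_hz": []},
      {"scale": 2, "shifts_ppm": [3.9130], "j_hz": []}]},
    {"name": "GABA", "moieties": [
      {"scale": 1,
       "shifts_ppm": [3.0128, 3.0128, 1.8890, 1.8890, 2.2840, 2.2840],
       "j_hz": [[1,3,7.30],[1,4,7.30],[2,3,7.30],[2,4,7.30],
                 [3,5,7.30],[3,6,7.30],[4,5,7.30],[4,6,7.30]]}]},
    {"name": "Glc", "moieties": [
      {"scale": 0.36,
       "shifts_ppm": [5.2160, 3.5190, 3.6980, 3.3950, 3.8220, 3.8260, 3.7490],
       "j_hz": [[1,2,3.8],[2,3,9.6],[3,4,9.4],[4,5,9.9],
                 [5,6,1.5],[5,7,6.0],[6,7,-12.1]]},
      {"scale": 0.64,
       "shifts_ppm": [4.6300, 3.2300, 3.4730, 3.3870, 3.4500, 3.8820, 3.7070],
       "j_hz": [[1,2,8.0],[2,3,9.1],[3,4,9.4],[4,5,8.9],
                 [5,6,1.6],[5,7,5.4],[6,7,-12.3]]}]},
    {"name": "Glu", "moieties": [
      {"scale": 1, "shifts_ppm": [3.7433, 2.0375, 2.1200, 2.3378, 2.3520],
       "j_hz": [[1,2,7.331],[1,3,4.651],[2,3,-14.849],[2,4,6.413],
                 [2,5,8.406],[3,4,8.478],[3,5,6.875],[4,5,-15.915]]}]},
    {"name": "Gln", "moieties": [
      {"scale": 1, "shifts_ppm": [3.7530, 2.1290, 2.1090, 2.4320, 2.4540],
       "j_hz": [[1,2,5.847],[1,3,6.500],[2,3,-14.504],[2,4,9.165],
                 [2,5,6.347],[3,4,6.324],[3,5,9.209],[4,5,-15.371]]}]},
    {"name": "GSH", "moieties": [
      {"scale": 2, "shifts_ppm": [3.7690], "j_hz": []},
      {"scale": 1, "shifts_ppm": [4.5608, 2.9264, 2.9747],
       "j_hz": [[1,2,7.09],[1,3,4.71],[2,3,-14.06]]},
      {"scale": 1, "shifts_ppm": [3.7690, 2.1590, 2.1460, 2.5100, 2.5600],
       "j_hz": [[1,2,6.34],[1,3,6.36],[2,3,-15.48],[2,4,6.70],
                 [2,5,7.60],[3,4,7.60],[3,5,6.70],[4,5,-15.92]]}]},
    {"name": "GPC", "moieties": [
      {"scale": 9, "shifts_ppm": [3.2120], "j_hz": []},
      {"scale": 1, "shifts_ppm": [4.3120, 4.3120, 3.7120, 3.7120],
       "j_hz": [[1,3,3.10],[1,4,5.90],[2,3,5.90],[2,4,3.10]]},
      {"scale": 1, "shifts_ppm": [3.6050, 3.6720, 3.9030, 3.8710, 3.9460],
       "j_hz": [[1,2,-14.78],[1,3,6.50],[2,3,4.40],[3,4,5.77],
                 [3,5,4.53],[4,5,-14.78]]}]},
    {"name": "Gly", "moieties": [
      {"scale": 2, "shifts_ppm": [3.5480], "j_hz": []}]},
    {"name": "Lac", "moieties": [
      {"scale": 1, "shifts_ppm": [4.0974, 1.3142, 1.3142, 1.3142],
       "j_hz": [[1,2,6.933],[1,3,6.933],[1,4,6.933]]}]},
    {"name": "Ins", "moieties": [
      {"scale": 1,
       "shifts_ppm": [3.5217, 4.0538, 3.5217, 3.6144, 3.2690, 3.6144],
       "j_hz": [[1,2,2.889],[2,3,3.006],[3,4,9.997],[4,5,9.485],
                 [5,6,9.482],[1,6,9.998]]}]},
    {"name": "NAA", "moieties": [
      {"scale": 3, "shifts_ppm": [2.0080], "j_hz": []},
      {"scale": 1, "shifts_ppm": [4.3817, 2.6727, 2.4863],
       "j_hz": [[1,2,3.861],[1,3,9.821],[2,3,-15.592]]}]},
    {"name": "NAAG", "moieties": [
      {"scale": 3, "shifts_ppm": [2.0420], "j_hz": []},
      {"scale": 1, "shifts_ppm": [4.6070, 2.7210, 2.5190],
       "j_hz": [[1,2,4.41],[1,3,9.52],[2,3,-15.91]]},
      {"scale": 1, "shifts_ppm": [4.1280, 2.0490, 1.8810, 2.1900, 2.1800],
       "j_hz": [[1,2,4.61],[1,3,8.42],[2,3,-14.28],[2,4,10.56],
                 [2,5,6.09],[3,4,4.90],[3,5,11.11],[4,5,-15.28]]}]},
    {"name": "PCho", "moieties": [
      {"scale": 9, "shifts_ppm": [3.2080], "j_hz": []},
      {"scale": 1, "shifts_ppm": [4.2805, 4.2805, 3.6410, 3.6410],
       "j_hz": [[1,3,3.10],[1,4,5.90],[2,3,5.90],[2,4,3.10]]}]},
    {"name": "PCr", "moieties": [
      {"scale": 3, "shifts_ppm": [3.0290], "j_hz": []},
      {"scale": 2, "shifts_ppm": [3.9300], "j_hz": []}]},
    {"name": "PEth", "moieties": [
      {"scale": 1, "shifts_ppm": [3.9765, 3.9765, 3.2160, 3.2160],
       "j_hz": [[1,3,3.18],[1,4,6.72],[2,3,6.72],[2,4,3.18]]}]},
    {"name": "sIns", "moieties": [
      {"scale": 6, "shifts_ppm": [3.3400], "j_hz": []}]},
    {"name": "Tau", "moieties": [
      {"scale": 1, "shifts_ppm": [3.4206, 3.4206, 3.2459, 3.2459],
       "j_hz": [[1,3,6.742],[1,4,6.403],[2,3,6.403],[2,4,6.792]]}]}
  ]
}
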