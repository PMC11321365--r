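{
  "name": "VIS",
  "band_centers_nm": [461, 470.066666666667, 479.133333333333, 488.2, 497.266666666667, 506.333333333333, 515.4, 524.466666666667, 533.533333333333, 542.6, 551.666666666667, 560.733333333333, 569.8, 578.866666666667, 587.933333333333, 597],
  "period": 4,
  "cell_band": [
    [1, 2, 3, 4],
    [5, 6, 7, 8],
    [9, 10, 11, 12],
    [13, 14, 15, 16]
  ],
  "bit_depth": 10,
  "filter_fwhm_nm": 15
}
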