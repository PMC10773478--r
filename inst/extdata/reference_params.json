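{
  "meta": {
    "description": "Published summary estimates from a two-country (India / United Kingdom) anchoring-vignette study of the Edinburgh Postnatal Depression Scale: the naive one-factor graded response model and the vignette-adjusted two-factor model.",
    "scale_note": "Loadings are printed standardized (all in (0,1)); thresholds and vignette severities are on the raw latent-propensity scale (unit residual SD), where values such as 5.51 exceed any standardized bound. load_printed_parameters() converts standardized loadings to raw propensity-scale loadings on load.",
    "orientation": "Ratings oriented so that higher = more distress (reverse-keyed items already flipped).",
    "items": 10,
    "vignettes": ["A", "B", "C", "D", "E", "F"],
    "mu_note": "Latent depression mean difference (UK minus India, India reference 0, SD units), with its printed 95% confidence interval."
  },
  "naive": {
    "loadings_std": [0.54, 0.27, 0.69, 0.74, 0.76, 0.69, 0.84, 0.90, 0.83, 0.71],
    "thresholds": [
      [1.59, 2.24, 2.67],
      [0.97, 1.40, 2.40],
      [0.21, 1.26, 2.55],
      [0.43, 1.39, 2.76],
      [1.12, 1.96, 3.08],
      [0.46, 1.58, 2.86],
      [1.64, 2.70, 3.64],
      [1.07, 2.99, 4.21],
      [1.42, 2.80, 3.72],
      [2.86, 3.37, 4.10]
    ],
    "mu_uk": 0.47,
    "mu_uk_ci": [0.36, 0.59]
  },
  "adjusted": {
    "loadings_std": [0.68, 0.48, 0.64, 0.72, 0.77, 0.67, 0.81, 0.86, 0.83, 0.74],
    "style_loadings_std": [0.01, 0.04, 0.28, 0.20, 0.23, 0.23, 0.27, 0.19, 0.23, 0.31],
    "vignette_severity": {
      "A": [3.05, 2.78, 2.71, 2.47, 3.66, 2.70, 3.86, 3.78, 4.06, 5.51],
      "B": [2.86, 2.60, 1.64, 2.40, 3.84, 2.69, 4.07, 2.64, 3.68, 5.03],
      "C": [2.30, 2.13, 2.05, 2.29, 2.87, 2.09, 3.26, 2.93, 3.23, 5.03],
      "D": [1.97, 1.82, 1.36, 1.62, 2.05, 1.74, 3.03, 2.10, 2.37, 4.16],
      "E": [1.40, 1.61, 0.99, 0.93, 1.89, 1.19, 2.40, 1.51, 0.95, 4.10],
      "F": [0.57, 0.68, -0.25, -0.48, 0.37, -0.70, 0.13, -0.47, 0.39, 1.85]
    },
    "thresholds_IN": [
      [1.73, 2.19, 3.23],
      [0.78, 1.11, 1.99],
      [0.58, 1.53, 2.60],
      [0.40, 1.33, 2.57],
      [1.02, 2.03, 3.32],
      [1.12, 1.62, 2.28],
      [1.58, 2.52, 3.32],
      [0.93, 2.46, 3.31],
      [1.16, 2.11, 3.46],
      [3.16, 4.14, 5.21]
    ],
    "thresholds_UK": [
      [1.17, 2.26, 3.85],
      [1.01, 2.02, 2.89],
      [-0.92, 0.57, 2.30],
      [-0.41, 0.62, 2.34],
      [0.28, 1.35, 3.07],
      [-0.62, 0.90, 2.73],
      [0.61, 1.86, 3.41],
      [-0.37, 1.64, 3.27],
      [0.45, 2.35, 3.77],
      [2.43, 3.01, 4.20]
    ],
    "mu_uk": -0.25,
    "mu_uk_ci": [-0.39, -0.10]
  }
}
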