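{
  "_comment": "Worked-example one-day diets of the nutrient-density educational tool, encoded as per-day totals (single composite pseudo-food consumed at 100 g). total_kcal is the published diet energy; macro kcal are the published per-macronutrient energies.",
  "high": {
    "name": "High nutrient-density one-day diet",
    "total_kcal": 1686,
    "macro_kcal_per_day": {"protein": 293.32, "fat": 475.2, "carbohydrate": 917.48},
    "nutrients_per_day": {
      "protein": 73.33,
      "fat": 52.84,
      "carbohydrate": 229.4,
      "vitamin_a": 1093,
      "vitamin_b1": 1.2,
      "vitamin_b2": 1.31,
      "vitamin_c": 205,
      "vitamin_e": 13.16,
      "niacin": 11.32,
      "potassium": 8074,
      "magnesium": 758,
      "calcium": 884,
      "iron": 29.46,
      "zinc": 13.13,
      "phosphorus": 1196,
      "selenium": 53.22,
      "fiber": 19.27
    }
  },
  "medium": {
    "name": "Medium nutrient-density one-day diet",
    "total_kcal": 2002,
    "macro_kcal_per_day": {"protein": 312.88, "fat": 505.71, "carbohydrate": 1183.41},
    "nutrients_per_day": {
      "protein": 78.22,
      "fat": 56.19,
      "carbohydrate": 296,
      "vitamin_a": 529,
      "vitamin_b1": 1.02,
      "vitamin_b2": 1.06,
      "vitamin_c": 160,
      "vitamin_e": 32.08,
      "niacin": 11.73,
      "potassium": 2577,
      "magnesium": 391,
      "calcium": 772,
      "iron": 21.49,
      "zinc": 11.06,
      "phosphorus": 1246,
      "selenium": 51,
      "fiber": 13.64
    }
  },
  "low": {
    "name": "Low nutrient-density one-day diet",
    "total_kcal": 2362,
    "macro_kcal_per_day": {"protein": 248.04, "fat": 1011.24, "carbohydrate": 1102.72},
    "nutrients_per_day": {
      "protein": 62.01,
      "fat": 112.36,
      "carbohydrate": 275.63,
      "vitamin_a": 406,
      "vitamin_b1": 0.73,
      "vitamin_b2": 1.23,
      "vitamin_c": 72,
      "vitamin_e": 35.98,
      "niacin": 9.93,
      "potassium": 2528,
      "magnesium": 323,
      "calcium": 701,
      "iron": 19.99,
      "zinc": 9.66,
      "phosphorus": 1084,
      "selenium": 53.38,
      "fiber": 17.73
    }
  }
}
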