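total_points: 110.0
components:
- component: cereals_tubers
  basis: group
  basis_id: cereals_tubers
  low: 200.0
  high: 300.0
  max_points: 10.0
- component: vegetables
  basis: group
  basis_id: vegetables
  low: 300.0
  high: 500.0
  max_points: 10.0
- component: fruits
  basis: group
  basis_id: fruits
  low: 200.0
  high: 350.0
  max_points: 10.0
- component: meat
  basis: group
  basis_id: meat
  low: 40.0
  high: 75.0
  max_points: 10.0
- component: fish_seafood
  basis: group
  basis_id: fish_seafood
  low: 40.0
  high: 75.0
  max_points: 10.0
- component: eggs
  basis: group
  basis_id: eggs
  low: 40.0
  high: 50.0
  max_points: 10.0
- component: dairy
  basis: group
  basis_id: dairy
  low: 300.0
  high: 400.0
  max_points: 10.0
- component: legumes_nuts
  basis: group
  basis_id: legumes_nuts
  low: 30.0
  high: 50.0
  max_points: 10.0
- component: oils_moderation
  basis: group
  basis_id: oils_fats
  low: 0.0
  high: 30.0
  max_points: 10.0
- component: sodium_moderation
  basis: nutrient
  basis_id: sodium_mg
  low: 0.0
  high: 2000.0
  max_points: 10.0
- component: energy
  basis: nutrient
  basis_id: energy_kcal
  low: 1600.0
  high: 2400.0
  max_points: 10.0
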