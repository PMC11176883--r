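#' Combo-meal templates
#'
#' The six price-tiered dish-combination templates used for combo assembly.
#' Each template prescribes a multiset of dish-category slots; a combo
#' instantiates exactly one template with distinct dishes of the required
#' categories.
#'
#' @return Tibble with columns `template_id`, `price_tier`, `dish_count` and
#'   `slots` (list-column; each element a list of allowed-category vectors,
#'   one per slot).
#' @export
#' @examples
#' combo_templates()
combo_templates <- function() {
  tibble(
    template_id = c("high_a", "high_b", "intermediate_high_a",
                    "intermediate_high_b", "intermediate", "low"),
    price_tier = c("high", "high", "intermediate-high", "intermediate-high",
                   "intermediate", "low"),
    dish_count = c(4L, 4L, 3L, 3L, 2L, 2L),
    slots = list(
      list("animal-derived", "vegan", "staple", "soup"),
      list("omnivorous", "omnivorous", "staple", "soup"),
      list("animal-derived", "vegan", "staple"),
      list("omnivorous", "omnivorous", "staple"),
      list(c("animal-derived", "omnivorous"), "complete"),
      list("vegan", "complete")))
}

#' Energy and macronutrient budget for one recommended lunch
#'
#' Encodes the per-user energy window and fat bound applied by
#' [check_constraints()]: daily energy is `kcal_per_kg * weight_kg` with the
#' per-kg range `[kcal_per_kg_low, kcal_per_kg_high]`; the lunch window is
#' `[daily_low * lunch_fraction_low, daily_high * lunch_fraction_high]`. The
#' default lunch fraction 0.40 follows the 3:4:3 daily energy split across
#' three meals; per-day restrict bounds and guideline ranges are scaled to
#' the lunch by `lunch_fraction`. Disease-specific overrides narrow the
#' window (by default diabetes restricts the lunch energy share to
#' 30\%-35\%), and the share of energy from fat is capped at
#' `fat_fraction_max`.
#'
#' @param kcal_per_kg_low,kcal_per_kg_high Daily energy prescription per kg
#'   of body weight (default 20-25 kcal/kg).
#' @param lunch_fraction Fraction of daily intake assigned to lunch
#'   (default 0.40); also used to scale daily restrict/guideline bounds.
#' @param lunch_fraction_low,lunch_fraction_high Lunch energy-share window;
#'   default both equal `lunch_fraction`.
#' @param fat_fraction_max Maximum share of combo energy from fat
#'   (default 0.25).
#' @param energy_nutrient,fat_nutrient Nutrient ids carrying energy (kcal)
#'   and fat (g).
#' @param fat_kcal_per_g Energy density of fat (default 9 kcal/g).
#' @param overrides Named list of per-disease overrides; each element may
#'   reset `lunch_fraction_low`/`lunch_fraction_high`.
#' @return An `energy_budget` list.
#' @export
energy_budget <- function(kcal_per_kg_low = 20, kcal_per_kg_high = 25,
                          lunch_fraction = 0.40,
                          lunch_fraction_low = NULL,
                          lunch_fraction_high = NULL,
                          fat_fraction_max = 0.25,
                          energy_nutrient = "energy_kcal",
                          fat_nutrient = "fat_g", fat_kcal_per_g = 9,
                          overrides = list(
                            diabetes = list(lunch_fraction_low = 0.30,
                                            lunch_fraction_high = 0.35))) {
  assert_that(kcal_per_kg_low > 0 && kcal_per_kg_low <= kcal_per_kg_high,
              "energy budget requires 0 < kcal_per_kg_low <= kcal_per_kg_high")
  assert_that(lunch_fraction > 0 && lunch_fraction < 1,
              "lunch_fraction must be in (0, 1)")
  structure(list(
    kcal_per_kg_low = kcal_per_kg_low, kcal_per_kg_high = kcal_per_kg_high,
    lunch_fraction = lunch_fraction,
    lunch_fraction_low = lunch_fraction_low %||% lunch_fraction,
    lunch_fraction_high = lunch_fraction_high %||% lunch_fraction,
    fat_fraction_max = fat_fraction_max, energy_nutrient = energy_nutrient,
    fat_nutrient = fat_nutrient, fat_kcal_per_g = fat_kcal_per_g,
    overrides = overrides), class = "energy_budget")
}

# lunch energy window and fractions after disease overrides
resolve_budget <- function(budget, diseases) {
  lf_lo <- budget$lunch_fraction_low
  lf_hi <- budget$lunch_fraction_high
  for (d in intersect(names(budget$overrides), diseases)) {
    ov <- budget$overrides[[d]]
    lf_lo <- ov$lunch_fraction_low %||% lf_lo
    lf_hi <- ov$lunch_fraction_high %||% lf_hi
  }
  list(lf_lo = lf_lo, lf_hi = lf_hi, lf = budget$lunch_fraction)
}
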