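#' Seeded synthetic food databases and cohorts
#'
#' Generates food databases and older-adult cohorts with the structural and
#' distributional features of a community-canteen setting: by default 180
#' dishes over 112 ingredients in 20 categories, 27 nutrients, 30 diseases,
#' and a 96-person cohort in which roughly 35\% of members have tracked
#' eating histories and the leading chronic conditions have prevalences of
#' 59\% (hypertension), 31\% (arthritis) and 24\% (diabetes). Everything is
#' deterministic for a fixed seed.
#'
#' @name syndata
NULL

SYN_CATEGORIES <- c(
  "rice_products", "leafy_vegetables", "pork", "seasonings", "cooking_oils",
  "fish", "eggs", "soy_products", "root_vegetables", "poultry",
  "wheat_products", "tubers", "gourd_vegetables", "mushrooms", "fruits",
  "beef_lamb", "organ_meats", "shellfish", "dairy", "nuts")

SYN_NUTRIENTS <- tibble(
  nutrient_id = c("energy_kcal", "protein_g", "fat_g", "carbohydrate_g",
                  "sodium_mg", "cholesterol_mg", "fiber_g", "calcium_mg",
                  "iron_mg", "zinc_mg", "selenium_ug", "potassium_mg",
                  "magnesium_mg", "phosphorus_mg", "vit_a_ug", "vit_b1_mg",
                  "vit_b2_mg", "niacin_mg", "vit_b6_mg", "vit_b12_ug",
                  "vit_c_mg", "vit_d_ug", "vit_e_mg", "folate_ug",
                  "iodine_ug", "copper_mg", "manganese_mg"),
  unit = c("kcal", "g", "g", "g", "mg", "mg", "g", "mg", "mg", "mg", "ug",
           "mg", "mg", "mg", "ug", "mg", "mg", "mg", "mg", "ug", "mg", "ug",
           "mg", "ug", "ug", "mg", "mg"))

SYN_DISEASES <- c(
  "hypertension", "arthritis", "diabetes", "dyslipidemia", "osteoporosis",
  "coronary_heart_disease", "cataract", "cerebral_infarction", "gout",
  "copd", "chronic_kidney_disease", "fatty_liver", "chronic_gastritis",
  "anemia", "hypothyroidism", "parkinson_disease", "depression", "insomnia",
  "chronic_constipation", "gallstones", "chronic_hepatitis", "asthma",
  "prostatic_hyperplasia", "glaucoma", "hearing_impairment",
  "mild_cognitive_impairment", "sarcopenia", "peripheral_neuropathy",
  "varicose_veins", "chronic_bronchitis")

# default marginal prevalences; the three leading conditions match the
# target cohort, the tail is a plausible declining profile
default_prevalences <- function(n = 30) {
  p <- c(0.59, 0.31, 0.24, 0.15, 0.12, 0.10, 0.10, 0.05, 0.05, 0.04, 0.03,
         rep(0.025, 19))
  setNames(p[seq_len(n)], SYN_DISEASES[seq_len(n)])
}

# per-100g macronutrient priors (uniform ranges) by ingredient category
MACRO_PRIORS <- list(
  rice_products = list(p = c(2, 8), f = c(0.3, 2), c = c(20, 60)),
  wheat_products = list(p = c(4, 12), f = c(0.5, 3), c = c(25, 60)),
  tubers = list(p = c(1, 3), f = c(0.1, 0.5), c = c(12, 25)),
  leafy_vegetables = list(p = c(1, 3), f = c(0.1, 0.6), c = c(2, 6)),
  root_vegetables = list(p = c(1, 2.5), f = c(0.1, 0.5), c = c(4, 12)),
  gourd_vegetables = list(p = c(0.5, 2), f = c(0.1, 0.4), c = c(2, 7)),
  mushrooms = list(p = c(2, 4), f = c(0.1, 0.6), c = c(2, 7)),
  fruits = list(p = c(0.3, 1.2), f = c(0.1, 0.5), c = c(8, 20)),
  pork = list(p = c(14, 22), f = c(4, 10), c = c(0, 2)),
  poultry = list(p = c(16, 24), f = c(3, 8), c = c(0, 2)),
  beef_lamb = list(p = c(18, 26), f = c(3, 8), c = c(0, 2)),
  organ_meats = list(p = c(14, 20), f = c(3, 8), c = c(1, 4)),
  fish = list(p = c(15, 22), f = c(1, 8), c = c(0, 2)),
  shellfish = list(p = c(10, 18), f = c(0.5, 3), c = c(1, 4)),
  eggs = list(p = c(11, 14), f = c(8, 12), c = c(1, 3)),
  dairy = list(p = c(3, 4), f = c(3, 4), c = c(4, 6)),
  soy_products = list(p = c(8, 18), f = c(4, 10), c = c(2, 8)),
  nuts = list(p = c(14, 24), f = c(40, 60), c = c(10, 20)),
  cooking_oils = list(p = c(0, 0.1), f = c(99, 100), c = c(0, 0.1)),
  seasonings = list(p = c(0, 2), f = c(0, 0.5), c = c(0, 5)))

# log-uniform micro-nutrient priors per 100 g (nutrient-native units),
# before source-category multipliers
MICRO_PRIORS <- list(
  fiber_g = c(0.3, 1.2), calcium_mg = c(8, 40), iron_mg = c(0.3, 1.5),
  zinc_mg = c(0.3, 1.2), selenium_ug = c(1, 6), potassium_mg = c(60, 200),
  magnesium_mg = c(8, 40), phosphorus_mg = c(30, 120),
  vit_a_ug = c(2, 15), vit_b1_mg = c(0.02, 0.12), vit_b2_mg = c(0.02, 0.12),
  niacin_mg = c(0.3, 1.5), vit_b6_mg = c(0.02, 0.15),
  vit_b12_ug = c(0.2, 0.8), vit_c_mg = c(0.5, 3), vit_d_ug = c(0.1, 0.5),
  vit_e_mg = c(0.2, 1.2), folate_ug = c(4, 20), iodine_ug = c(0.5, 4),
  copper_mg = c(0.04, 0.2), manganese_mg = c(0.1, 0.6))

# source structure of micronutrients: per-category multipliers applied to
# the base priors, mirroring how real food composition concentrates each
# micronutrient in particular food groups (this is what makes nutrient
# adequacy reward food-group coverage)
veg_cats <- c("leafy_vegetables", "root_vegetables", "gourd_vegetables")
meat_cats <- c("pork", "poultry", "beef_lamb")
sea_cats <- c("fish", "shellfish")
mult_for <- function(default, ...) {
  m <- c(...)
  out <- setNames(rep(default, length(SYN_CATEGORIES)), SYN_CATEGORIES)
  out[names(m)] <- m
  out
}
MICRO_SOURCES <- list(
  fiber_g = mult_for(0.05, setNames(rep(5, 3), veg_cats), mushrooms = 6,
                     fruits = 3, wheat_products = 3, tubers = 3,
                     soy_products = 4, nuts = 5),
  calcium_mg = mult_for(0.3, dairy = 14, soy_products = 4, shellfish = 2),
  iron_mg = mult_for(0.3, organ_meats = 12, setNames(rep(4, 3), meat_cats),
                     soy_products = 2),
  zinc_mg = mult_for(0.3, shellfish = 9, setNames(rep(5, 3), meat_cats),
                     organ_meats = 5),
  selenium_ug = mult_for(0.3, setNames(rep(8, 2), sea_cats),
                         organ_meats = 5, eggs = 2),
  potassium_mg = mult_for(0.3, setNames(rep(3, 3), veg_cats), fruits = 3,
                          tubers = 3, mushrooms = 3),
  magnesium_mg = mult_for(0.3, nuts = 6, soy_products = 4,
                          wheat_products = 2),
  phosphorus_mg = mult_for(0.3, setNames(rep(3, 2), sea_cats), eggs = 3,
                           dairy = 3, setNames(rep(2, 3), meat_cats)),
  vit_a_ug = mult_for(0.3, organ_meats = 40, eggs = 8,
                      leafy_vegetables = 6, gourd_vegetables = 4),
  vit_b1_mg = mult_for(0.3, pork = 7, wheat_products = 3,
                       soy_products = 2),
  vit_b2_mg = mult_for(0.3, organ_meats = 9, eggs = 5, dairy = 4,
                       mushrooms = 3),
  niacin_mg = mult_for(0.3, setNames(rep(5, 3), meat_cats), fish = 4,
                       organ_meats = 5, mushrooms = 2),
  vit_b6_mg = mult_for(0.3, setNames(rep(4, 3), meat_cats), fish = 3,
                       tubers = 2),
  vit_b12_ug = mult_for(0.02, organ_meats = 15, setNames(rep(7, 2), sea_cats),
                        setNames(rep(4, 3), meat_cats), eggs = 3, dairy = 2),
  vit_c_mg = mult_for(0.2, setNames(rep(12, 3), veg_cats), fruits = 16,
                      tubers = 5),
  vit_d_ug = mult_for(0.05, fish = 16, eggs = 2),
  vit_e_mg = mult_for(0.3, nuts = 7, cooking_oils = 9, soy_products = 3),
  folate_ug = mult_for(0.3, leafy_vegetables = 9, soy_products = 3),
  iodine_ug = mult_for(0.3, setNames(rep(12, 2), sea_cats), seasonings = 2),
  copper_mg = mult_for(0.3, organ_meats = 9, shellfish = 6, nuts = 4,
                       mushrooms = 3),
  manganese_mg = mult_for(0.3, nuts = 5, rice_products = 3,
                          wheat_products = 3))

#' Specify a synthetic world
#'
#' Defaults reproduce the reference censuses: 180 dishes, 112 ingredients,
#' 20 ingredient categories, 27 nutrients, 30 diseases, a 96-person cohort
#' with a 34/96 tracked fraction and the default disease prevalences.
#'
#' @param n_dishes,n_ingredients,n_categories,n_nutrients,n_diseases Entity
#'   counts.
#' @param cohort_size Number of cohort members.
#' @param tracked_fraction Fraction of the cohort given a tracked eating
#'   history (at least 5 records).
#' @param disease_prevalences Named numeric vector of marginal prevalences
#'   (defaults cover the generated disease list).
#' @param frailty_rho Shared-frailty correlation of the Gaussian copula used
#'   for multimorbidity (0 = independent diseases). Default 0.1.
#' @param seed Default seed used by the generators when none is passed.
#' @return A `world_spec` list.
#' @export
world_spec <- function(n_dishes = 180, n_ingredients = 112,
                       n_categories = 20, n_nutrients = 27, n_diseases = 30,
                       cohort_size = 96, tracked_fraction = 34 / 96,
                       disease_prevalences = NULL, frailty_rho = 0.1,
                       seed = 1) {
  assert_that(all(c(n_dishes, n_ingredients, n_categories, n_nutrients,
                    n_diseases, cohort_size) >= 0),
              "all world counts must be nonnegative", "eldermeal_spec_error")
  assert_that(n_categories <= length(SYN_CATEGORIES),
              paste0("at most ", length(SYN_CATEGORIES),
                     " ingredient categories are available"),
              "eldermeal_spec_error")
  assert_that(tracked_fraction >= 0 && tracked_fraction <= 1,
              "tracked_fraction must be in [0, 1]", "eldermeal_spec_error")
  prev <- disease_prevalences %||% default_prevalences(n_diseases)
  assert_that(all(prev >= 0 & prev <= 1),
              "disease prevalences must lie in [0, 1]", "eldermeal_spec_error")
  structure(list(n_dishes = n_dishes, n_ingredients = n_ingredients,
                 n_categories = n_categories, n_nutrients = n_nutrients,
                 n_diseases = n_diseases, cohort_size = cohort_size,
                 tracked_fraction = tracked_fraction,
                 disease_prevalences = prev, frailty_rho = frailty_rho,
                 seed = seed),
            class = "world_spec")
}

runif_range <- function(n, r) runif(n, r[1], r[2])
rlogunif <- function(n, r) exp(runif(n, log(r[1]), log(r[2])))

#' Generate a synthetic food database
#'
#' Produces the four input tables of [build_graph()]: a long-format recipe
#' table in which every dish category is represented, an ingredient
#' composition table with category-specific macronutrient profiles and
#' log-uniform micronutrient magnitudes, a disease-rule table in which every
#' disease carries at least one discourage and one restrict relation, and
#' nutrient guideline ranges calibrated around typical combo totals.
#' Recipes are returned with per-dish sodium already inside the standard
#' 0.8\%-1.0\% band, and no two dishes share an ingredient set at or above
#' the 0.85 duplicate threshold.
#'
#' @param spec A [world_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return Named list of tibbles: `recipes`, `composition`, `disease_rules`,
#'   `guidelines`.
#' @export
generate_food_database <- function(spec = world_spec(), seed = NULL) {
  seed <- seed %||% spec$seed
  with_seed(seed, generate_food_database_impl(spec))
}

generate_food_database_impl <- function(spec) {
  if (spec$n_dishes > 0 && spec$n_dishes < length(DISH_CATEGORIES)) {
    abort("n_dishes too small to cover the six dish categories",
          class = "eldermeal_spec_error")
  }
  if (spec$n_dishes > 0) {
    assert_that(spec$n_categories >= 6,
                "need at least the first 6 ingredient categories to assemble dishes",
                "eldermeal_spec_error")
    assert_that(spec$n_nutrients >= 6,
                "need at least the 6 core nutrients", "eldermeal_spec_error")
    assert_that(spec$n_ingredients >= spec$n_categories,
                "need at least one ingredient per category",
                "eldermeal_spec_error")
  }
  cats <- SYN_CATEGORIES[seq_len(spec$n_categories)]
  nutrients <- SYN_NUTRIENTS[seq_len(spec$n_nutrients), ]
  composition <- synth_ingredients(spec, cats, nutrients)
  recipes <- synth_dishes(spec, composition, cats)
  if (nrow(recipes) > 0 && "sodium_mg" %in% nutrients$nutrient_id) {
    recipes <- standardize_sodium(recipes, composition)
  }
  cal <- calibrate_combo_totals(recipes, composition)
  guidelines <- synth_guidelines(nutrients, cal)
  disease_rules <- synth_disease_rules(spec, composition, cats, cal)
  list(recipes = recipes, composition = composition,
       disease_rules = disease_rules, guidelines = guidelines)
}

synth_ingredients <- function(spec, cats, nutrients) {
  n <- spec$n_ingredients
  if (n == 0) {
    return(tibble(ingredient_id = character(), name = character(),
                  category_id = character(), nutrient_id = character(),
                  amount_per_100g = double(), unit = character()))
  }
  # one ingredient per category first, extras spread round-robin over the
  # food (non-seasoning, non-oil) categories
  assign <- cats
  food_cats <- setdiff(cats, c("seasonings", "cooking_oils"))
  if (n > length(cats)) {
    assign <- c(assign, rep_len(food_cats, n - length(cats)))
  }
  assign <- assign[seq_len(n)]
  ids <- sprintf("ing_%03d", seq_len(n))
  names_ <- paste0(assign, "_", ave(seq_len(n), assign, FUN = seq_along))

  per_ing <- lapply(seq_len(n), function(i) {
    cat <- assign[i]
    pr <- MACRO_PRIORS[[cat]]
    p <- runif_range(1, pr$p); f <- runif_range(1, pr$f)
    cb <- runif_range(1, pr$c)
    vals <- c(energy_kcal = 4 * p + 9 * f + 4 * cb, protein_g = p,
              fat_g = f, carbohydrate_g = cb)
    vals["sodium_mg"] <- if (cat == "seasonings") {
      if (i == match("seasonings", assign)) 39000 else rlogunif(1, c(2000, 15000))
    } else rlogunif(1, c(1, 120))
    vals["cholesterol_mg"] <- switch(
      cat,
      pork = , poultry = , beef_lamb = runif(1, 40, 120),
      organ_meats = runif(1, 200, 400), eggs = runif(1, 350, 550),
      shellfish = runif(1, 100, 200), fish = runif(1, 40, 80),
      dairy = runif(1, 5, 15), 0)
    for (m in intersect(names(MICRO_PRIORS), nutrients$nutrient_id)) {
      vals[m] <- rlogunif(1, MICRO_PRIORS[[m]]) * MICRO_SOURCES[[m]][[cat]]
    }
    vals[nutrients$nutrient_id]
  })
  amounts <- do.call(rbind, per_ing)
  tibble(ingredient_id = rep(ids, each = nrow(nutrients)),
         name = rep(names_, each = nrow(nutrients)),
         category_id = rep(assign, each = nrow(nutrients)),
         nutrient_id = rep(nutrients$nutrient_id, n),
         amount_per_100g = round(as.numeric(t(amounts)), 4),
         unit = rep(nutrients$unit, n))
}

# main-ingredient pools by culinary role, restricted to available categories
role_pools <- function(ing_cat, cats) {
  pool <- function(want) {
    names(ing_cat)[ing_cat %in% intersect(want, cats)]
  }
  list(cereal = pool(c("rice_products", "wheat_products", "tubers")),
       veg = pool(c("leafy_vegetables", "root_vegetables",
                    "gourd_vegetables", "mushrooms")),
       meat = pool(c("pork", "poultry", "beef_lamb", "organ_meats")),
       fish = pool(c("fish", "shellfish")),
       egg = pool("eggs"), legume = pool(c("soy_products", "nuts")),
       fruit = pool("fruits"), dairy = pool("dairy"),
       salt = pool("seasonings"), oil = pool("cooking_oils"))
}

DISH_CATEGORY_PROPS <- c("animal-derived" = 0.20, vegan = 0.22,
                         omnivorous = 0.18, staple = 0.15, soup = 0.13,
                         complete = 0.12)

# per-dish energy windows (kcal per portion, oil included) by dish
# category, sized so template combos span the 20-25 kcal/kg lunch window of
# a typical older adult (roughly 480-680 kcal at the 0.40 lunch share)
DISH_ENERGY_KCAL <- list(
  staple = c(160, 300), vegan = c(70, 150), "animal-derived" = c(140, 260),
  omnivorous = c(120, 220), soup = c(40, 110), complete = c(300, 450))

synth_dishes <- function(spec, composition, cats) {
  empty <- tibble(dish_id = character(), name = character(),
                  dish_category = character(), flavor = character(),
                  cooking_method = character(), price_level = integer(),
                  ingredient_id = character(), grams = double())
  if (spec$n_dishes == 0) return(empty)
  ing_cat <- setNames(
    composition$category_id[!duplicated(composition$ingredient_id)],
    composition$ingredient_id[!duplicated(composition$ingredient_id)])
  e_rows <- composition[composition$nutrient_id == "energy_kcal", ]
  ing_energy <- setNames(e_rows$amount_per_100g, e_rows$ingredient_id)
  pools <- role_pools(ing_cat, cats)
  counts <- round(DISH_CATEGORY_PROPS * spec$n_dishes)
  counts[1] <- spec$n_dishes - sum(counts[-1])
  dish_cats <- rep(names(counts), counts)

  flavors <- c("salty", "light", "sweet", "spicy", "sour")
  methods <- c("steamed", "stir-fried", "boiled", "stewed", "braised",
               "cold-dressed")
  sets_seen <- list()
  l_ing <- vector("list", spec$n_dishes)
  l_g <- vector("list", spec$n_dishes)
  d_flavor <- character(spec$n_dishes)
  d_method <- character(spec$n_dishes)
  d_price <- integer(spec$n_dishes)
  for (i in seq_len(spec$n_dishes)) {
    dc <- dish_cats[i]
    use_oil <- length(pools$oil) > 0 && !dc %in% c("soup", "staple")
    for (attempt in 1:200) {
      mains <- dish_mains(dc, pools)
      full <- sort(c(names(mains),
                     if (length(pools$salt)) pools$salt[1],
                     if (use_oil) pools$oil[1]))
      dup <- any(vapply(sets_seen, function(s) set_jaccard(s, full) >= 0.85,
                        logical(1)))
      if (!dup) break
      if (attempt == 200) {
        abort("could not draw a sufficiently distinct ingredient set",
              class = "eldermeal_spec_error")
      }
    }
    sets_seen[[i]] <- full
    # plain staples and soups are not oiled; stir-fried/braised dishes are
    oil_id <- character(0); oil_g <- numeric(0)
    if (use_oil) {
      oil_id <- pools$oil[1]
      oil_g <- runif(1, 1, 3)
    }
    # rescale mains and oil jointly so the dish lands in its category's
    # energy window (salt carries no energy and is set by the sodium
    # standardization anyway)
    if (length(ing_energy) > 0 && length(mains) > 0) {
      e_now <- sum(c(mains, setNames(oil_g, oil_id)) *
                     unname(ing_energy[c(names(mains), oil_id)]) / 100)
      if (e_now > 0) {
        f <- runif_range(1, DISH_ENERGY_KCAL[[dc]]) / e_now
        mains <- mains * f
        oil_g <- oil_g * f
      }
    }
    extra_id <- character(0); extra_g <- numeric(0)
    if (length(pools$salt)) {
      extra_id <- c(extra_id, pools$salt[1])
      extra_g <- c(extra_g, round(runif(1, 1.5, 3.5), 1))
    }
    if (length(oil_id)) {
      extra_id <- c(extra_id, oil_id)
      extra_g <- c(extra_g, round(oil_g, 2))
    }
    d_flavor[i] <- sample(flavors, 1)
    d_method[i] <- sample(methods, 1)
    d_price[i] <- sample.int(4, 1)
    l_ing[[i]] <- c(names(mains), extra_id)
    l_g[[i]] <- c(round(unname(mains), 1), extra_g)
  }
  n_per <- lengths(l_ing)
  tibble(
    dish_id = rep(sprintf("dish_%03d", seq_len(spec$n_dishes)), n_per),
    name = rep(sprintf("%s dish %03d", dish_cats, seq_len(spec$n_dishes)),
               n_per),
    dish_category = rep(dish_cats, n_per),
    flavor = rep(d_flavor, n_per),
    cooking_method = rep(d_method, n_per),
    price_level = rep(d_price, n_per),
    ingredient_id = unlist(l_ing, use.names = FALSE),
    grams = unlist(l_g, use.names = FALSE))
}

# draw main ingredients (named grams vector) for one dish category
dish_mains <- function(dish_category, pools) {
  pick <- function(pool, n, lo, hi) {
    n <- min(n, length(pool))
    if (n == 0) return(setNames(numeric(0), character(0)))
    setNames(runif(n, lo, hi), sample(pool, n))
  }
  fallback <- function(p, fb) if (length(p)) p else fb
  protein_pool <- c(pools$meat, pools$fish, pools$egg)
  # each dish concentrates one or two food groups, as canteen dishes do;
  # variety across groups comes from how dishes are combined into meals
  switch(dish_category,
    staple = pick(pools$cereal, sample(1:2, 1), 80, 200),
    vegan = {
      v <- runif(1)
      if (v < 0.45 || length(c(pools$legume, pools$fruit)) == 0) {
        pick(pools$veg, sample(2:3, 1), 60, 150)
      } else if (v < 0.75 && length(pools$legume) > 0) {
        c(pick(pools$veg, sample(1:2, 1), 60, 130),
          pick(pools$legume, 1, 40, 90))
      } else {
        c(pick(pools$veg, 1, 60, 120),
          pick(fallback(pools$fruit, pools$legume), 1, 50, 110))
      }
    },
    "animal-derived" = {
      v <- runif(1)
      prot <- if (v < 0.55) fallback(pools$meat, protein_pool)
      else if (v < 0.85) fallback(pools$fish, protein_pool)
      else fallback(pools$egg, protein_pool)
      c(pick(prot, sample(1:2, 1), 60, 150),
        pick(pools$veg, rbinom(1, 1, 0.3), 30, 70))
    },
    omnivorous = c(
      pick(if (runif(1) < 0.7) fallback(pools$meat, protein_pool)
           else fallback(pools$fish, protein_pool), 1, 50, 120),
      pick(pools$veg, sample(1:2, 1), 50, 120),
      pick(pools$legume, rbinom(1, 1, 0.2), 20, 50)),
    soup = {
      v <- runif(1)
      if (v < 0.40) {
        pick(pools$veg, sample(1:2, 1), 40, 100)
      } else if (v < 0.65) {
        c(pick(fallback(pools$egg, pools$veg), 1, 30, 60),
          pick(pools$veg, 1, 30, 70))
      } else if (v < 0.85) {
        c(pick(fallback(pools$fish, pools$veg), 1, 40, 80),
          pick(pools$veg, 1, 30, 60))
      } else {
        c(pick(fallback(pools$dairy, pools$veg), 1, 60, 120),
          pick(fallback(pools$fruit, pools$veg), 1, 40, 90))
      }
    },
    complete = c(pick(pools$cereal, 1, 100, 180),
                 pick(if (runif(1) < 0.6) fallback(pools$meat, protein_pool)
                      else fallback(pools$fish, protein_pool), 1, 50, 110),
                 pick(pools$veg, 1, 40, 100)))
}

# sample template-valid combos (uniform template / uniform dishes) and
# return their per-nutrient totals, for guideline and bound calibration;
# samples are restricted to lunch-appropriate energies (the meals the
# energy prescription admits) so bands describe suitable meals rather
# than meal size
calibrate_combo_totals <- function(recipes, composition, n_samples = NULL,
                                   energy_window = c(450, 700)) {
  if (nrow(recipes) == 0) return(NULL)
  dishes <- recipes %>% distinct(.data$dish_id, .data$dish_category)
  by_cat <- split(dishes$dish_id, dishes$dish_category)
  n_samples <- n_samples %||%
    min(300L, max(60L, 4L * nrow(dishes)))
  # dish x nutrient totals via the composition matrices
  ing <- sort(unique(composition$ingredient_id))
  nut <- sort(unique(composition$nutrient_id))
  IN <- matrix(0, length(ing), length(nut), dimnames = list(ing, nut))
  IN[cbind(match(composition$ingredient_id, ing),
           match(composition$nutrient_id, nut))] <- composition$amount_per_100g
  DI <- matrix(0, nrow(dishes), length(ing),
               dimnames = list(dishes$dish_id, ing))
  DI[cbind(match(recipes$dish_id, dishes$dish_id),
           match(recipes$ingredient_id, ing))] <- recipes$grams
  M <- DI %*% IN / 100
  tpl <- combo_templates()
  draws <- matrix(0, n_samples, ncol(M), dimnames = list(NULL, colnames(M)))
  ok <- logical(n_samples)
  for (s in seq_len(n_samples)) {
    t <- tpl[sample.int(nrow(tpl), 1), ]
    ids <- character(0)
    feasible <- TRUE
    for (slot in t$slots[[1]]) {
      avail <- setdiff(unlist(by_cat[slot], use.names = FALSE), ids)
      if (length(avail) == 0) { feasible <- FALSE; break }
      ids <- c(ids, avail[sample.int(length(avail), 1)])
    }
    if (!feasible) next
    draws[s, ] <- colSums(M[ids, , drop = FALSE])
    ok[s] <- TRUE
  }
  draws <- draws[ok, , drop = FALSE]
  if ("energy_kcal" %in% colnames(draws)) {
    e <- draws[, "energy_kcal"]
    in_window <- e >= energy_window[1] & e <= energy_window[2]
    if (sum(in_window) >= 30) draws <- draws[in_window, , drop = FALSE]
  }
  list(combos = draws, dishes = M)
}

# guideline daily ranges, mirroring how reference intakes are framed:
# micronutrients and protein carry a minimum only -- a reference intake set
# so that one standard portion of a source dish meets it (85% of the median
# contribution among the nutrient's top-quartile source dishes), which a
# meal without any source food group cannot reach from background levels --
# and sodium and cholesterol carry upper bounds from the suitable-combo
# distribution. Energy and fat carry no fixed band here: both are
# prescribed per person (kcal per kg body weight, share of energy from
# fat) and enforced as constraints by the energy budget.
MODERATION_NUTRIENTS <- c("sodium_mg", "cholesterol_mg")
UNBANDED_NUTRIENTS <- c("energy_kcal", "fat_g")

synth_guidelines <- function(nutrients, cal, lunch_fraction = 0.4) {
  if (is.null(cal) || nrow(cal$combos) == 0) {
    return(tibble(nutrient_id = character(), low = double(),
                  high = double(), unit = character()))
  }
  combo_q <- function(p) {
    v <- apply(cal$combos, 2, quantile, probs = p)[nutrients$nutrient_id]
    unname(v) %na% 0
  }
  # one standard source-dish portion: median contribution among the dishes
  # in the top quartile for the nutrient
  lo <- vapply(nutrients$nutrient_id, function(m) {
    if (!m %in% colnames(cal$dishes)) return(0)
    v <- cal$dishes[, m]
    src <- v[v >= quantile(v, 0.5)]
    0.85 * stats::median(src)
  }, numeric(1))
  hi <- rep(NA_real_, nrow(nutrients))
  mod <- nutrients$nutrient_id %in% MODERATION_NUTRIENTS
  hi[mod] <- combo_q(0.80)[mod]
  lo[mod] <- NA_real_
  unbanded <- nutrients$nutrient_id %in% UNBANDED_NUTRIENTS
  lo[unbanded] <- NA_real_
  hi[unbanded] <- NA_real_
  tibble(nutrient_id = nutrients$nutrient_id,
         low = round(unname(lo) / lunch_fraction, 4),
         high = round(hi / lunch_fraction, 4),
         unit = nutrients$unit)
}

# categories safe to discourage wholesale (never staples, oils or salt)
DISCOURAGEABLE_CATS <- c("organ_meats", "shellfish", "nuts", "beef_lamb",
                         "mushrooms", "dairy")

synth_disease_rules <- function(spec, composition, cats, cal,
                                lunch_fraction = 0.4) {
  empty <- tibble(disease_id = character(), relation = character(),
                  target_type = character(), target_id = character(),
                  bound_type = character(), amount = double(),
                  unit = character())
  if (spec$n_diseases == 0) return(empty)
  diseases <- SYN_DISEASES[seq_len(spec$n_diseases)]
  ing <- composition %>% distinct(.data$ingredient_id, .data$category_id)
  targetable <- ing$ingredient_id[
    !ing$category_id %in% c("seasonings", "cooking_oils")]
  cat_targets <- intersect(DISCOURAGEABLE_CATS, cats)
  units <- setNames(SYN_NUTRIENTS$unit, SYN_NUTRIENTS$nutrient_id)
  restrictable <- intersect(c("sodium_mg", "cholesterol_mg", "fat_g",
                              "energy_kcal"),
                            colnames(cal$combos) %||% character())
  rows <- lapply(diseases, function(d) {
    n_disc <- sample.int(2, 1)
    disc <- tibble(disease_id = d, relation = "discourage",
                   target_type = "ingredient",
                   target_id = sample(targetable, n_disc),
                   bound_type = NA_character_, amount = NA_real_,
                   unit = NA_character_)
    if (d == "gout" && length(cat_targets) > 0) {
      disc <- bind_rows(disc, tibble(
        disease_id = d, relation = "discourage", target_type = "category",
        target_id = intersect(c("organ_meats", "shellfish"), cat_targets),
        bound_type = NA_character_, amount = NA_real_,
        unit = NA_character_))
    } else if (runif(1) < 0.25 && length(cat_targets) > 0) {
      disc <- bind_rows(disc, tibble(
        disease_id = d, relation = "discourage", target_type = "category",
        target_id = resample(cat_targets), bound_type = NA_character_,
        amount = NA_real_, unit = NA_character_))
    }
    disc <- distinct(disc, .data$target_id, .keep_all = TRUE)
    if (d == "dyslipidemia" && "cholesterol_mg" %in% restrictable) {
      # the canonical clinical bound for blood-lipid management
      restr_target <- "cholesterol_mg"
      bound <- 200
    } else {
      restr_target <- resample(restrictable)
      q <- runif(1, 0.70, 0.95)
      bound <- round(as.numeric(
        quantile(cal$combos[, restr_target], q)) / lunch_fraction, 2)
    }
    restr <- tibble(disease_id = d, relation = "restrict",
                    target_type = "nutrient", target_id = restr_target,
                    bound_type = "max", amount = bound,
                    unit = unname(units[restr_target]))
    reco <- tibble(disease_id = d, relation = "recommend",
                   target_type = "ingredient",
                   target_id = resample(setdiff(targetable, disc$target_id)),
                   bound_type = NA_character_, amount = NA_real_,
                   unit = NA_character_)
    bind_rows(disc, restr, reco)
  })
  bind_rows(rows)
}

#' Generate a synthetic older-adult cohort
#'
#' Samples demographics (ages 60-90 centered near 71, 47\% female), BMI and
#' body weight, income band, activity level and the four dietary-preference
#' dimensions; diseases are drawn from a Gaussian copula with the spec's
#' marginal prevalences and a shared frailty correlation so multimorbidity
#' clusters realistically. When a graph is supplied, a `tracked_fraction`
#' share of members receives at least 5 days of disease-safe eating history
#' built from the generated dishes.
#'
#' @param spec A [world_spec()].
#' @param kg Optional `food_kg` used to build eating histories; without it
#'   all histories are empty.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return Cohort tibble (one row per user; `diseases` and `history`
#'   list-columns).
#' @export
generate_cohort <- function(spec = world_spec(), kg = NULL, seed = NULL) {
  seed <- seed %||% spec$seed
  with_seed(seed, generate_cohort_impl(spec, kg, seed))
}

generate_cohort_impl <- function(spec, kg, seed) {
  n <- spec$cohort_size
  if (n == 0) {
    return(tibble(user_id = character(), sex = character(),
                  age_years = integer(), weight_kg = double(),
                  bmi = double(), income_band = integer(),
                  activity_level = character(), flavor = character(),
                  staple = character(), oil = character(),
                  cooking_method = character(), diseases = list(),
                  history = list()))
  }
  sex <- ifelse(runif(n) < 0.47, "female", "male")
  age <- pmin(pmax(round(rnorm(n, 71, 7)), 60L), 90L)
  height_cm <- rnorm(n, ifelse(sex == "female", 153, 165), 5)
  bmi <- pmin(pmax(rnorm(n, 24.5, 3.2), 17), 32)
  weight <- round(bmi * (height_cm / 100)^2, 1)

  prev <- spec$disease_prevalences
  rho <- spec$frailty_rho
  z <- rnorm(n)
  dis <- lapply(seq_len(n), function(i) {
    x <- sqrt(rho) * z[i] + sqrt(1 - rho) * rnorm(length(prev))
    names(prev)[x < qnorm(prev)]
  })

  cohort <- tibble(
    user_id = sprintf("user_%04d", seq_len(n)),
    sex = sex, age_years = as.integer(age), weight_kg = weight,
    bmi = round(bmi, 1),
    income_band = sample(1:4, n, replace = TRUE, prob = c(0.2, 0.4, 0.3, 0.1)),
    activity_level = sample(c("light", "moderate", "vigorous"), n,
                            replace = TRUE, prob = c(0.55, 0.38, 0.07)),
    flavor = sample(c("salty", "light", "sweet", "spicy", "sour"), n,
                    replace = TRUE, prob = c(0.3, 0.35, 0.1, 0.15, 0.1)),
    staple = sample(c("rice", "noodles", "mixed"), n, replace = TRUE,
                    prob = c(0.55, 0.25, 0.2)),
    oil = sample(c("vegetable", "peanut", "olive", "lard"), n, replace = TRUE,
                 prob = c(0.45, 0.3, 0.1, 0.15)),
    cooking_method = sample(c("stir-fried", "steamed", "boiled", "stewed"),
                            n, replace = TRUE),
    diseases = dis,
    history = rep(list(tibble(day = integer(), dish_id = character())), n))

  if (!is.null(kg)) {
    n_tracked <- round(spec$tracked_fraction * n)
    tracked_idx <- sort(sample.int(n, n_tracked))
    n_rec_tracked <- sample(5:15, n_tracked, replace = TRUE)
    untracked_idx <- setdiff(seq_len(n), tracked_idx)
    has_partial <- runif(length(untracked_idx)) < 0.4
    n_rec_part <- ifelse(has_partial,
                         sample(1:4, length(untracked_idx), replace = TRUE), 0L)
    for (k in seq_along(tracked_idx)) {
      i <- tracked_idx[k]
      cohort$history[[i]] <- generate_history(
        cohort[i, ], kg, n_rec_tracked[k], seed = child_seed(seed, i))
    }
    for (k in seq_along(untracked_idx)) {
      if (n_rec_part[k] == 0) next
      i <- untracked_idx[k]
      cohort$history[[i]] <- generate_history(
        cohort[i, ], kg, n_rec_part[k], seed = child_seed(seed, i))
    }
  }
  cohort
}

#' Generate a disease-safe habitual eating history for one user
#'
#' Draws `n_records` day-indexed combo selections over template-valid
#' combos of dishes not discouraged for the user's diseases (standing in
#' for a canteen sensing log). Selection is habitual: the user repeatedly
#' draws from a small seeded personal repertoire of dishes, preferring
#' price tiers at or below their income band, which reproduces the
#' repetitive structure of observed autonomous eating.
#'
#' @param user One-row cohort tibble.
#' @param kg A `food_kg`.
#' @param n_records Number of recorded days.
#' @param seed Integer seed.
#' @return Tibble with columns `day`, `dish_id` (several rows per day -- one
#'   per dish of that day's combo).
#' @export
generate_history <- function(user, kg, n_records, seed = 1) {
  if (n_records == 0) return(tibble(day = integer(), dish_id = character()))
  st <- world_state(kg)
  safe <- which(kg$dishes$dish_id %in% filter_by_disease(user, kg))
  tw <- habit_tier_weights(st, user$income_band %||% 2L)
  with_seed(seed, {
    repertoire <- habit_repertoire(st, safe)
    prep <- prep_random_combo(st, safe, repertoire)
    days <- vector("list", n_records)
    for (d in seq_len(n_records)) {
      ids <- draw_random_combo(prep, tw)
      if (is.null(ids)) {
        abort(paste0("no feasible combo for user ", user$user_id),
              class = "eldermeal_generation_error")
      }
      days[[d]] <- ids
    }
    tibble(day = rep(seq_len(n_records), lengths(days)),
           dish_id = st$dish_ids[unlist(days, use.names = FALSE)])
  })
}

PRICE_TIER_RANK <- c(low = 1, intermediate = 2, "intermediate-high" = 3,
                     high = 4)

# per-safe-set slot candidate lists and feasible templates, so repeated
# draws (histories, the autonomous baseline) stay cheap. When a habitual
# `repertoire` of dish indices is given, slots draw from it and fall back
# to the full safe set only for categories the repertoire lacks.
prep_random_combo <- function(st, safe, repertoire = NULL) {
  cats <- st$kg$dishes$dish_category
  per_tpl <- lapply(st$templates, function(t) {
    lists <- lapply(t$slots, function(slot) {
      full <- safe[cats[safe] %in% slot]
      if (is.null(repertoire)) return(full)
      habit <- repertoire[cats[repertoire] %in% slot]
      if (length(habit) >= if (t$pair_first) 2L else 1L) habit else full
    })
    ok <- all(lengths(lists) >= 1) &&
      (!t$pair_first || length(lists[[1]]) >= 2)
    list(lists = lists, pair_first = t$pair_first, ok = ok,
         tier_rank = unname(PRICE_TIER_RANK[t$price_tier]))
  })
  list(per_tpl = per_tpl,
       feasible = which(vapply(per_tpl, `[[`, logical(1), "ok")))
}

# one template-valid combo; templates drawn uniformly over the feasible
# set, or with `tier_weights` (a weight per template) when modeling
# price-tier preference
draw_random_combo <- function(prep, tier_weights = NULL) {
  if (length(prep$feasible) == 0) return(NULL)
  ti <- if (is.null(tier_weights)) {
    resample(prep$feasible)
  } else {
    w <- tier_weights[prep$feasible]
    prep$feasible[sample.int(length(prep$feasible), 1, prob = w)]
  }
  t <- prep$per_tpl[[ti]]
  if (t$pair_first) {
    ids <- resample(t$lists[[1]], 2)
    rest <- t$lists[-(1:2)]
  } else {
    ids <- integer(0)
    rest <- t$lists
  }
  for (l in rest) {
    avail <- setdiff(l, ids)
    if (length(avail) == 0) return(NULL)
    ids <- c(ids, resample(avail))
  }
  ids
}

# uniform template-valid combo over a safe dish set (NULL if none feasible)
random_template_combo <- function(st, safe) {
  draw_random_combo(prep_random_combo(st, safe))
}

# habitual behavior model: a repetitive eater keeps a small taste-centred
# repertoire -- per dish category, the few dishes most similar (by
# ingredient cosine) to a personal seed dish -- and prefers price tiers at
# or below their income band
habit_repertoire <- function(st, safe, per_cat = 1:3) {
  if (length(safe) == 0) return(integer(0))
  seed_dish <- resample(safe)
  v <- st$DI[seed_dish, ]
  vn <- sqrt(sum(v^2))
  sims <- if (vn > 0) {
    as.numeric(st$DI[safe, , drop = FALSE] %*% v) /
      pmax(st$di_norm[safe] * vn, 1e-12)
  } else rep(0, length(safe))
  cats <- st$kg$dishes$dish_category[safe]
  out <- integer(0)
  for (cc in unique(cats)) {
    in_cat <- which(cats == cc)
    k <- min(length(in_cat), resample(per_cat))
    out <- c(out, safe[in_cat[order(-sims[in_cat], in_cat)]][seq_len(k)])
  }
  sort(unique(out))
}

habit_tier_weights <- function(st, income_band) {
  vapply(st$templates, function(t) {
    r <- unname(PRICE_TIER_RANK[t$price_tier])
    exp(-1.5 * max(r - income_band, 0))
  }, numeric(1))
}
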