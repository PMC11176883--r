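# fixtures built in code: hand-sized tables for exact arithmetic, seeded
# synthetic worlds for property tests, and independent oracles

# -- hand-built toy tables ----------------------------------------------------

toy_composition <- function() {
  tibble::tribble(
    ~ingredient_id, ~name,      ~category_id,       ~nutrient_id,  ~amount_per_100g, ~unit,
    "ing_a",        "rice",     "rice_products",    "iron_mg",     2.0,              "mg",
    "ing_a",        "rice",     "rice_products",    "vit_c_mg",    0.0,              "mg",
    "ing_b",        "cabbage",  "leafy_vegetables", "iron_mg",     1.0,              "mg",
    "ing_b",        "cabbage",  "leafy_vegetables", "vit_c_mg",    10.0,             "mg")
}

toy_recipes <- function() {
  tibble::tibble(
    dish_id = "dish_1", name = "rice with cabbage",
    dish_category = "complete", flavor = "light",
    cooking_method = "steamed", price_level = 1L,
    ingredient_id = c("ing_a", "ing_b"), grams = c(150, 50))
}

toy_rules <- function() {
  tibble::tibble(disease_id = "gout", relation = "discourage",
                 target_type = "ingredient", target_id = "ing_b",
                 bound_type = NA_character_, amount = NA_real_,
                 unit = NA_character_)
}

# recipes table with an arbitrary ingredient-set per dish (all "vegan" so
# category checks stay out of the way)
recipes_from_sets <- function(sets, names = NULL, grams = 100) {
  names <- names %||% paste0("dish ", seq_along(sets))
  ids <- sprintf("d%02d", seq_along(sets))
  dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    tibble::tibble(dish_id = ids[i], name = names[i],
                   dish_category = "vegan", flavor = "light",
                   cooking_method = "boiled", price_level = 1L,
                   ingredient_id = sets[[i]], grams = grams)
  }))
}

# -- seeded synthetic worlds --------------------------------------------------

small_spec <- function(seed, n_dishes = 16, n_ingredients = 26,
                       n_categories = 8, n_nutrients = 8, n_diseases = 4,
                       cohort_size = 3) {
  world_spec(n_dishes = n_dishes, n_ingredients = n_ingredients,
             n_categories = n_categories, n_nutrients = n_nutrients,
             n_diseases = n_diseases, cohort_size = cohort_size,
             tracked_fraction = 1 / 3, seed = seed)
}

small_world <- function(seed, ...) {
  spec <- small_spec(seed, ...)
  db <- generate_food_database(spec)
  kg <- build_graph(db$recipes, db$composition, db$disease_rules,
                    db$guidelines)
  cohort <- generate_cohort(spec, kg)
  list(spec = spec, db = db, kg = kg, cohort = cohort)
}

# the default-scale world is expensive; build it once per test session
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- world_spec(seed = 20260923 %% 1e6)
      db <- generate_food_database(spec)
      kg <- build_graph(db$recipes, db$composition, db$disease_rules,
                        db$guidelines)
      cohort <- generate_cohort(spec, kg)
      cache <<- list(spec = spec, db = db, kg = kg, cohort = cohort)
    }
    cache
  }
})

# -- independent oracles ------------------------------------------------------

# nutrient totals of one dish by direct summation over the raw tables
oracle_dish_nutrients <- function(dish_id, recipes, composition) {
  rec <- recipes[recipes$dish_id == dish_id, ]
  nut <- sort(unique(composition$nutrient_id))
  out <- setNames(rep(0, length(nut)), nut)
  for (k in seq_len(nrow(rec))) {
    rows <- composition[composition$ingredient_id == rec$ingredient_id[k], ]
    for (j in seq_len(nrow(rows))) {
      out[rows$nutrient_id[j]] <- out[rows$nutrient_id[j]] +
        rows$amount_per_100g[j] * rec$grams[k] / 100
    }
  }
  out
}

# dishes discouraged for a disease by scanning every (rule, dish) pair
oracle_disease_dishes <- function(kg, disease_id) {
  rules <- kg$rules[kg$rules$disease_id == disease_id &
                      kg$rules$relation == "discourage", ]
  bad_ing <- rules$target_id[rules$target_type == "ingredient"]
  for (cat in rules$target_id[rules$target_type == "category"]) {
    bad_ing <- union(bad_ing, kg$ingredients$ingredient_id[
      kg$ingredients$category_id == cat])
  }
  hits <- character(0)
  for (d in kg$dishes$dish_id) {
    ings <- kg$recipes$ingredient_id[kg$recipes$dish_id == d]
    if (length(intersect(ings, bad_ing)) > 0) hits <- c(hits, d)
  }
  sort(hits)
}

# does a dish-id set instantiate exactly one template? (brute matcher)
oracle_template_match <- function(dish_ids, kg,
                                  templates = combo_templates()) {
  cats <- kg$dishes$dish_category[match(dish_ids, kg$dishes$dish_id)]
  fits <- vapply(seq_len(nrow(templates)), function(i) {
    slots <- templates$slots[[i]]
    if (length(slots) != length(dish_ids)) return(FALSE)
    # try every assignment of dishes to slots
    ok <- FALSE
    for (p in asplit(permutations_of(length(slots)), 1)) {
      if (all(mapply(function(ci, sl) ci %in% sl, cats[p], slots))) {
        ok <- TRUE
        break
      }
    }
    ok
  }, logical(1))
  sum(fits)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# exhaustive recommend: enumerate every template-valid combo, filter by
# discouragement and constraints, sort by adequacy / preference / sorted
# dish-id tuple, truncate -- all with plain loops, independent of the
# pipeline implementation
oracle_recommend <- function(user, kg, pool, n_options = 5,
                             budget = energy_budget(), min_history = 5,
                             k_frequent = 10) {
  safe <- filter_by_disease(user, kg)
  ranked <- if (nrow(user$history[[1]]) >= min_history &&
                length(unique(user$history[[1]]$day)) >= min_history) {
    cosine_rank(user, safe, kg, k_frequent)
  } else {
    cold_boot_rank(user, pool, safe, kg, min_history, k_frequent)
  }
  scores <- setNames(ranked$score, ranked$dish_id)
  cats <- setNames(kg$dishes$dish_category, kg$dishes$dish_id)
  templates <- combo_templates()

  combos <- list()
  for (ti in seq_len(nrow(templates))) {
    slots <- templates$slots[[ti]]
    pools <- lapply(slots, function(sl) safe[cats[safe] %in% sl])
    if (any(lengths(pools) == 0)) next
    grid <- expand.grid(pools, stringsAsFactors = FALSE)
    keep <- apply(grid, 1, function(x) length(unique(x)) == length(x))
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) == 0) next
    seen <- character(0)
    for (r in seq_len(nrow(grid))) {
      ids <- as.character(unlist(grid[r, ]))
      key <- paste(sort(ids), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      combos[[length(combos) + 1]] <- list(ids = ids, tpl = ti)
    }
  }
  if (length(combos) == 0) return(NULL)

  comp_like <- build_composition_like(kg)
  dish_tot <- lapply(setNames(nm = kg$dishes$dish_id), function(d) {
    oracle_dish_nutrients(d, kg$recipes, comp_like)
  })
  rows <- lapply(combos, function(cb) {
    tot <- setNames(rep(0, nrow(kg$nutrients)), kg$nutrients$nutrient_id)
    for (d in cb$ids) {
      dn <- dish_tot[[d]]
      tot[names(dn)] <- tot[names(dn)] + dn
    }
    list(ids = cb$ids, tpl = cb$tpl, tot = tot,
         pref = mean(scores[cb$ids]))
  })

  frac <- eldermeal:::resolve_budget(budget, user$diseases[[1]])
  lf <- frac$lf
  keep <- vapply(rows, function(cb) {
    oracle_constraints_ok(cb$tot, user, kg, budget, frac)
  }, logical(1))
  rows <- rows[keep]
  if (length(rows) == 0) return(NULL)

  adequacy <- vapply(rows, function(cb) {
    n_ok <- 0
    for (i in seq_len(nrow(kg$nutrients))) {
      lo <- kg$nutrients$guideline_low[i]
      hi <- kg$nutrients$guideline_high[i]
      if (is.na(lo) && is.na(hi)) next
      v <- cb$tot[kg$nutrients$nutrient_id[i]]
      ok <- (is.na(lo) || v >= lo * lf) && (is.na(hi) || v <= hi * lf)
      if (ok) n_ok <- n_ok + 1
    }
    n_ok
  }, numeric(1))
  pref <- vapply(rows, function(cb) cb$pref, numeric(1))
  keys <- vapply(rows, function(cb) {
    paste(formatC(match(sort(cb$ids), kg$dishes$dish_id), width = 6,
                  flag = "0"), collapse = ",")
  }, "")
  ord <- order(-adequacy, -pref, keys)
  ord <- ord[seq_len(min(n_options, length(ord)))]
  list(dish_sets = lapply(rows[ord], function(cb) sort(cb$ids)),
       adequacy = adequacy[ord])
}

# reconstruct a composition-like table from the graph for the oracle
build_composition_like <- function(kg) {
  e <- kg$edges[kg$edges$relation == "contain" &
                  kg$edges$head %in% kg$ingredients$ingredient_id, ]
  tibble::tibble(
    ingredient_id = e$head,
    name = kg$ingredients$name[match(e$head, kg$ingredients$ingredient_id)],
    category_id = kg$ingredients$category_id[
      match(e$head, kg$ingredients$ingredient_id)],
    nutrient_id = e$tail, amount_per_100g = e$amount,
    unit = kg$nutrients$unit[match(e$tail, kg$nutrients$nutrient_id)])
}

oracle_constraints_ok <- function(tot, user, kg, budget, frac) {
  rr <- kg$rules[kg$rules$disease_id %in% user$diseases[[1]] &
                   kg$rules$relation == "restrict", ]
  for (i in seq_len(nrow(rr))) {
    if (rr$target_type[i] != "nutrient") next
    v <- tot[rr$target_id[i]]
    bound <- rr$amount[i] * budget$lunch_fraction
    if (rr$bound_type[i] == "max" && v > bound) return(FALSE)
    if (rr$bound_type[i] == "min" && v < bound) return(FALSE)
  }
  if (!is.null(budget) && "energy_kcal" %in% names(tot)) {
    e <- tot[["energy_kcal"]]
    lo <- budget$kcal_per_kg_low * user$weight_kg * frac$lf_lo
    hi <- budget$kcal_per_kg_high * user$weight_kg * frac$lf_hi
    if (e < lo || e > hi) return(FALSE)
    if ("fat_g" %in% names(tot) && e > 0 &&
        tot[["fat_g"]] * budget$fat_kcal_per_g / e >
          budget$fat_fraction_max) {
      return(FALSE)
    }
  }
  TRUE
}
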