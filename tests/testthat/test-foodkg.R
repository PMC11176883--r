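test_that("build_graph materializes and infers the expected edges on toy tables", {
  kg <- build_graph(toy_recipes(), toy_composition(),
                    disease_rules = toy_rules(), sodium_bounds = NULL)
  e <- kg$edges
  expect_equal(sum(e$relation == "consist_of"), 2)
  expect_equal(sum(e$relation == "belong_to"), 2)
  # ingredient-level contain edges: zero amounts carry no edge
  ing_contain <- e[e$relation == "contain" & e$head %in% c("ing_a", "ing_b"), ]
  expect_lte(nrow(ing_contain), 4)
  # inferred dish-level contain edges exist
  dish_contain <- e[e$relation == "contain" & e$head == "dish_1", ]
  expect_gt(nrow(dish_contain), 0)
  # inferred disease -> dish discourage edge
  expect_true(any(e$relation == "discourage" & e$head == "gout" &
                    e$tail == "dish_1"))
  # entity invariants
  expect_equal(kg$dishes$portion_mass_g, 200)
  expect_true(all(e$relation %in% c("consist_of", "contain", "belong_to",
                                    "discourage", "restrict", "recommend")))
})

test_that("an empty disease table yields no disease relations", {
  kg <- build_graph(toy_recipes(), toy_composition(), sodium_bounds = NULL)
  expect_equal(sum(kg$edges$relation %in%
                     c("discourage", "restrict", "recommend")), 0)
})

test_that("build_graph reports unresolved references and negative amounts", {
  bad <- toy_recipes()
  bad$ingredient_id[2] <- "ing_zzz"
  expect_error(build_graph(bad, toy_composition(), sodium_bounds = NULL),
               "ing_zzz", class = "eldermeal_load_error")
  neg <- toy_recipes()
  neg$grams[1] <- -5
  expect_error(build_graph(neg, toy_composition(), sodium_bounds = NULL),
               class = "eldermeal_validation_error")
})

test_that("the default synthetic build reproduces the full entity census", {
  w <- default_world()
  expect_equal(nrow(w$kg$dishes), 180)
  expect_equal(nrow(w$kg$ingredients), 112)
  expect_equal(nrow(w$kg$categories), 20)
  expect_equal(nrow(w$kg$nutrients), 27)
  expect_equal(nrow(w$kg$diseases), 30)
})

test_that("graph integrity holds after building synthetic worlds", {
  for (s in 1:3) {
    w <- small_world(s)
    e <- w$kg$edges
    nodes <- c(w$kg$dishes$dish_id, w$kg$ingredients$ingredient_id,
               w$kg$categories$category_id, w$kg$nutrients$nutrient_id,
               w$kg$diseases$disease_id)
    expect_true(all(e$head %in% nodes))
    expect_true(all(e$tail %in% nodes))
    expect_true(all(e$relation %in% c("consist_of", "contain", "belong_to",
                                      "discourage", "restrict", "recommend")))
  }
})

test_that("dedup merges name-equal and high-overlap dishes, keeps distinct ones", {
  # two byte-identical dishes collapse to one
  sets <- list(letters[1:3], letters[1:3])
  rec <- recipes_from_sets(sets, names = c("soup", "soup"))
  expect_equal(length(unique(dedup_dishes(rec)$dish_id)), 1)

  # Jaccard 9/10 = 0.90 merges; 6/8 = 0.75 keeps both
  sets <- list(paste0("i", 1:9), paste0("i", 1:10),
               paste0("j", 1:7), c(paste0("j", 1:6), "jx"))
  rec <- recipes_from_sets(sets)
  kept <- unique(dedup_dishes(rec, threshold = 0.85)$dish_id)
  expect_length(kept, 3)
  expect_true(all(c("d03", "d04") %in% kept))

  # similarity exactly 0.85 merges (inclusive threshold):
  # |A|=18, |B|=19, overlap 17 -> 17/20 = 0.85
  a <- paste0("k", 1:18)
  b <- c(paste0("k", 1:17), "m1", "m2")
  rec <- recipes_from_sets(list(a, b))
  expect_equal(length(unique(dedup_dishes(rec, 0.85)$dish_id)), 1)
})

test_that("dedup keeps the most frequent variant and is idempotent", {
  # variant B occurs twice (identical sets), variant A once; cluster keeps B
  sets <- list(paste0("i", 1:10), paste0("i", 1:9), paste0("i", 1:9))
  rec <- recipes_from_sets(sets)
  kept <- unique(dedup_dishes(rec)$dish_id)
  expect_equal(kept, "d02")  # frequency 2 beats d01; tie rule gives d02

  for (s in 1:3) {
    rec <- small_world(s)$db$recipes
    once <- dedup_dishes(rec)
    expect_identical(dedup_dishes(once), once)
    expect_lte(dplyr::n_distinct(once$dish_id),
               dplyr::n_distinct(rec$dish_id))
  }
})

test_that("dish nutrient inference matches hand arithmetic and is linear", {
  kg <- build_graph(toy_recipes(), toy_composition(), sodium_bounds = NULL)
  got <- infer_dish_nutrients(kg, "dish_1")
  vals <- setNames(got$amount, got$nutrient_id)
  # 150 g x 2.0/100 + 50 g x 1.0/100 = 3.5 mg iron
  expect_equal(vals[["iron_mg"]], 3.5)
  # 50 g x 10/100 = 5 mg vitamin C
  expect_equal(vals[["vit_c_mg"]], 5)

  # identity scaling: 100 g of an ingredient with 10 per 100 g
  rec1 <- toy_recipes()[1, ]
  rec1$grams <- 100
  kg1 <- build_graph(rec1, toy_composition(), sodium_bounds = NULL)
  v1 <- infer_dish_nutrients(kg1, "dish_1")
  expect_equal(v1$amount[v1$nutrient_id == "iron_mg"], 2)

  # linearity: scaling all grams by alpha scales every amount by alpha
  for (alpha in c(0.5, 2)) {
    rec <- toy_recipes()
    rec$grams <- rec$grams * alpha
    kga <- build_graph(rec, toy_composition(), sodium_bounds = NULL)
    va <- infer_dish_nutrients(kga, "dish_1")
    expect_identical(va$amount, got$amount * alpha)
  }
})

test_that("disease-dish inference equals exhaustive enumeration", {
  kg <- build_graph(toy_recipes(), toy_composition(),
                    disease_rules = toy_rules(), sodium_bounds = NULL)
  expect_equal(infer_disease_dish(kg, "gout"), "dish_1")

  for (s in 1:4) {
    w <- small_world(s, n_dishes = 10)
    for (d in w$kg$diseases$disease_id) {
      expect_equal(infer_disease_dish(w$kg, d),
                   oracle_disease_dishes(w$kg, d), info = paste(s, d))
    }
  }
})

test_that("category discouragement is inherited by member ingredients", {
  rules <- tibble::tibble(disease_id = "gout", relation = "discourage",
                          target_type = "category",
                          target_id = "leafy_vegetables",
                          bound_type = NA_character_, amount = NA_real_,
                          unit = NA_character_)
  kg <- build_graph(toy_recipes(), toy_composition(), disease_rules = rules,
                    sodium_bounds = NULL)
  expect_equal(infer_disease_dish(kg, "gout"), "dish_1")
})

test_that("sodium standardization reaches the band exactly", {
  comp <- tibble::tribble(
    ~ingredient_id, ~name,   ~category_id, ~nutrient_id, ~amount_per_100g, ~unit,
    "veg",          "veg",   "leafy_vegetables", "sodium_mg", 20,        "mg",
    "salt",         "salt",  "seasonings",       "sodium_mg", 39000,     "mg")
  rec <- tibble::tibble(
    dish_id = "d1", name = "salty dish", dish_category = "vegan",
    flavor = "salty", cooking_method = "boiled", price_level = 1L,
    ingredient_id = c("veg", "salt"), grams = c(380, 20))
  out <- standardize_sodium(rec, comp)
  frac <- sum(out$grams * c(20, 39000)[match(out$ingredient_id,
                                             c("veg", "salt"))] / 1e5) /
    sum(out$grams)
  expect_equal(frac, 0.010, tolerance = 1e-12)
  # independent root-finding oracle for the seasoning factor
  g <- function(f) {
    (380 * 20 / 1e5 + f * 20 * 0.39) / (380 + f * 20) - 0.010
  }
  f_star <- uniroot(g, c(0, 1), tol = 1e-12)$root
  expect_equal(out$grams[out$ingredient_id == "salt"], 20 * f_star,
               tolerance = 1e-6)
  expect_identical(out$grams[out$ingredient_id == "veg"], 380)

  # already inside the band: unchanged
  rec_in <- rec
  rec_in$grams <- c(380, 9.2)  # fraction ~ 0.0093
  expect_identical(standardize_sodium(rec_in, comp), rec_in)

  # zero portion mass errors
  rec0 <- rec
  rec0$grams <- c(0, 0)
  expect_error(standardize_sodium(rec0, comp),
               class = "eldermeal_validation_error")
})

test_that("standardized dishes always land inside the sodium band", {
  for (s in 1:5) {
    w <- small_world(s)
    comp <- w$db$composition
    dens <- comp$amount_per_100g[comp$nutrient_id == "sodium_mg"]
    names(dens) <- comp$ingredient_id[comp$nutrient_id == "sodium_mg"]
    fr <- w$db$recipes %>%
      dplyr::mutate(na = .data$grams * dens[.data$ingredient_id] / 1e5) %>%
      dplyr::group_by(.data$dish_id) %>%
      dplyr::summarise(frac = sum(.data$na) / sum(.data$grams))
    expect_true(all(fr$frac >= 0.008 - 1e-9 & fr$frac <= 0.010 + 1e-9))
  }
})

test_that("rule statements parse into typed triples", {
  st <- tibble::tibble(
    disease_id = c("gout", "dyslipidemia", "anemia"),
    target_type = c("ingredient", "nutrient", "ingredient"),
    target_id = c("ing_b", "cholesterol_mg", "ing_a"),
    text = c("patients with gout should avoid organ meats",
             "limit dietary cholesterol to less than 200 mg/day",
             "iron-rich foods are recommended"))
  rules <- parse_disease_rules(st)
  expect_equal(rules$relation, c("discourage", "restrict", "recommend"))
  expect_equal(rules$amount[2], 200)
  expect_equal(rules$unit[2], "mg")
  expect_equal(rules$bound_type[2], "max")
  expect_equal(nrow(attr(rules, "unmatched")), 0)

  # empty table
  empty <- parse_disease_rules(st[0, ])
  expect_equal(nrow(empty), 0)

  # unmatched statements are reported, never dropped silently
  st2 <- st[1, ]
  st2$text <- "eat a balanced diet"
  expect_warning(out <- parse_disease_rules(st2), "unmatched")
  expect_equal(nrow(attr(out, "unmatched")), 1)

  # discourage + recommend in one statement is ambiguous
  st3 <- st[1, ]
  st3$text <- "avoid shellfish but recommend fish"
  expect_error(parse_disease_rules(st3), class = "eldermeal_ambiguity_error")
})

test_that("graph round-trips through JSON serialization", {
  w <- small_world(11)
  path <- withr::local_tempfile(fileext = ".json")
  write_foodkg(w$kg, path, seed = 11)
  kg2 <- read_foodkg(path)
  expect_equal(kg2$dishes, w$kg$dishes)
  expect_equal(kg2$ingredients, w$kg$ingredients)
  expect_equal(sort(names(kg2$discouraged)), sort(names(w$kg$discouraged)))
  expect_equal(kg2$matrices$dish_nutrient, w$kg$matrices$dish_nutrient,
               tolerance = 1e-12)
  expect_setequal(
    paste(kg2$edges$head, kg2$edges$relation, kg2$edges$tail),
    paste(w$kg$edges$head, w$kg$edges$relation, w$kg$edges$tail))
})
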