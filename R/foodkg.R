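#' Food knowledge graph construction and reasoning
#'
#' The food knowledge graph (KG) stores five entity classes -- dishes,
#' ingredients, ingredient categories, nutrients and diseases -- connected by
#' six typed relations: `consist_of` (dish -> ingredient, grams per portion),
#' `belong_to` (ingredient -> category), `contain` (ingredient -> nutrient per
#' 100 g, and inferred dish -> nutrient per portion), and the three
#' disease-to-food relations `discourage` (hard exclusion), `restrict`
#' (quantitative daily bound) and `recommend` (soft positive signal).
#'
#' @name foodkg
NULL

DISH_CATEGORIES <- c("animal-derived", "vegan", "omnivorous", "staple",
                     "soup", "complete")

RELATION_TYPES <- c("consist_of", "contain", "belong_to",
                    "discourage", "restrict", "recommend")

#' Build the food knowledge graph from tabular inputs
#'
#' Assembles a `food_kg` object from a long-format recipe table, an
#' ingredient/nutrient composition table, an optional disease-rule table and
#' optional nutrient guideline ranges. Construction follows four stages:
#' schema validation, data preparation (duplicate-dish removal and per-dish
#' sodium standardization), edge materialization, and first-order inference
#' (dish-level nutrient totals and disease-level dish exclusions).
#'
#' @param recipes Tibble with columns `dish_id`, `name`, `dish_category`,
#'   `flavor`, `cooking_method`, `price_level`, `ingredient_id`, `grams`
#'   (one row per dish-ingredient pair).
#' @param composition Tibble with columns `ingredient_id`, `name`,
#'   `category_id`, `nutrient_id`, `amount_per_100g`, `unit` (one row per
#'   ingredient-nutrient pair; nutrient-native units per 100 g).
#' @param disease_rules Optional tibble with columns `disease_id`, `relation`
#'   (`discourage`/`restrict`/`recommend`), `target_type`
#'   (`ingredient`/`category`/`nutrient`), `target_id`, and for restrict rows
#'   `bound_type` (`max`/`min`), `amount` (per day) and `unit`.
#' @param guidelines Optional tibble with columns `nutrient_id`, `low`,
#'   `high`, `unit` (daily intake ranges; either bound may be `NA`).
#' @param dds_groups Optional named character vector mapping ingredient
#'   category ids to the nine diversity groups (see [default_dds_groups()]);
#'   unmapped categories get `"none"`.
#' @param dedup_threshold Jaccard threshold (inclusive) above which two
#'   dishes' ingredient sets are treated as duplicates; `NULL` disables
#'   deduplication. Default 0.85.
#' @param sodium_bounds Length-2 numeric, the admissible sodium mass-fraction
#'   band per dish; `NULL` disables sodium standardization. Default
#'   `c(0.008, 0.010)`.
#' @param sodium_nutrient,seasoning_categories Passed to
#'   [standardize_sodium()].
#'
#' @return A `food_kg` object: a list of entity tibbles (`dishes`,
#'   `ingredients`, `categories`, `nutrients`, `diseases`), the `rules`
#'   table, the full typed edge list (`edges`), and dense matrix caches used
#'   by the recommender.
#' @export
#' @examples
#' db <- generate_food_database(world_spec(n_dishes = 12, n_ingredients = 20,
#'                                         n_nutrients = 8, n_diseases = 3),
#'                              seed = 1)
#' kg <- build_graph(db$recipes, db$composition, db$disease_rules, db$guidelines)
#' kg
build_graph <- function(recipes, composition, disease_rules = NULL,
                        guidelines = NULL, dds_groups = NULL,
                        dedup_threshold = 0.85,
                        sodium_bounds = c(0.008, 0.010),
                        sodium_nutrient = "sodium_mg",
                        seasoning_categories = "seasonings") {
  recipes <- as_tibble(recipes)
  composition <- as_tibble(composition)
  validate_recipes(recipes, composition)

  if (!is.null(dedup_threshold) && nrow(recipes) > 0) {
    recipes <- dedup_dishes(recipes, threshold = dedup_threshold)
  }
  if (!is.null(sodium_bounds) &&
      sodium_nutrient %in% composition$nutrient_id && nrow(recipes) > 0) {
    recipes <- standardize_sodium(recipes, composition,
                                  low = sodium_bounds[1],
                                  high = sodium_bounds[2],
                                  sodium_nutrient = sodium_nutrient,
                                  seasoning_categories = seasoning_categories)
  }

  ingredients <- composition %>%
    distinct(.data$ingredient_id, .data$name, .data$category_id) %>%
    arrange(.data$ingredient_id)
  if (anyDuplicated(ingredients$ingredient_id)) {
    abort("composition assigns multiple names/categories to one ingredient_id",
          class = "eldermeal_load_error")
  }

  categories <- tibble(category_id = sort(unique(ingredients$category_id)))
  categories$name <- categories$category_id
  grp <- if (is.null(dds_groups)) character() else dds_groups
  categories$dds_group <- unname(grp[categories$category_id]) %na% "none"

  nutrients <- composition %>%
    distinct(.data$nutrient_id, .data$unit) %>%
    arrange(.data$nutrient_id) %>%
    rename(name = "nutrient_id") %>%
    mutate(nutrient_id = .data$name, .before = 1)
  if (anyDuplicated(nutrients$nutrient_id)) {
    abort("composition declares conflicting units for one nutrient_id",
          class = "eldermeal_load_error")
  }
  nutrients$guideline_low <- NA_real_
  nutrients$guideline_high <- NA_real_
  if (!is.null(guidelines) && nrow(guidelines) > 0) {
    gl <- as_tibble(guidelines)
    i <- match(nutrients$nutrient_id, gl$nutrient_id)
    nutrients$guideline_low <- gl$low[i]
    nutrients$guideline_high <- gl$high[i]
    bad <- !is.na(nutrients$guideline_low) & !is.na(nutrients$guideline_high) &
      nutrients$guideline_low > nutrients$guideline_high
    if (any(bad)) {
      abort(paste0("guideline low > high for nutrient(s): ",
                   paste(nutrients$nutrient_id[bad], collapse = ", ")),
            class = "eldermeal_load_error")
    }
  }

  dishes <- recipes %>%
    group_by(.data$dish_id, .data$name, .data$dish_category, .data$flavor,
             .data$cooking_method, .data$price_level) %>%
    summarise(portion_mass_g = sum(.data$grams), .groups = "drop") %>%
    arrange(.data$dish_id)
  if (anyDuplicated(dishes$dish_id)) {
    abort("recipes give conflicting attributes for one dish_id",
          class = "eldermeal_load_error")
  }

  rules <- normalize_rules(disease_rules)
  unknown <- setdiff(
    rules$target_id[rules$target_type == "ingredient"], ingredients$ingredient_id)
  unknown <- c(unknown, setdiff(
    rules$target_id[rules$target_type == "category"], categories$category_id))
  unknown <- c(unknown, setdiff(
    rules$target_id[rules$target_type == "nutrient"], nutrients$nutrient_id))
  if (length(unknown) > 0) {
    abort(paste0("disease rule targets not present in the graph: ",
                 paste(unique(unknown), collapse = ", ")),
          class = "eldermeal_load_error")
  }
  diseases <- tibble(disease_id = sort(unique(rules$disease_id)))
  diseases$name <- diseases$disease_id

  kg <- structure(
    list(dishes = dishes, ingredients = ingredients, categories = categories,
         nutrients = nutrients, diseases = diseases, rules = rules,
         recipes = recipes, edges = NULL, matrices = NULL,
         discouraged = NULL),
    class = "food_kg")
  kg$matrices <- kg_matrices(recipes, composition, dishes, ingredients,
                             nutrients)
  kg$discouraged <- infer_all_disease_dishes(kg)
  kg$edges <- kg_edge_table(kg, composition)
  kg
}

validate_recipes <- function(recipes, composition) {
  need_r <- c("dish_id", "name", "dish_category", "flavor", "cooking_method",
              "price_level", "ingredient_id", "grams")
  need_c <- c("ingredient_id", "name", "category_id", "nutrient_id",
              "amount_per_100g", "unit")
  miss <- setdiff(need_r, names(recipes))
  if (length(miss)) abort(paste0("recipes table lacks column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "eldermeal_load_error")
  miss <- setdiff(need_c, names(composition))
  if (length(miss)) abort(paste0("composition table lacks column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "eldermeal_load_error")
  if (any(recipes$grams < 0, na.rm = TRUE)) {
    i <- which(recipes$grams < 0)[1]
    abort(paste0("negative gram amount for dish ", recipes$dish_id[i],
                 ", ingredient ", recipes$ingredient_id[i]),
          class = "eldermeal_validation_error")
  }
  if (any(composition$amount_per_100g < 0, na.rm = TRUE)) {
    i <- which(composition$amount_per_100g < 0)[1]
    abort(paste0("negative nutrient amount for ingredient ",
                 composition$ingredient_id[i], ", nutrient ",
                 composition$nutrient_id[i]),
          class = "eldermeal_validation_error")
  }
  bad <- !(recipes$dish_category %in% DISH_CATEGORIES)
  if (any(bad)) {
    abort(paste0("unknown dish_category '",
                 recipes$dish_category[which(bad)[1]], "' for dish ",
                 recipes$dish_id[which(bad)[1]]),
          class = "eldermeal_validation_error")
  }
  unresolved <- setdiff(recipes$ingredient_id, composition$ingredient_id)
  if (length(unresolved) > 0) {
    d <- recipes$dish_id[match(unresolved[1], recipes$ingredient_id)]
    abort(paste0("dish ", d, " references ingredient ", unresolved[1],
                 " absent from the composition table"),
          class = "eldermeal_load_error")
  }
  invisible(TRUE)
}

normalize_rules <- function(disease_rules) {
  empty <- tibble(disease_id = character(), relation = character(),
                  target_type = character(), target_id = character(),
                  bound_type = character(), amount = double(),
                  unit = character())
  if (is.null(disease_rules) || nrow(disease_rules) == 0) return(empty)
  r <- as_tibble(disease_rules)
  for (col in c("bound_type", "unit")) if (!col %in% names(r)) r[[col]] <- NA_character_
  if (!"amount" %in% names(r)) r$amount <- NA_real_
  bad <- !(r$relation %in% c("discourage", "restrict", "recommend"))
  if (any(bad)) abort(paste0("unknown rule relation '", r$relation[which(bad)[1]], "'"),
                      class = "eldermeal_validation_error")
  # per disease+target the three relation sets must be disjoint
  dup <- r %>%
    distinct(.data$disease_id, .data$relation, .data$target_id) %>%
    count(.data$disease_id, .data$target_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("disease ", dup$disease_id[1], " assigns multiple relation ",
                 "types to target ", dup$target_id[1]),
          class = "eldermeal_validation_error")
  }
  no_unit <- r$relation == "restrict" & (is.na(r$unit) | r$unit == "")
  if (any(no_unit)) {
    abort(paste0("restrict rule without a unit (disease ",
                 r$disease_id[which(no_unit)[1]], ")"),
          class = "eldermeal_validation_error")
  }
  r[c("disease_id", "relation", "target_type", "target_id", "bound_type",
      "amount", "unit")]
}

# dense matrix caches: ingredient x nutrient (per 100 g),
# dish x ingredient (grams per portion), dish x nutrient (per portion)
kg_matrices <- function(recipes, composition, dishes, ingredients, nutrients) {
  ing <- ingredients$ingredient_id
  nut <- nutrients$nutrient_id
  dsh <- dishes$dish_id
  IN <- matrix(0, length(ing), length(nut), dimnames = list(ing, nut))
  IN[cbind(match(composition$ingredient_id, ing),
           match(composition$nutrient_id, nut))] <- composition$amount_per_100g
  DI <- matrix(0, length(dsh), length(ing), dimnames = list(dsh, ing))
  if (nrow(recipes) > 0) {
    # duplicated dish-ingredient rows accumulate
    di <- match(recipes$dish_id, dsh)
    ii <- match(recipes$ingredient_id, ing)
    agg <- rowsum(recipes$grams, (di - 1) * length(ing) + ii)
    flat <- as.integer(rownames(agg))
    DI[cbind((flat - 1L) %/% length(ing) + 1L,
             (flat - 1L) %% length(ing) + 1L)] <- agg[, 1]
  }
  DN <- DI %*% IN / 100
  list(ing_nutrient = IN, dish_ingredient = DI, dish_nutrient = DN)
}

# apply the disease->dish inference rule for every disease
infer_all_disease_dishes <- function(kg) {
  out <- lapply(kg$diseases$disease_id, function(d) infer_disease_dish(kg, d))
  names(out) <- kg$diseases$disease_id
  out
}

kg_edge_table <- function(kg, composition) {
  rec <- kg$recipes
  e_consist <- tibble(head = rec$dish_id, relation = "consist_of",
                      tail = rec$ingredient_id, amount = rec$grams)
  e_belong <- tibble(head = kg$ingredients$ingredient_id,
                     relation = "belong_to",
                     tail = kg$ingredients$category_id, amount = NA_real_)
  e_contain_in <- tibble(head = composition$ingredient_id,
                         relation = "contain", tail = composition$nutrient_id,
                         amount = composition$amount_per_100g)
  DN <- kg$matrices$dish_nutrient
  nz <- which(DN > 0, arr.ind = TRUE)
  e_contain_dish <- tibble(head = rownames(DN)[nz[, 1]], relation = "contain",
                           tail = colnames(DN)[nz[, 2]], amount = DN[nz])
  e_rules <- tibble(head = kg$rules$disease_id, relation = kg$rules$relation,
                    tail = kg$rules$target_id, amount = kg$rules$amount)
  e_disc_dish <- tibble(
    head = rep(names(kg$discouraged), lengths(kg$discouraged)),
    relation = "discourage",
    tail = unlist(kg$discouraged, use.names = FALSE) %||% character(),
    amount = NA_real_)
  bind_rows(e_consist, e_belong, e_contain_in, e_contain_dish, e_rules,
            e_disc_dish) %>%
    distinct(.data$head, .data$relation, .data$tail, .keep_all = TRUE)
}

#' @export
print.food_kg <- function(x, ...) {
  cat("<food_kg>\n")
  cat(sprintf("  dishes: %d | ingredients: %d | categories: %d | nutrients: %d | diseases: %d\n",
              nrow(x$dishes), nrow(x$ingredients), nrow(x$categories),
              nrow(x$nutrients), nrow(x$diseases)))
  cat(sprintf("  triples: %d (%s)\n", nrow(x$edges),
              paste(names(table(x$edges$relation)), collapse = ", ")))
  invisible(x)
}

#' Remove duplicate dishes by name and ingredient-set similarity
#'
#' Two dishes are duplicates when their (case-folded) names are equal or the
#' Jaccard similarity of their ingredient-id sets is at or above `threshold`
#' (the threshold is inclusive). Within each duplicate cluster the variant
#' whose exact ingredient set occurs most frequently in the input is kept;
#' frequency ties keep the lexicographically smallest dish id.
#'
#' @param recipes Long-format recipe tibble (see [build_graph()]).
#' @param threshold Inclusive Jaccard threshold in (0, 1]. Default 0.85.
#' @return The recipe tibble restricted to retained dishes.
#' @export
dedup_dishes <- function(recipes, threshold = 0.85) {
  assert_that(threshold > 0 && threshold <= 1,
              "dedup threshold must be in (0, 1]")
  recipes <- as_tibble(recipes)
  if (nrow(recipes) == 0) return(recipes)
  ids <- sort(unique(recipes$dish_id))
  if (length(ids) == 1L) return(recipes)
  sets <- split(recipes$ingredient_id, recipes$dish_id)[ids]
  sets <- lapply(sets, unique)
  nm <- tolower(recipes$name[match(ids, recipes$dish_id)])

  # pairwise Jaccard via a binary membership matrix
  vocab <- unique(unlist(sets))
  M <- matrix(0L, length(ids), length(vocab), dimnames = list(ids, vocab))
  M[cbind(rep(seq_along(ids), lengths(sets)),
          match(unlist(sets), vocab))] <- 1L
  inter <- M %*% t(M)
  sz <- rowSums(M)
  uni <- outer(sz, sz, "+") - inter
  jac <- inter / pmax(uni, 1)
  dup <- (jac >= threshold) | outer(nm, nm, "==")
  diag(dup) <- FALSE

  g <- igraph::graph_from_adjacency_matrix(dup, mode = "undirected")
  comp <- igraph::components(g)$membership

  # frequency of each exact ingredient-set signature in the input
  sig <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  freq <- table(sig)[sig]
  keep <- vapply(split(seq_along(ids), comp), function(members) {
    f <- freq[members]
    best <- members[f == max(f)]
    best[order(ids[best])][1]
  }, integer(1))
  recipes[recipes$dish_id %in% ids[keep], , drop = FALSE]
}

#' Infer a dish's nutrient totals from its composition
#'
#' Applies the first-order rule
#' `Contain(ingredient, nutrient, M) & Consist_of(dish, ingredient, P)
#'  => Contain(dish, nutrient, Q)` with `Q = sum_i M_i * P_i / 100`,
#' where `P_i` is the grams of ingredient i in the dish and `M_i` the
#' nutrient amount per 100 g.
#'
#' @param kg A `food_kg`.
#' @param dish_id A dish id present in the graph.
#' @return Tibble with columns `nutrient_id`, `amount` (per portion).
#' @export
infer_dish_nutrients <- function(kg, dish_id) {
  rec <- kg$recipes[kg$recipes$dish_id == dish_id, , drop = FALSE]
  if (nrow(rec) == 0) {
    abort(paste0("dish ", dish_id, " not present in the graph"),
          class = "eldermeal_inference_error")
  }
  missing <- setdiff(rec$ingredient_id, kg$ingredients$ingredient_id)
  if (length(missing) > 0) {
    abort(paste0("dish ", dish_id, " uses ingredient ", missing[1],
                 " with no composition data"),
          class = "eldermeal_inference_error")
  }
  IN <- kg$matrices$ing_nutrient
  q <- colSums(IN[rec$ingredient_id, , drop = FALSE] * rec$grams / 100)
  tibble(nutrient_id = names(q), amount = unname(q))
}

#' Infer the dishes discouraged for a disease
#'
#' Applies `Discourage(disease, ingredient) & Consist_of(dish, ingredient)
#' => Discourage(disease, dish)`. An ingredient also inherits the
#' discouragement of its ingredient category, so dishes using any ingredient
#' of a discouraged category are excluded too.
#'
#' @param kg A `food_kg`.
#' @param disease_id A disease id present in the graph's rule table.
#' @return Character vector of discouraged dish ids (sorted).
#' @export
infer_disease_dish <- function(kg, disease_id) {
  r <- kg$rules[kg$rules$disease_id == disease_id &
                  kg$rules$relation == "discourage", , drop = FALSE]
  if (nrow(r) == 0) {
    if (!disease_id %in% kg$rules$disease_id) {
      abort(paste0("disease ", disease_id, " not present in the graph"),
            class = "eldermeal_inference_error")
    }
    return(character())
  }
  bad_ing <- r$target_id[r$target_type == "ingredient"]
  bad_cat <- r$target_id[r$target_type == "category"]
  if (length(bad_cat) > 0) {
    inherit <- kg$ingredients$ingredient_id[
      kg$ingredients$category_id %in% bad_cat]
    bad_ing <- union(bad_ing, inherit)
  }
  if (length(bad_ing) == 0) return(character())
  sort(unique(kg$recipes$dish_id[kg$recipes$ingredient_id %in% bad_ing]))
}

#' Standardize per-dish sodium to a target mass-fraction band
#'
#' Rescales the grams of seasoning-category ingredients in each dish so the
#' dish's total sodium mass fraction (grams of sodium per gram of portion)
#' falls inside `[low, high]`; dishes already inside the band are returned
#' unchanged, and non-seasoning composition entries are never touched. The
#' seasoning scale factor `f` solves `(b + f*s) / (Mb + f*m) = t` exactly,
#' where `b`, `Mb` are the sodium and mass of the non-seasoning part, `s`,
#' `m` of the seasoning part, and `t` the nearest band edge, so the portion
#' mass stays consistent with the summed composition.
#'
#' @param recipes Long-format recipe tibble.
#' @param composition Ingredient composition tibble (must include the sodium
#'   nutrient).
#' @param low,high Sodium mass-fraction band. Defaults 0.008 and 0.010.
#' @param sodium_nutrient Nutrient id carrying sodium. Default `"sodium_mg"`.
#' @param seasoning_categories Category ids whose ingredients count as
#'   seasonings. Default `"seasonings"`.
#' @return The recipe tibble with adjusted seasoning grams.
#' @export
standardize_sodium <- function(recipes, composition, low = 0.008,
                               high = 0.010, sodium_nutrient = "sodium_mg",
                               seasoning_categories = "seasonings") {
  assert_that(low > 0 && low <= high, "sodium band must satisfy 0 < low <= high")
  recipes <- as_tibble(recipes)
  comp <- as_tibble(composition)
  na_rows <- comp[comp$nutrient_id == sodium_nutrient, , drop = FALSE]
  if (nrow(na_rows) == 0) {
    abort(paste0("composition has no '", sodium_nutrient, "' rows"),
          class = "eldermeal_validation_error")
  }
  unit <- unique(na_rows$unit)[1]
  to_g <- switch(unit, g = 1, mg = 1e-3, ug = 1e-6, "µg" = 1e-6,
                 abort(paste0("unsupported sodium unit '", unit, "'"),
                       class = "eldermeal_validation_error"))
  # grams of sodium per gram of ingredient
  dens <- setNames(na_rows$amount_per_100g * to_g / 100, na_rows$ingredient_id)
  cat_of <- comp %>% distinct(.data$ingredient_id, .data$category_id)
  seasoning <- setNames(cat_of$category_id %in% seasoning_categories,
                        cat_of$ingredient_id)

  r_dens <- unname(dens[recipes$ingredient_id]) %na% 0
  r_seas <- (unname(seasoning[recipes$ingredient_id]) %na% FALSE) & r_dens > 0

  dish_ids <- sort(unique(recipes$dish_id))
  di <- match(recipes$dish_id, dish_ids)
  agg <- function(x) {
    out <- numeric(length(dish_ids))
    a <- rowsum(x, di)
    out[as.integer(rownames(a))] <- a[, 1]
    out
  }
  mass <- agg(recipes$grams)
  if (any(mass <= 0)) {
    abort(paste0("dish ", dish_ids[which(mass <= 0)[1]],
                 " has zero portion mass"),
          class = "eldermeal_validation_error")
  }
  na_tot <- agg(recipes$grams * r_dens)
  m_seas <- agg(recipes$grams * r_seas)
  na_seas <- agg(recipes$grams * r_dens * r_seas)
  frac <- na_tot / mass
  target <- ifelse(frac < low, low, ifelse(frac > high, high, NA_real_))
  need <- which(!is.na(target))
  if (length(need) == 0) return(recipes)
  mb <- mass - m_seas
  b <- na_tot - na_seas
  bad <- need[na_seas[need] <= 0 |
                b[need] / pmax(mb[need], 1e-12) > target[need]]
  f <- rep(1, length(dish_ids))
  f[need] <- (target[need] * mb[need] - b[need]) /
    (na_seas[need] - target[need] * m_seas[need])
  bad <- union(bad, need[f[need] < 0])
  if (length(bad) > 0) {
    abort(paste0("dish ", dish_ids[bad[1]], " cannot reach the sodium band ",
                 "by rescaling seasonings"),
          class = "eldermeal_validation_error")
  }
  recipes$grams <- recipes$grams * ifelse(r_seas, f[di], 1)
  recipes
}

#' Default relation lexicon for rule extraction
#'
#' Maps surface patterns in guideline statements to the three
#' disease-to-food relation types.
#'
#' @return Tibble with columns `pattern` (regular expression, matched
#'   case-insensitively) and `relation`.
#' @export
default_relation_lexicon <- function() {
  tibble(
    pattern = c("\\bavoid\\b", "should not (eat|consume|take)",
                "\\beliminate\\b", "\\bforbidden\\b", "stay away from",
                "\\blimit\\b", "\\brestrict\\b", "no more than",
                "less than", "at most", "not exceed", "<",
                "at least", "no less than", "≥", ">",
                "\\brecommend", "\\bprefer\\b", "\\bbeneficial\\b",
                "\\bencourage", "\\bincrease\\b", "good source"),
    relation = c(rep("discourage", 5),
                 rep("restrict", 7), rep("restrict", 0),
                 rep("restrict", 4),
                 rep("recommend", 6)))
}

#' Parse disease-diet guideline statements into typed rules
#'
#' Applies a pattern lexicon to free-text statements, producing one typed
#' triple per matched statement. Restrict statements additionally capture a
#' numeric daily bound with its unit and direction (`max` for upper bounds,
#' `min` for lower). Statements matching no pattern are reported in the
#' `unmatched` attribute (and a warning), never silently dropped; a
#' statement matching two different relation types raises an ambiguity
#' error listing the offending patterns.
#'
#' @param statements Tibble with columns `disease_id`, `target_type`,
#'   `target_id`, `text`.
#' @param lexicon Pattern map, see [default_relation_lexicon()].
#' @return Rule tibble in the [build_graph()] `disease_rules` schema, with
#'   a `source_text` column and an `unmatched` attribute.
#' @export
#' @examples
#' st <- tibble::tibble(disease_id = "gout", target_type = "ingredient",
#'                      target_id = "ing_007",
#'                      text = "patients with gout should avoid organ meats")
#' parse_disease_rules(st)
parse_disease_rules <- function(statements, lexicon = default_relation_lexicon()) {
  statements <- as_tibble(statements)
  empty <- tibble(disease_id = character(), relation = character(),
                  target_type = character(), target_id = character(),
                  bound_type = character(), amount = double(),
                  unit = character(), source_text = character())
  if (nrow(statements) == 0) {
    attr(empty, "unmatched") <- statements
    return(empty)
  }
  rows <- purrr::pmap(statements, function(disease_id, target_type, target_id,
                                           text, ...) {
    hits <- lexicon[vapply(lexicon$pattern,
                           function(p) grepl(p, text, ignore.case = TRUE),
                           logical(1)), , drop = FALSE]
    rels <- unique(hits$relation)
    # a bound direction alongside a discourage/recommend verb is not
    # ambiguous; true ambiguity is discourage vs recommend
    if (all(c("discourage", "recommend") %in% rels)) {
      abort(paste0("statement matches two relation types (",
                   paste(hits$pattern, collapse = ", "), "): ", text),
            class = "eldermeal_ambiguity_error")
    }
    if (length(rels) == 0) return(NULL)
    rel <- if ("restrict" %in% rels && length(rels) > 1) {
      setdiff(rels, "restrict")[1]
    } else rels[1]
    amount <- NA_real_
    unit <- NA_character_
    bound_type <- NA_character_
    if (rel == "restrict") {
      m <- regmatches(text, regexec(
        "([0-9]+\\.?[0-9]*)\\s*(mg|g|kg|ug|µg|kcal)\\s*(/|per)\\s*(day|d)\\b",
        text, ignore.case = TRUE))[[1]]
      if (length(m) > 0) {
        amount <- as.numeric(m[2])
        unit <- tolower(m[3])
      }
      lower <- grepl("at least|no less than|more than|>|≥", text,
                     ignore.case = TRUE) &&
        !grepl("no more than|not exceed|less than|<", text, ignore.case = TRUE)
      bound_type <- if (lower) "min" else "max"
    }
    tibble(disease_id = disease_id, relation = rel,
           target_type = target_type, target_id = target_id,
           bound_type = bound_type, amount = amount, unit = unit,
           source_text = text)
  })
  matched <- !vapply(rows, is.null, logical(1))
  out <- bind_rows(rows[matched])
  if (nrow(out) == 0) out <- empty
  unmatched <- statements[!matched, , drop = FALSE]
  if (nrow(unmatched) > 0) {
    warn(paste0(nrow(unmatched), " statement(s) matched no lexicon pattern; ",
                "see attr(, 'unmatched')"))
  }
  attr(out, "unmatched") <- unmatched
  out
}
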