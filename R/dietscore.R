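#' Dietary diversity and diet-quality scoring
#'
#' Two outcome indices: the dietary diversity score (DDS), the count of
#' distinct food groups (0-9) represented in a day's combos, and a
#' configurable guideline diet-quality index on a 0-110 scale whose
#' components follow the Chinese senior food-pagoda groups. The component
#' table, not code, defines the quality scoring, so a refined component
#' specification can be swapped in as data.
#'
#' @name dietscore
NULL

DDS_GROUPS <- c("cereals_tubers", "vegetables", "fruits", "meat",
                "fish_seafood", "eggs", "dairy", "legumes_nuts", "oils_fats")

#' Default mapping from ingredient categories to the nine diversity groups
#'
#' Maps the ingredient categories used by the synthetic food database onto
#' the standard nine food groups of the dietary diversity score; categories
#' outside the scoring scheme (seasonings) map to `"none"`.
#'
#' @return Named character vector `category_id -> dds group`.
#' @export
default_dds_groups <- function() {
  c(rice_products = "cereals_tubers", wheat_products = "cereals_tubers",
    tubers = "cereals_tubers",
    leafy_vegetables = "vegetables", root_vegetables = "vegetables",
    gourd_vegetables = "vegetables", mushrooms = "vegetables",
    fruits = "fruits",
    pork = "meat", poultry = "meat", beef_lamb = "meat",
    organ_meats = "meat",
    fish = "fish_seafood", shellfish = "fish_seafood",
    eggs = "eggs", dairy = "dairy",
    soy_products = "legumes_nuts", nuts = "legumes_nuts",
    cooking_oils = "oils_fats", seasonings = "none")
}

#' Dietary diversity score of a day's combos
#'
#' Counts the distinct diversity groups represented by at least one
#' ingredient across all dishes of the day's selected combos (nonrepetitive
#' count, 0-9).
#'
#' @param dish_ids Character vector of the dish ids eaten that day (one or
#'   more combos, flattened), or a list of such vectors.
#' @param kg A `food_kg`.
#' @param groups Named mapping `category_id -> group`, see
#'   [default_dds_groups()].
#' @param strict If `TRUE`, an ingredient category with no group mapping
#'   raises a scoring error; otherwise it is treated as `"none"`.
#' @return Integer in `[0, 9]`.
#' @export
dds <- function(dish_ids, kg, groups = default_dds_groups(),
                strict = FALSE) {
  dish_ids <- unique(unlist(dish_ids, use.names = FALSE))
  if (length(dish_ids) == 0) return(0L)
  rec <- kg$recipes[kg$recipes$dish_id %in% dish_ids &
                      kg$recipes$grams > 0, , drop = FALSE]
  cats <- kg$ingredients$category_id[
    match(unique(rec$ingredient_id), kg$ingredients$ingredient_id)]
  mapped <- unname(groups[cats])
  if (strict && anyNA(mapped)) {
    abort(paste0("no diversity-group mapping for category ",
                 cats[which(is.na(mapped))[1]]),
          class = "eldermeal_scoring_error")
  }
  length(intersect(unique(mapped), DDS_GROUPS))
}

#' Aggregate a day's intake for quality-index scoring
#'
#' Sums food-group grams and nutrient amounts over the dishes eaten in a
#' day, keyed as `group:<group>` and `nutrient:<nutrient_id>` to match
#' quality-spec component bases.
#'
#' @inheritParams dds
#' @return Named numeric vector of basis amounts.
#' @export
day_intake <- function(dish_ids, kg, groups = default_dds_groups()) {
  dish_ids <- unique(unlist(dish_ids, use.names = FALSE))
  st <- world_state(kg, groups = groups)
  idx <- match(dish_ids, st$dish_ids)
  idx <- idx[!is.na(idx)]
  gg <- if (length(idx)) colSums(st$dish_group_g[idx, , drop = FALSE]) else
    setNames(rep(0, length(DDS_GROUPS)), DDS_GROUPS)
  nn <- if (length(idx)) colSums(st$DN[idx, , drop = FALSE]) else
    setNames(rep(0, ncol(st$DN)), colnames(st$DN))
  c(setNames(gg, paste0("group:", names(gg))),
    setNames(nn, paste0("nutrient:", names(nn))))
}

#' Construct a diet-quality index specification
#'
#' @param components Tibble with columns `component`, `basis`
#'   (`"group"` or `"nutrient"`), `basis_id`, `low`, `high` (the optimal
#'   daily intake band; `low = 0` gives a moderation component), and
#'   `max_points`.
#' @param total_points Required sum of `max_points` (default 110).
#' @return A `quality_spec` object.
#' @export
quality_spec <- function(components, total_points = 110) {
  components <- as_tibble(components)
  need <- c("component", "basis", "basis_id", "low", "high", "max_points")
  miss <- setdiff(need, names(components))
  if (length(miss)) abort(paste0("quality spec lacks column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "eldermeal_validation_error")
  if (abs(sum(components$max_points) - total_points) > 1e-9) {
    abort(sprintf("component points sum to %g, expected %g",
                  sum(components$max_points), total_points),
          class = "eldermeal_validation_error")
  }
  if (any(components$low < 0 | components$high < components$low)) {
    abort("each component needs 0 <= low <= high",
          class = "eldermeal_validation_error")
  }
  structure(components, total_points = total_points,
            class = c("quality_spec", class(components)))
}

#' Default diet-quality component table (0-110)
#'
#' Eleven components of 10 points each, following the food-pagoda groups for
#' Chinese seniors: eight food-group intake bands (daily grams), an oil
#' moderation band, a sodium moderation band and a daily energy band. Bands
#' are daily amounts; use [scale_quality_spec()] to score a single meal.
#'
#' @return A `quality_spec`.
#' @export
default_quality_spec <- function() {
  quality_spec(tibble(
    component = c("cereals_tubers", "vegetables", "fruits", "meat",
                  "fish_seafood", "eggs", "dairy", "legumes_nuts",
                  "oils_moderation", "sodium_moderation", "energy"),
    basis = c(rep("group", 9), "nutrient", "nutrient"),
    basis_id = c("cereals_tubers", "vegetables", "fruits", "meat",
                 "fish_seafood", "eggs", "dairy", "legumes_nuts",
                 "oils_fats", "sodium_mg", "energy_kcal"),
    low = c(200, 300, 200, 40, 40, 40, 300, 30, 0, 0, 1600),
    high = c(300, 500, 350, 75, 75, 50, 400, 50, 30, 2000, 2400),
    max_points = rep(10, 11)))
}

#' Derive a world-consistent diet-quality spec from a knowledge graph
#'
#' Builds an 11-component, 110-point quality spec whose food-group bands are
#' calibrated to the graph's own food supply: the band for each diversity
#' group is `[0.5, 1.5]` times the mean group grams among sampled
#' template-valid combos that contain the group at all (a typical served
#' portion), expressed as daily amounts via the lunch fraction. This is the
#' same calibration basis as the nutrient guideline ranges, so guideline
#' adequacy and quality scoring share one basis, as they do when both
#' derive from a single set of national dietary guidelines.
#' Groups absent from the food supply and the sodium/energy components fall
#' back to the graph's guideline rows or, failing that, the fixed bands of
#' [default_quality_spec()].
#'
#' @param kg A `food_kg`.
#' @param lunch_fraction Meal share used to express combo amounts as daily
#'   equivalents. Default 0.40.
#' @param n_samples Combos sampled for calibration (internally seeded, so
#'   the derivation is deterministic). Default 200.
#' @return A `quality_spec` (daily bands).
#' @export
derive_quality_spec <- function(kg, lunch_fraction = 0.4, n_samples = 200) {
  st <- world_state(kg)
  base <- default_quality_spec()
  safe <- seq_len(st$n_dishes)
  draws <- with_seed(104729, {
    out <- matrix(0, n_samples, length(DDS_GROUPS),
                  dimnames = list(NULL, DDS_GROUPS))
    ok <- logical(n_samples)
    for (s in seq_len(n_samples)) {
      ids <- random_template_combo(st, safe)
      if (is.null(ids)) next
      out[s, ] <- colSums(st$dish_group_g[ids, , drop = FALSE])
      ok[s] <- TRUE
    }
    out[ok, , drop = FALSE]
  })
  # typical served portion: mean over combos actually containing the group
  mu <- if (nrow(draws) > 0) {
    apply(draws, 2, function(x) if (any(x > 0)) mean(x[x > 0]) else 0)
  } else setNames(rep(0, length(DDS_GROUPS)), DDS_GROUPS)
  for (i in which(base$basis == "group")) {
    g <- base$basis_id[i]
    if (!is.na(mu[g]) && mu[g] > 1) {
      lo <- if (base$low[i] == 0) 0 else 0.5 * mu[g] / lunch_fraction
      base$low[i] <- round(lo, 2)
      base$high[i] <- round(1.5 * mu[g] / lunch_fraction, 2)
    }
  }
  gl_hi <- setNames(kg$nutrients$guideline_high, kg$nutrients$nutrient_id)
  gl_lo <- setNames(kg$nutrients$guideline_low, kg$nutrients$nutrient_id)
  for (i in which(base$basis == "nutrient")) {
    id <- base$basis_id[i]
    if (!is.na(gl_hi[id] %na% NA)) {
      if (base$low[i] > 0 && !is.na(gl_lo[id] %na% NA)) {
        base$low[i] <- gl_lo[[id]]
      }
      base$high[i] <- gl_hi[[id]]
    }
  }
  quality_spec(base, total_points = attr(base, "total_points"))
}

#' Read a diversity-group mapping or quality spec from YAML
#'
#' The scoring configuration is data, not code: the category-to-group
#' mapping and the quality component table ship as YAML
#' (`inst/extdata/dds_groups.yaml`, `inst/extdata/cdgi_spec.yaml`) and a
#' refined component table can be swapped in as a file.
#'
#' @param path YAML file; defaults to the copies installed with the
#'   package.
#' @return [read_dds_groups()]: named character vector
#'   `category_id -> group`. [read_quality_spec()]: a `quality_spec`.
#' @export
read_dds_groups <- function(path = system.file("extdata", "dds_groups.yaml",
                                               package = "eldermeal")) {
  unlist(yaml::read_yaml(path))
}

#' @rdname read_dds_groups
#' @export
read_quality_spec <- function(path = system.file("extdata",
                                                 "cdgi_spec.yaml",
                                                 package = "eldermeal")) {
  doc <- yaml::read_yaml(path)
  quality_spec(bind_rows(lapply(doc$components, as_tibble)),
               total_points = doc$total_points)
}

#' Scale a daily quality spec to one meal
#'
#' Multiplies every component band by a meal fraction (e.g. the 0.40 lunch
#' share of the 3:4:3 daily split) so a single meal's intake is scored
#' against meal-sized bands.
#'
#' @param spec A `quality_spec`.
#' @param fraction Meal share of daily intake.
#' @return A `quality_spec` with scaled bands.
#' @export
scale_quality_spec <- function(spec, fraction) {
  spec$low <- spec$low * fraction
  spec$high <- spec$high * fraction
  quality_spec(spec, total_points = attr(spec, "total_points"))
}

# vectorized piecewise-linear component score: full points inside
# [low, high], linear to 0 at intake 0 and at 2*high, clamped
component_score <- function(x, low, high, max_points) {
  s <- ifelse(x < low, max_points * x / pmax(low, 1e-12),
              ifelse(x <= high, max_points,
                     max_points * (1 - (x - high) / pmax(high, 1e-12))))
  pmin(pmax(s, 0), max_points)
}

#' Guideline diet-quality index
#'
#' Scores a day's intake against a component specification: each component
#' earns its full points when intake lies inside its optimal band, with
#' linear decay to zero at zero intake and at twice the band's upper edge.
#'
#' @param intake Named numeric vector from [day_intake()] (keys
#'   `group:<g>` / `nutrient:<id>`).
#' @param spec A `quality_spec`; see [default_quality_spec()].
#' @return Numeric in `[0, total_points]`.
#' @export
#' @examples
#' spec <- default_quality_spec()
#' optimal <- setNames((spec$low + spec$high) / 2,
#'                     paste0(spec$basis, ":", spec$basis_id))
#' quality_index(optimal, spec)  # 110
quality_index <- function(intake, spec = default_quality_spec()) {
  if (any(intake < 0, na.rm = TRUE)) {
    abort("intake amounts must be nonnegative",
          class = "eldermeal_validation_error")
  }
  keys <- paste0(spec$basis, ":", spec$basis_id)
  x <- unname(intake[keys]) %na% 0
  sum(component_score(x, spec$low, spec$high, spec$max_points))
}
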