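#' Serialization and validated table loading
#'
#' All tabular artifacts are UTF-8 comma-separated files with a mandatory
#' header row; nested structures (graphs, cohorts, run outputs) serialize to
#' JSON, per-record logs to JSON lines. Every writer embeds a provenance
#' block (seed, package version, configuration digest) where the format
#' allows it.
#'
#' @name cli_io
NULL

TABLE_SCHEMAS <- list(
  recipes = c("dish_id", "name", "dish_category", "flavor", "cooking_method",
              "price_level", "ingredient_id", "grams"),
  composition = c("ingredient_id", "name", "category_id", "nutrient_id",
                  "amount_per_100g", "unit"),
  disease_rules = c("disease_id", "relation", "target_type", "target_id",
                    "bound_type", "amount", "unit"),
  guidelines = c("nutrient_id", "low", "high", "unit"))

#' Load and validate the four knowledge-graph input tables
#'
#' Reads CSV files against the fixed schemas, reporting schema mismatches
#' and value violations (negative amounts) with file and row references.
#'
#' @param recipes,composition,disease_rules,guidelines File paths; the
#'   latter two may be `NULL`.
#' @return Named list of validated tibbles, ready for [build_graph()].
#' @export
load_tables <- function(recipes, composition, disease_rules = NULL,
                        guidelines = NULL) {
  read_one <- function(path, what) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      abort(paste0(what, " file not found: ", path),
            class = "eldermeal_load_error")
    }
    tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(TABLE_SCHEMAS[[what]], names(tb))
    if (length(miss) > 0) {
      abort(paste0(path, ": missing column(s) ", paste(miss, collapse = ", ")),
            class = "eldermeal_load_error")
    }
    num_cols <- intersect(c("grams", "amount_per_100g", "amount", "low",
                            "high"), names(tb))
    for (cc in num_cols) {
      bad <- which(!is.na(tb[[cc]]) & tb[[cc]] < 0)
      if (length(bad) > 0) {
        abort(sprintf("%s: negative %s at row %d", path, cc, bad[1]),
              class = "eldermeal_validation_error")
      }
    }
    tb
  }
  list(recipes = read_one(recipes, "recipes"),
       composition = read_one(composition, "composition"),
       disease_rules = read_one(disease_rules, "disease_rules"),
       guidelines = read_one(guidelines, "guidelines"))
}

provenance <- function(seed = NULL, config = NULL) {
  list(package = "eldermeal",
       version = as.character(utils::packageVersion("eldermeal")),
       seed = seed,
       config_digest = if (!is.null(config)) {
         sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
       },
       written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a knowledge graph to a JSON document
#'
#' @param kg A `food_kg`.
#' @param path Output file.
#' @param seed Optional seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_foodkg <- function(kg, path, seed = NULL) {
  doc <- list(provenance = provenance(seed = seed),
              dishes = kg$dishes, ingredients = kg$ingredients,
              categories = kg$categories, nutrients = kg$nutrients,
              diseases = kg$diseases, rules = kg$rules,
              recipes = kg$recipes, edges = kg$edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a knowledge graph written by [write_foodkg()]
#'
#' Rebuilds the graph from its serialized recipe and composition content,
#' so matrix caches and inferred edges are reconstructed rather than
#' trusted from disk.
#'
#' @param path JSON file produced by [write_foodkg()].
#' @return A `food_kg`.
#' @export
read_foodkg <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp_long <- as_tibble(doc$edges) %>%
    filter(.data$relation == "contain",
           .data$head %in% doc$ingredients$ingredient_id)
  ing <- as_tibble(doc$ingredients)
  nut <- as_tibble(doc$nutrients)
  composition <- comp_long %>%
    mutate(ingredient_id = .data$head, nutrient_id = .data$tail,
           amount_per_100g = .data$amount) %>%
    left_join(ing, by = "ingredient_id") %>%
    left_join(nut %>% select("nutrient_id", "unit"), by = "nutrient_id") %>%
    select("ingredient_id", "name", "category_id", "nutrient_id",
           "amount_per_100g", "unit")
  rules <- as_tibble(doc$rules)
  if (nrow(rules) > 0) rules$amount <- as.numeric(rules$amount)
  gl <- as_tibble(doc$nutrients) %>%
    filter(!is.na(.data$guideline_low) | !is.na(.data$guideline_high)) %>%
    mutate(low = .data$guideline_low, high = .data$guideline_high) %>%
    select("nutrient_id", "low", "high", "unit")
  dg <- setNames(doc$categories$dds_group, doc$categories$category_id)
  build_graph(as_tibble(doc$recipes), composition,
              disease_rules = if (nrow(rules) > 0) rules,
              guidelines = if (nrow(gl) > 0) gl,
              dds_groups = dg[dg != "none"],
              dedup_threshold = NULL, sodium_bounds = NULL)
}

#' Export the graph as node and edge CSV tables
#'
#' @param kg A `food_kg`.
#' @param dir Output directory (created if needed); writes `nodes.csv` and
#'   `edges.csv`.
#' @return The two file paths, invisibly.
#' @export
export_graph_csv <- function(kg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- bind_rows(
    tibble(id = kg$dishes$dish_id, label = kg$dishes$name, type = "dish"),
    tibble(id = kg$ingredients$ingredient_id, label = kg$ingredients$name,
           type = "ingredient"),
    tibble(id = kg$categories$category_id, label = kg$categories$name,
           type = "category"),
    tibble(id = kg$nutrients$nutrient_id, label = kg$nutrients$name,
           type = "nutrient"),
    tibble(id = kg$diseases$disease_id, label = kg$diseases$name,
           type = "disease"))
  np <- file.path(dir, "nodes.csv")
  ep <- file.path(dir, "edges.csv")
  readr::write_csv(nodes, np)
  readr::write_csv(kg$edges, ep)
  invisible(c(np, ep))
}

#' Write a cohort (with histories) to JSON
#'
#' @param cohort Cohort tibble.
#' @param path Output file.
#' @param seed Optional provenance seed.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  doc <- list(provenance = provenance(seed = seed), users = cohort)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path JSON file.
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  users <- as_tibble(doc$users)
  fix_hist <- function(h) {
    if (is.null(h) || (is.data.frame(h) && nrow(h) == 0) ||
        length(h) == 0) {
      return(tibble(day = integer(), dish_id = character()))
    }
    as_tibble(h)
  }
  users$history <- lapply(users$history, fix_hist)
  users$diseases <- lapply(users$diseases, function(d) {
    as.character(unlist(d) %||% character())
  })
  users
}

#' Export the comparison table and daily series
#'
#' Writes the group-by-indicator comparison as CSV with a stable column
#' order (group, indicator, autonomous mean (SD), recommended mean (SD),
#' t (df), p) and the per-day series with confidence bounds as CSV, plus a
#' JSON report bundling both with a provenance block.
#'
#' @param comparison An `outcome_comparison` (may have zero rows).
#' @param series Daily series tibble (`day`, `group`, `indicator`, `mean`,
#'   `ci_lo`, `ci_hi`).
#' @param dir Output directory.
#' @param seed Optional provenance seed.
#' @return Paths of the written files, invisibly.
#' @export
export_report <- function(comparison, series, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cols <- c("group", "indicator", "autonomous_mean", "autonomous_sd",
            "recommended_mean", "recommended_sd", "t", "df", "p")
  comp <- as_tibble(comparison)[, cols, drop = FALSE]
  cp <- file.path(dir, "comparison.csv")
  sp <- file.path(dir, "series.csv")
  jp <- file.path(dir, "report.json")
  readr::write_csv(comp, cp)
  readr::write_csv(as_tibble(series), sp)
  jsonlite::write_json(list(provenance = provenance(seed = seed),
                            comparison = comp, series = as_tibble(series)),
                       jp, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(cp, sp, jp))
}

#' Write per-user-day selections as JSON lines
#'
#' @param sim A `meal_simulation`.
#' @param path Output `.jsonl` file (one record per user-day).
#' @return `path`, invisibly.
#' @export
write_history_jsonl <- function(sim, path) {
  sel <- sim$selections
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(sel))) {
    rec <- list(user_id = sel$user_id[i], day = sel$day[i],
                group = sel$group[i], dish_ids = sel$dish_ids[[i]],
                dds = sel$dds[i], quality = sel$quality[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}
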