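#' User profiles and cold-start similarity
#'
#' A cohort is a tibble with one row per older adult. Scalar columns hold
#' sociodemographics, anthropometrics and the four dietary-preference
#' dimensions; `diseases` is a list-column of disease-id vectors and
#' `history` a list-column of `tibble(day, dish_id)` eating records (one row
#' per dish selected on a day).
#'
#' @name profiles
NULL

AGE_BANDS <- c("60-64", "65-79", ">=80")
BMI_BANDS <- c("<=19.9", "20.0-26.9", ">=27.0")

age_band <- function(age) {
  dplyr::case_when(age < 65 ~ AGE_BANDS[1],
                   age < 80 ~ AGE_BANDS[2],
                   TRUE ~ AGE_BANDS[3])
}

bmi_band <- function(bmi) {
  dplyr::case_when(bmi <= 19.9 ~ BMI_BANDS[1],
                   bmi < 27.0 ~ BMI_BANDS[2],
                   TRUE ~ BMI_BANDS[3])
}

#' Construct a single user profile row
#'
#' @param user_id Identifier.
#' @param sex `"male"` or `"female"`.
#' @param age_years Age in years (cohort members are 60+).
#' @param weight_kg Body weight in kg.
#' @param bmi Body mass index in kg/m^2.
#' @param income_band Ordinal income band (integer).
#' @param activity_level `"light"`, `"moderate"` or `"vigorous"`.
#' @param diseases Character vector of disease ids.
#' @param flavor,staple,oil,cooking_method Dietary preference values.
#' @param history Tibble with columns `day`, `dish_id` (may be empty).
#' @return One-row cohort tibble.
#' @export
user_profile <- function(user_id, sex, age_years, weight_kg, bmi,
                         income_band = 2L, activity_level = "light",
                         diseases = character(), flavor = "light",
                         staple = "rice", oil = "vegetable",
                         cooking_method = "steamed",
                         history = tibble(day = integer(),
                                          dish_id = character())) {
  tibble(user_id = user_id, sex = sex, age_years = as.integer(age_years),
         weight_kg = weight_kg, bmi = bmi,
         income_band = as.integer(income_band),
         activity_level = activity_level, flavor = flavor, staple = staple,
         oil = oil, cooking_method = cooking_method,
         diseases = list(as.character(diseases)),
         history = list(as_tibble(history)))
}

history_of <- function(user) user$history[[1]]
diseases_of <- function(user) user$diseases[[1]]
history_length <- function(user) {
  h <- history_of(user)
  if (is.null(h) || nrow(h) == 0) 0L else dplyr::n_distinct(h$day)
}

#' Encode a user profile as a categorical feature set
#'
#' Recodes profile fields as `dimension=value` tokens: sex, age band
#' (60-64 / 65-79 / >=80), BMI band (<=19.9 / 20.0-26.9 / >=27.0), income
#' band, activity level, the four preference dimensions, and one token per
#' diagnosed disease. Encoding is deterministic, so equal profiles yield
#' equal token sets.
#'
#' @param user One-row cohort tibble.
#' @param include_income Whether the income band enters the feature set
#'   (toggleable; default `TRUE`).
#' @return Sorted character vector of tokens.
#' @export
encode_profile <- function(user, include_income = TRUE) {
  mandatory <- c("sex", "age_years", "bmi", "activity_level", "flavor",
                 "staple", "oil", "cooking_method")
  for (f in mandatory) {
    v <- user[[f]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      abort(paste0("cannot encode profile: missing mandatory field '", f, "'"),
            class = "eldermeal_encoding_error")
    }
  }
  tokens <- c(paste0("sex=", user$sex),
              paste0("age=", age_band(user$age_years)),
              paste0("bmi=", bmi_band(user$bmi)),
              paste0("activity=", user$activity_level),
              paste0("flavor=", user$flavor),
              paste0("staple=", user$staple),
              paste0("oil=", user$oil),
              paste0("cooking=", user$cooking_method),
              paste0("disease=", sort(diseases_of(user))))
  if (include_income && !is.null(user$income_band) &&
      !is.na(user$income_band)) {
    tokens <- c(tokens, paste0("income=", user$income_band))
  }
  sort(unique(tokens))
}

#' Jaccard similarity of two feature sets
#'
#' `|a intersect b| / |a union b|`; symmetric, in `[0, 1]`. Raises an error
#' when both sets are empty (the ratio is undefined).
#'
#' @param a,b Character vectors of feature tokens.
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) set_jaccard(a, b)

#' Find the best-matching reference user for a cold-start target
#'
#' Among pool members with at least `min_history` recorded eating days,
#' returns the one maximizing the Jaccard similarity of encoded profiles to
#' the target; similarity ties keep the smallest user id.
#'
#' @param target One-row cohort tibble (the cold-start user).
#' @param pool Cohort tibble of potential reference users.
#' @param min_history Minimum eating-history length for eligibility.
#'   Default 5.
#' @param include_income Passed to [encode_profile()].
#' @return One-row cohort tibble, with the attained similarity in
#'   `attr(, "similarity")`.
#' @export
find_reference_user <- function(target, pool, min_history = 5,
                                include_income = TRUE) {
  pool <- as_tibble(pool)
  pool <- pool[pool$user_id != target$user_id, , drop = FALSE]
  hl <- vapply(seq_len(nrow(pool)),
               function(i) history_length(pool[i, ]), integer(1))
  eligible <- pool[hl >= min_history, , drop = FALSE]
  if (nrow(eligible) == 0) {
    abort("cold boot failed: no pool member has sufficient eating history",
          class = "eldermeal_coldboot_error")
  }
  ft <- encode_profile(target, include_income = include_income)
  sims <- vapply(seq_len(nrow(eligible)), function(i) {
    jaccard_similarity(ft, encode_profile(eligible[i, ],
                                          include_income = include_income))
  }, numeric(1))
  best <- which(sims == max(sims))
  best <- best[order(eligible$user_id[best])][1]
  out <- eligible[best, , drop = FALSE]
  attr(out, "similarity") <- sims[best]
  out
}

#' Rank a user's most frequently selected dishes
#'
#' @param user One-row cohort tibble.
#' @param k Maximum number of dishes to return.
#' @return Tibble with columns `dish_id`, `n_selected`, ordered by
#'   descending selection count then smallest dish id, truncated to `k`.
#'   Empty history yields an empty tibble (callers switch to cold boot).
#' @export
frequent_dishes <- function(user, k = 10L) {
  h <- history_of(user)
  if (is.null(h) || nrow(h) == 0) {
    return(tibble(dish_id = character(), n_selected = integer()))
  }
  h %>%
    count(.data$dish_id, name = "n_selected") %>%
    arrange(desc(.data$n_selected), .data$dish_id) %>%
    head(k)
}
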