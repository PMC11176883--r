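mk_user <- function(id = "u1", ...) {
  do.call(user_profile, modifyList(
    list(user_id = id, sex = "female", age_years = 72, weight_kg = 70,
         bmi = 29, income_band = 2L, activity_level = "light",
         diseases = c("hypertension", "diabetes"), flavor = "salty",
         staple = "rice"),
    list(...)))
}

test_that("profile encoding is deterministic and covers the banded dimensions", {
  u <- mk_user()
  t1 <- encode_profile(u)
  t2 <- encode_profile(mk_user())
  expect_identical(t1, t2)
  expect_true(all(c("age=65-79", "bmi=>=27.0", "disease=hypertension",
                    "disease=diabetes", "flavor=salty", "staple=rice",
                    "activity=light", "sex=female") %in% t1))
  # one token per encoded dimension plus one per disease
  expect_equal(length(t1), 9 + length(u$diseases[[1]]))

  # age and BMI band edges
  expect_true("age=60-64" %in% encode_profile(mk_user(age_years = 64)))
  expect_true("age=>=80" %in% encode_profile(mk_user(age_years = 80)))
  expect_true("bmi=<=19.9" %in% encode_profile(mk_user(bmi = 19.9)))
  expect_true("bmi=20.0-26.9" %in% encode_profile(mk_user(bmi = 26.9)))

  # differing only in flavor: symmetric difference of exactly 2 tokens
  t3 <- encode_profile(mk_user(flavor = "light"))
  expect_length(union(setdiff(t1, t3), setdiff(t3, t1)), 2)

  # income toggle
  expect_false(any(grepl("^income=",
                         encode_profile(u, include_income = FALSE))))

  # missing mandatory field
  bad <- mk_user()
  bad$sex <- NA_character_
  expect_error(encode_profile(bad), "sex",
               class = "eldermeal_encoding_error")
})

test_that("jaccard similarity follows its set definition", {
  expect_equal(jaccard_similarity(letters[1:4], letters[1:4]), 1)
  expect_equal(jaccard_similarity(letters[1:4], letters[5:8]), 0)
  a <- paste0("t", 1:8)
  b <- c(paste0("t", 1:7), "x", "y")
  expect_equal(jaccard_similarity(a, b), 0.7)
  expect_error(jaccard_similarity(character(), character()),
               class = "eldermeal_error")

  # symmetry and range over random token sets
  withr::with_seed(5, {
    for (k in 1:25) {
      a <- sample(letters, sample(1:10, 1))
      b <- sample(letters, sample(1:10, 1))
      s <- jaccard_similarity(a, b)
      expect_identical(s, jaccard_similarity(b, a))
      expect_true(s >= 0 && s <= 1)
      expect_equal(jaccard_similarity(a, a), 1)
    }
  })
})

test_that("reference-user lookup maximizes similarity with deterministic ties", {
  hist5 <- tibble::tibble(day = 1:5, dish_id = paste0("d", 1:5))
  target <- mk_user("t")
  # the only eligible member is returned
  pool1 <- mk_user("p1", history = hist5)
  expect_equal(find_reference_user(target, pool1)$user_id, "p1")

  # argmax over hand-differentiated profiles: p_same shares everything,
  # p_far differs in several dimensions
  pool <- dplyr::bind_rows(
    mk_user("p_far", sex = "male", flavor = "sour", staple = "noodles",
            diseases = "gout", history = hist5),
    mk_user("p_mid", flavor = "light", history = hist5),
    mk_user("p_same", history = hist5))
  best <- find_reference_user(target, pool)
  expect_equal(best$user_id, "p_same")
  expect_equal(attr(best, "similarity"), 1)

  # permutation invariance of the pool
  best2 <- find_reference_user(target, pool[c(3, 1, 2), ])
  expect_equal(best2$user_id, "p_same")

  # similarity ties keep the smallest user id
  tied <- dplyr::bind_rows(mk_user("pb", history = hist5),
                           mk_user("pa", history = hist5))
  expect_equal(find_reference_user(target, tied)$user_id, "pa")

  # insufficient history in the whole pool -> cold-boot error
  short <- mk_user("p1", history = hist5[1:3, ])
  expect_error(find_reference_user(target, short),
               class = "eldermeal_coldboot_error")
})

test_that("frequent dishes rank by count with id tie-breaks", {
  h <- tibble::tibble(
    day = c(1, 1, 1, 2, 2, 3, 3, 4),
    dish_id = c("d1", "d2", "d3", "d1", "d3", "d1", "d1", "d2"))
  u <- mk_user(history = h)
  top <- frequent_dishes(u, k = 2)
  expect_equal(top$dish_id, c("d1", "d2"))
  expect_equal(top$n_selected, c(4L, 2L))

  # one combo of three dishes, k = 5: all three with count 1
  u1 <- mk_user(history = tibble::tibble(day = 1, dish_id = c("a", "b", "c")))
  f1 <- frequent_dishes(u1, 5)
  expect_equal(nrow(f1), 3)
  expect_true(all(f1$n_selected == 1))

  # empty history yields an empty ranking (cold-boot route)
  expect_equal(nrow(frequent_dishes(mk_user(), 5)), 0)
})
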