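test_that("dds counts distinct diversity groups across a day's dishes", {
  w <- small_world(3)
  expect_equal(dds(character(), w$kg), 0L)

  # hand-check one dish against its ingredient categories
  d1 <- w$kg$dishes$dish_id[1]
  cats <- w$kg$ingredients$category_id[
    match(unique(w$kg$recipes$ingredient_id[w$kg$recipes$dish_id == d1]),
          w$kg$ingredients$ingredient_id)]
  grp <- default_dds_groups()[cats]
  expected <- length(setdiff(unique(grp[!is.na(grp)]), "none"))
  expect_equal(dds(d1, w$kg), expected)

  # strict mode rejects unmapped categories
  expect_error(dds(d1, w$kg, groups = c(bogus = "vegetables"),
                   strict = TRUE),
               class = "eldermeal_scoring_error")
})

test_that("dds is bounded, integer, monotone and permutation invariant", {
  w <- default_world()
  ids <- w$kg$dishes$dish_id
  withr::with_seed(8, {
    for (k in 1:40) {
      sel <- sample(ids, sample(1:6, 1))
      v <- dds(sel, w$kg)
      expect_true(v >= 0 && v <= 9 && v == as.integer(v))
      # permutation invariance
      expect_identical(dds(rev(sel), w$kg), v)
      # adding a dish never decreases the score
      extra <- sample(setdiff(ids, sel), 1)
      expect_gte(dds(c(sel, extra), w$kg), v)
    }
  })
  # a day covering every group scores the maximum of 9
  st <- eldermeal:::world_state(w$kg)
  cover <- character(0)
  for (g in seq_along(colnames(st$dish_group_g))) {
    hit <- which(st$dish_group_g[, g] > 0)
    if (length(hit)) cover <- c(cover, w$kg$dishes$dish_id[hit[1]])
  }
  expect_equal(dds(cover, w$kg), 9L)
})

test_that("the quality index spans its range with piecewise-linear components", {
  spec <- default_quality_spec()
  expect_equal(attr(spec, "total_points"), 110)
  expect_equal(sum(spec$max_points), 110)

  optimal <- setNames((spec$low + spec$high) / 2,
                      paste0(spec$basis, ":", spec$basis_id))
  expect_equal(quality_index(optimal, spec), 110)
  expect_equal(quality_index(setNames(rep(0, nrow(spec)), names(optimal)),
                             spec), sum(spec$max_points[spec$low == 0]))

  # two-component toy spec: one optimal, one zero -> only its points
  toy <- quality_spec(tibble::tibble(
    component = c("veg", "fruit"), basis = "group",
    basis_id = c("vegetables", "fruits"), low = c(100, 100),
    high = c(200, 200), max_points = c(60, 50)), total_points = 110)
  expect_equal(quality_index(c("group:vegetables" = 150,
                               "group:fruits" = 0), toy), 60)
  # linear decay to zero at twice the upper edge
  expect_equal(quality_index(c("group:vegetables" = 300,
                               "group:fruits" = 150), toy),
               60 * (1 - 100 / 200) + 50)
  expect_equal(quality_index(c("group:vegetables" = 400,
                               "group:fruits" = 150), toy), 50)
  # halfway up to the lower edge earns half the points
  expect_equal(quality_index(c("group:vegetables" = 50,
                               "group:fruits" = 150), toy), 30 + 50)

  # malformed spec: points not summing to the total
  expect_error(quality_spec(toy[1, ], total_points = 110),
               class = "eldermeal_validation_error")
  # negative intake rejected
  expect_error(quality_index(c("group:vegetables" = -1), toy),
               class = "eldermeal_validation_error")
})

test_that("quality index stays within bounds on random intakes", {
  spec <- default_quality_spec()
  keys <- paste0(spec$basis, ":", spec$basis_id)
  withr::with_seed(9, {
    for (k in 1:50) {
      x <- setNames(runif(length(keys), 0, 5000), keys)
      q <- quality_index(x, spec)
      expect_true(q >= 0 && q <= 110)
    }
  })
})

test_that("derive_quality_spec calibrates food-group bands to the world", {
  w <- default_world()
  spec <- derive_quality_spec(w$kg)
  expect_s3_class(spec, "quality_spec")
  expect_equal(sum(spec$max_points), 110)
  # calibration is deterministic
  expect_identical(derive_quality_spec(w$kg), spec)
  # group bands moved to world scale where the group is served at all
  veg <- spec[spec$basis_id == "vegetables", ]
  expect_true(veg$low > 0 && veg$high > veg$low)
})

test_that("day_intake aggregates group grams and nutrient totals", {
  w <- small_world(4)
  ids <- w$kg$dishes$dish_id[1:2]
  x <- day_intake(ids, w$kg)
  tot <- colSums(w$kg$matrices$dish_nutrient[ids, , drop = FALSE])
  expect_equal(unname(x[paste0("nutrient:", names(tot))]), unname(tot))
  expect_true(all(x >= 0))
})

test_that("scoring configuration round-trips through the shipped YAML files", {
  g <- read_dds_groups()
  expect_identical(g, default_dds_groups())
  spec <- read_quality_spec()
  expect_equal(as.data.frame(spec), as.data.frame(default_quality_spec()))
  expect_equal(attr(spec, "total_points"), 110)
})
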