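fake_user <- function(id, n_hist = 0) {
  user_profile(id, "female", 70, 60, 24,
               history = if (n_hist > 0) {
                 tibble::tibble(day = seq_len(n_hist), dish_id = "d1")
               } else tibble::tibble(day = integer(), dish_id = character()))
}

test_that("group assignment partitions the cohort at the history threshold", {
  cohort <- dplyr::bind_rows(fake_user("u0", 0), fake_user("u4", 4),
                             fake_user("u5", 5), fake_user("u9", 9))
  ga <- assign_groups(cohort)
  expect_equal(ga$group, c("untracked", "untracked", "tracked", "tracked"))
  expect_equal(sort(unique(ga$group)), c("tracked", "untracked"))

  # the default synthetic cohort reproduces the 34/62 split
  w <- default_world()
  tab <- table(assign_groups(w$cohort)$group)
  expect_equal(unname(tab[["tracked"]]), 34)
  expect_equal(unname(tab[["untracked"]]), 62)
})

test_that("the repeated-measures sample size reproduces the printed values", {
  expect_identical(required_sample_size(delta = 2, sigma = 6, rho = 0.5), 71L)
  # rho = 0 doubles the effective variance term
  expect_identical(required_sample_size(2, 6, 0),
                   as.integer(ceiling(2 * 36 * (qnorm(0.975) + qnorm(0.8))^2 / 4)))
  expect_identical(required_sample_size(2, 6, 0), 142L)
  # quarter scaling in delta
  expect_identical(required_sample_size(4, 6, 0.5), 18L)
  expect_error(required_sample_size(2, 6, 1),
               class = "eldermeal_design_error")

  # monotonicity: decreasing in delta and rho, increasing in sigma and power
  expect_gte(required_sample_size(1.5, 6, 0.5),
             required_sample_size(2, 6, 0.5))
  expect_gte(required_sample_size(2, 6, 0.3),
             required_sample_size(2, 6, 0.5))
  expect_gte(required_sample_size(2, 7, 0.5),
             required_sample_size(2, 6, 0.5))
  expect_gte(required_sample_size(2, 6, 0.5, power = 0.9),
             required_sample_size(2, 6, 0.5, power = 0.8))
})

test_that("attrition inflation follows ceil(n / (1 - rate))", {
  expect_identical(inflate_for_attrition(71, 0.20), 89L)
  expect_identical(inflate_for_attrition(10, 0), 10L)
  expect_identical(inflate_for_attrition(10, 0.5), 20L)
  expect_error(inflate_for_attrition(10, 1),
               class = "eldermeal_error")
})

# build a meal_simulation-shaped object from per-user-day scores
fake_sim <- function(df, policy = "recommended") {
  structure(list(
    selections = tibble::tibble(
      user_id = df$user_id, day = df$day, group = df$group,
      dish_ids = rep(list("d1"), nrow(df)), n_offered = 1L,
      dds = df$dds, quality = df$quality),
    daily = tibble::tibble(), groups = tibble::tibble(),
    policy = policy, seed = 1,
    params = list()), class = "meal_simulation")
}

test_that("outcome comparison reproduces textbook paired and Welch t tests", {
  # paired: per-user means (5,6,7) vs (6,7,9); differences (1,1,2)
  grid <- expand.grid(user_id = c("a", "b", "c"), day = 1)
  rec <- fake_sim(tibble::tibble(user_id = c("a", "b", "c"), day = 1,
                                 group = "tracked", dds = c(6, 7, 9),
                                 quality = c(6, 7, 9)))
  aut <- fake_sim(tibble::tibble(user_id = c("a", "b", "c"), day = 1,
                                 group = "tracked", dds = c(5, 6, 7),
                                 quality = c(5, 6, 7)), "autonomous")
  out <- compare_outcomes(rec, aut)
  tr <- out[out$group == "tracked" & out$indicator == "dds", ]
  expect_equal(tr$t, 4, tolerance = 1e-12)
  expect_equal(tr$df, 2)
  expect_equal(tr$p, 2 * (1 - pt(4, 2)), tolerance = 1e-12)

  # identical vectors give t = 0, p = 1
  same <- compare_outcomes(rec, fake_sim(rec$selections, "autonomous"))
  expect_equal(same$t[same$group == "tracked"], c(0, 0))
  expect_equal(same$p[same$group == "tracked"], c(1, 1))

  # a single tracked user is a statistics error
  one <- fake_sim(tibble::tibble(user_id = "a", day = 1, group = "tracked",
                                 dds = 5, quality = 5))
  expect_error(compare_outcomes(one, fake_sim(one$selections, "autonomous")),
               class = "eldermeal_statistics_error")
})

test_that("the untracked comparison is Welch against tracked autonomous scores", {
  sel_rec <- tibble::tibble(
    user_id = c("t1", "t2", "t3", "u1", "u2"), day = 1,
    group = c("tracked", "tracked", "tracked", "untracked", "untracked"),
    dds = c(6, 7, 9, 5, 8), quality = c(6, 7, 9, 5, 8))
  sel_aut <- tibble::tibble(
    user_id = c("t1", "t2", "t3"), day = 1, group = "tracked",
    dds = c(5, 6, 7), quality = c(5, 6, 7))
  out <- compare_outcomes(fake_sim(sel_rec), fake_sim(sel_aut, "autonomous"))
  un <- out[out$group == "untracked" & out$indicator == "dds", ]
  # hand Welch arithmetic: x = (5,8), y = (5,6,7)
  x <- c(5, 8); y <- c(5, 6, 7)
  se2 <- var(x) / 2 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 2)^2 / 1 + (var(y) / 3)^2 / 2)
  expect_equal(un$t, t_hand, tolerance = 1e-12)
  expect_equal(un$df, df_hand, tolerance = 1e-12)
})

test_that("the simulation is structurally sound and seed-deterministic", {
  w <- small_world(21, n_dishes = 18, n_ingredients = 28, cohort_size = 4)
  sim0 <- run_simulation(w$cohort, w$kg, days = 0, seed = 1)
  expect_equal(nrow(sim0$selections), 0)

  ga <- assign_groups(w$cohort)
  pair <- w$cohort[c(which(ga$group == "tracked")[1],
                     which(ga$group == "untracked")[1]), ]
  sim <- run_simulation(pair, w$kg, days = 3, seed = 5)
  expect_equal(nrow(sim$selections), 6)
  expect_true(all(sim$selections$n_offered <= 5))
  sim2 <- run_simulation(pair, w$kg, days = 3, seed = 5)
  expect_identical(sim$selections, sim2$selections)

  # a different seed changes selections but not the day-1 offer counts
  sim3 <- run_simulation(pair, w$kg, days = 3, seed = 6)
  d1 <- sim$selections$day == 1
  expect_identical(sim$selections$n_offered[d1], sim3$selections$n_offered[d1])

  # weekday restriction keeps 5 of 7 day indices
  simw <- run_simulation(pair, w$kg, days = 7, seed = 5,
                         weekdays_only = TRUE)
  expect_equal(sort(unique(simw$selections$day)), c(1:5))
})

test_that("a prepared context reproduces the direct simulation exactly", {
  w <- small_world(22, n_dishes = 18, n_ingredients = 28, cohort_size = 4)
  cx <- prepare_simulation(w$cohort, w$kg)
  a <- run_simulation(w$cohort, w$kg, days = 4, seed = 3, context = cx)
  b <- run_simulation(w$cohort, w$kg, days = 4, seed = 3)
  expect_identical(a$selections, b$selections)
  expect_identical(a$daily, b$daily)
})

test_that("recommended outcomes dominate autonomous ones on synthetic worlds", {
  # module-scale check of the directional property (the acceptance suite
  # runs the full 96-user x 30-day x 100-seed version)
  w <- default_world()
  cx <- prepare_simulation(w$cohort, w$kg)
  wins_dds <- 0; wins_q <- 0; n_seeds <- 3
  for (s in seq_len(n_seeds)) {
    rec <- run_simulation(w$cohort, w$kg, days = 10, seed = s, context = cx)
    aut <- run_simulation(w$cohort, w$kg, days = 10, seed = s,
                          policy = "autonomous", context = cx)
    pr <- rec$selections[!is.na(rec$selections$dds), ]
    pa <- aut$selections[!is.na(aut$selections$dds), ]
    wins_dds <- wins_dds + (mean(pr$dds) > mean(pa$dds))
    wins_q <- wins_q + (mean(pr$quality) > mean(pa$quality))
  }
  expect_equal(wins_dds, n_seeds)
  expect_equal(wins_q, n_seeds)
})

test_that("tidiers and glance summarize results", {
  w <- small_world(23, n_dishes = 18, n_ingredients = 28, cohort_size = 6)
  rec <- run_simulation(w$cohort, w$kg, days = 3, seed = 2)
  aut <- run_simulation(w$cohort, w$kg, days = 3, seed = 2,
                        policy = "autonomous")
  g <- glance(rec)
  expect_equal(g$n_users, 6)
  expect_equal(g$policy, "recommended")
  cmp <- try(compare_outcomes(rec, aut), silent = TRUE)
  if (!inherits(cmp, "try-error")) {
    td <- tidy(cmp)
    expect_true(all(c("group", "indicator", "t", "df", "p") %in% names(td)))
  }
})
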