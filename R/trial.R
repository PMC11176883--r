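#' Simulated 30-day intervention and statistical evaluation
#'
#' Runs a seeded simulated meal-recommendation intervention over a cohort:
#' each user-day the recommender offers `n_options` combos and the
#' participant takes one uniformly at random; tracked users' histories grow
#' so hot-boot rankings update over time. An autonomous baseline policy
#' (uniform disease-safe template combos, no adequacy ranking) stands in for
#' participants' own selections. Outcomes are compared with a paired t test
#' (tracked group) and a Welch t test (untracked group against the tracked
#' group's autonomous scores), and the companion power calculation uses the
#' repeated-measures sample-size formula.
#'
#' @name trial
NULL

#' Partition a cohort into tracked and untracked groups
#'
#' @param cohort Cohort tibble.
#' @param threshold Minimum number of recorded eating days for the tracked
#'   group (inclusive). Default 5.
#' @return Tibble with columns `user_id`, `history_days`, `group`
#'   (`"tracked"`/`"untracked"`).
#' @export
assign_groups <- function(cohort, threshold = 5) {
  hd <- vapply(seq_len(nrow(cohort)),
               function(i) history_length(cohort[i, ]), integer(1))
  tibble(user_id = cohort$user_id, history_days = hd,
         group = ifelse(hd >= threshold, "tracked", "untracked"))
}

# quality score of combo blocks given precomputed group-gram and nutrient
# totals (spec already meal-scaled)
block_quality <- function(qspec, groups_g, totals) {
  n <- nrow(groups_g)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (i in seq_len(nrow(qspec))) {
    x <- if (qspec$basis[i] == "group") {
      if (qspec$basis_id[i] %in% colnames(groups_g))
        groups_g[, qspec$basis_id[i]] else rep(0, n)
    } else {
      if (qspec$basis_id[i] %in% colnames(totals))
        totals[, qspec$basis_id[i]] else rep(0, n)
    }
    out <- out + component_score(x, qspec$low[i], qspec$high[i],
                                 qspec$max_points[i])
  }
  out
}

#' Precompute the seed-invariant state of a simulated intervention
#'
#' Builds everything [run_simulation()] needs that does not depend on the
#' seed: the indexed world state, the derived (meal-scaled) quality spec,
#' the group assignment, per-user constraint contexts and coverage-lattice
#' blocks, cold-boot reference assignments and baseline selection counts.
#' Reusing one context across many seeded runs (as the power and
#' directional analyses do) avoids repeating this setup; results are
#' identical with or without a supplied context.
#'
#' @inheritParams run_simulation
#' @return A `sim_context` list, to pass as `context` to
#'   [run_simulation()].
#' @export
prepare_simulation <- function(cohort, kg, budget = energy_budget(),
                               groups = default_dds_groups(),
                               quality = NULL,
                               templates = combo_templates(),
                               per_template_cap = 50,
                               tracked_threshold = 5) {
  st <- world_state(kg, groups = groups, templates = templates)
  quality <- quality %||% derive_quality_spec(kg, budget$lunch_fraction)
  qspec <- scale_quality_spec(quality, budget$lunch_fraction)
  ga <- assign_groups(cohort, tracked_threshold)
  n_users <- nrow(cohort)
  ctxs <- lapply(seq_len(n_users), function(i) {
    user_context(st, cohort[i, ], budget)
  })
  # the coverage-lattice block of the enumeration is static per user, so
  # its assembly and constraint assessment are hoisted out of the day loop
  lattices <- if (is.finite(per_template_cap)) {
    lat_n <- per_template_cap - ceiling(per_template_cap * 0.4)
    lapply(ctxs, function(ctx) lattice_block(st, ctx, lat_n))
  }
  counts0 <- lapply(seq_len(n_users), function(i) {
    h <- history_of(cohort[i, ])
    cnt <- integer(st$n_dishes)
    if (nrow(h) > 0) {
      idx <- match(h$dish_id, st$dish_ids)
      tab <- table(idx[!is.na(idx)])
      cnt[as.integer(names(tab))] <- as.integer(tab)
    }
    cnt
  })
  tracked <- ga$group == "tracked"
  # cold-boot users follow their reference user's (possibly growing)
  # history; profiles are encoded once and compared in bulk
  ref_of <- rep(NA_integer_, n_users)
  if (any(!tracked)) {
    if (!any(tracked)) {
      abort("cold boot failed: no tracked user available as reference",
            class = "eldermeal_coldboot_error")
    }
    tokens <- lapply(seq_len(n_users),
                     function(i) encode_profile(cohort[i, ]))
    tr_idx <- which(tracked)
    tr_idx <- tr_idx[order(cohort$user_id[tr_idx])]
    for (i in which(!tracked)) {
      sims <- vapply(tr_idx, function(j) {
        set_jaccard(tokens[[i]], tokens[[j]])
      }, numeric(1))
      ref_of[i] <- tr_idx[which.max(sims)]
    }
  }
  structure(list(st = st, qspec = qspec, ga = ga, ctxs = ctxs,
                 lattices = lattices, counts0 = counts0, tracked = tracked,
                 ref_of = ref_of), class = "sim_context")
}

#' Run the simulated intervention
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param kg A `food_kg`.
#' @param days Number of recommendation days. Default 30; with
#'   `weekdays_only = TRUE` weekend day indices are dropped (22 of 30).
#' @param n_options Combos offered per user-day. Default 5.
#' @param seed Integer seed driving every random selection.
#' @param budget An [energy_budget()].
#' @param policy `"recommended"` runs the full recommendation pipeline;
#'   `"autonomous"` simulates independent choices -- one uniform
#'   template-valid combo over the user's disease-safe dishes per day,
#'   ignoring nutritional constraints and adequacy ranking.
#' @param groups Diversity-group mapping for scoring.
#' @param quality Daily `quality_spec`, scored against meal-scaled bands
#'   (`lunch_fraction` of the budget); `NULL` (default) derives a
#'   world-consistent spec from the graph via [derive_quality_spec()].
#' @param templates,per_template_cap,k_frequent Recommender settings.
#' @param tracked_threshold Tracked-group history threshold. Default 5.
#' @param weekdays_only Restrict to weekday indices. Default `FALSE`.
#' @param context Optional `sim_context` from [prepare_simulation()]; when
#'   supplied, its settings take precedence over the matching arguments.
#' @return A `meal_simulation` object: `selections` (one row per user-day
#'   with the selected combo's dishes, DDS and quality index), `daily`
#'   (per-day means with normal-approximation 95\% CIs across that day's
#'   offered options, by group), `groups`, `policy`, `seed`, `params`.
#' @export
run_simulation <- function(cohort, kg, days = 30, n_options = 5, seed = 1,
                           budget = energy_budget(),
                           policy = c("recommended", "autonomous"),
                           groups = default_dds_groups(), quality = NULL,
                           templates = combo_templates(),
                           per_template_cap = 50, tracked_threshold = 5,
                           k_frequent = 10L, weekdays_only = FALSE,
                           context = NULL) {
  policy <- match.arg(policy)
  cx <- context %||% prepare_simulation(
    cohort, kg, budget = budget, groups = groups, quality = quality,
    templates = templates, per_template_cap = per_template_cap,
    tracked_threshold = tracked_threshold)
  st <- cx$st
  qspec <- cx$qspec
  ga <- cx$ga
  ctxs <- cx$ctxs
  lattices <- cx$lattices
  tracked <- cx$tracked
  ref_of <- cx$ref_of
  n_users <- nrow(cohort)
  day_idx <- seq_len(days)
  if (weekdays_only) day_idx <- day_idx[((day_idx - 1) %% 7) < 5]
  # selection counts per user (dish index -> count), grown during the run
  # for tracked users so their preference centroids update
  counts <- lapply(cx$counts0, identity)

  n_rec <- length(day_idx) * n_users
  sel_user <- character(n_rec); sel_day <- integer(n_rec)
  sel_dishes <- vector("list", n_rec)
  sel_dds <- rep(NA_real_, n_rec); sel_q <- rep(NA_real_, n_rec)
  sel_noff <- integer(n_rec)
  off_day <- list(); off_dds <- list(); off_q <- list(); off_grp <- list()

  # single-combo quality scorer over plain numeric vectors (precomputed
  # column maps; avoids per-draw matrix construction)
  q_is_group <- qspec$basis == "group"
  q_gi <- match(qspec$basis_id, colnames(st$dish_group_g))
  q_ti <- match(qspec$basis_id, colnames(st$DN))
  score_quality <- function(gg, tt) {
    x <- ifelse(q_is_group, gg[q_gi], tt[q_ti])
    x[is.na(x)] <- 0
    sum(component_score(x, qspec$low, qspec$high, qspec$max_points))
  }

  centroid_for <- function(i) {
    src <- if (tracked[i]) i else ref_of[i]
    cnt <- counts[[src]]
    nz <- which(cnt > 0)
    if (length(nz) == 0) return(NULL)
    top <- nz[order(-cnt[nz], nz)][seq_len(min(k_frequent, length(nz)))]
    as.numeric(crossprod(st$DI[top, , drop = FALSE], cnt[top]) / sum(cnt[top]))
  }

  with_seed(seed, {
    r <- 0L
    for (d in day_idx) {
      day_dds <- numeric(0); day_q <- numeric(0); day_grp <- character(0)
      for (i in seq_len(n_users)) {
        r <- r + 1L
        sel_user[r] <- cohort$user_id[i]; sel_day[r] <- d
        if (policy == "recommended") {
          res <- pipeline_core(st, ctxs[[i]], centroid_for(i), n_options,
                               per_template_cap,
                               lattice = if (!is.null(lattices)) lattices[[i]])
          no <- length(res$offered)
          sel_noff[r] <- no
          if (no == 0) { sel_dishes[r] <- list(character(0)); next }
          o_dds <- st$popcnt[res$combos$mask[res$offered] + 1]
          o_q <- block_quality(qspec,
                               res$combos$groups_g[res$offered, , drop = FALSE],
                               res$combos$totals[res$offered, , drop = FALSE])
          pick <- res$offered[sample.int(no, 1)]
          k <- match(pick, res$offered)
          ids <- res$combos$ids[pick, ]
          ids <- ids[!is.na(ids)]
          sel_dishes[r] <- list(st$dish_ids[ids])
          sel_dds[r] <- o_dds[k]; sel_q[r] <- o_q[k]
          if (tracked[i]) counts[[i]][ids] <- counts[[i]][ids] + 1L
          day_dds <- c(day_dds, o_dds); day_q <- c(day_q, o_q)
          day_grp <- c(day_grp, rep(ga$group[i], no))
        } else {
          # autonomous choice: 2-4 dishes drawn uniformly from the user's
          # disease-safe dishes, with no template structure, constraint
          # assessment or adequacy ranking
          safe <- ctxs[[i]]$safe
          ids <- if (length(safe) >= 2) {
            resample(safe, min(resample(2:4), length(safe)))
          }
          sel_noff[r] <- if (is.null(ids)) 0L else 1L
          if (is.null(ids)) { sel_dishes[r] <- list(character(0)); next }
          sel_dishes[r] <- list(st$dish_ids[ids])
          mask <- Reduce(bitwOr, st$dish_mask[ids], 0L)
          sel_dds[r] <- st$popcnt[mask + 1]
          sel_q[r] <- score_quality(
            colSums(st$dish_group_g[ids, , drop = FALSE]),
            colSums(st$DN[ids, , drop = FALSE]))
          day_dds <- c(day_dds, sel_dds[r]); day_q <- c(day_q, sel_q[r])
          day_grp <- c(day_grp, ga$group[i])
        }
      }
      off_day[[length(off_day) + 1]] <- rep(d, length(day_dds))
      off_dds[[length(off_dds) + 1]] <- day_dds
      off_q[[length(off_q) + 1]] <- day_q
      off_grp[[length(off_grp) + 1]] <- day_grp
    }
  })

  selections <- tibble(user_id = sel_user, day = sel_day,
                       group = ga$group[match(sel_user, ga$user_id)],
                       dish_ids = sel_dishes, n_offered = sel_noff,
                       dds = sel_dds, quality = sel_q)
  offered <- tibble(day = unlist(off_day) %||% integer(),
                    group = unlist(off_grp) %||% character(),
                    dds = unlist(off_dds) %||% double(),
                    quality = unlist(off_q) %||% double())
  daily <- offered %>%
    tidyr::pivot_longer(c("dds", "quality"), names_to = "indicator") %>%
    group_by(.data$day, .data$group, .data$indicator) %>%
    summarise(mean = mean(.data$value),
              ci_lo = mean(.data$value) -
                1.96 * sd(.data$value) / sqrt(dplyr::n()),
              ci_hi = mean(.data$value) +
                1.96 * sd(.data$value) / sqrt(dplyr::n()),
              n = dplyr::n(), .groups = "drop")
  structure(list(selections = selections, daily = daily, groups = ga,
                 policy = policy, seed = seed,
                 params = list(days = days, n_options = n_options,
                               weekdays_only = weekdays_only,
                               lunch_fraction = budget$lunch_fraction)),
            class = "meal_simulation")
}

#' @export
print.meal_simulation <- function(x, ...) {
  cat(sprintf("<meal_simulation> policy=%s seed=%d: %d users x %d days\n",
              x$policy, x$seed, dplyr::n_distinct(x$selections$user_id),
              dplyr::n_distinct(x$selections$day)))
  ok <- !is.na(x$selections$dds)
  cat(sprintf("  mean DDS %.2f | mean quality %.2f | infeasible user-days %d\n",
              mean(x$selections$dds[ok]), mean(x$selections$quality[ok]),
              sum(!ok)))
  invisible(x)
}

per_user_means <- function(sim) {
  sim$selections %>%
    filter(!is.na(.data$dds)) %>%
    group_by(.data$user_id, .data$group) %>%
    summarise(dds = mean(.data$dds), quality = mean(.data$quality),
              .groups = "drop")
}

#' Compare recommended against autonomous outcomes
#'
#' Produces the group-by-indicator comparison table: for the tracked group a
#' paired two-tailed t test of per-user mean scores (recommended vs
#' autonomous); for the untracked group a Welch independent t test of the
#' untracked users' recommended means against the tracked group's autonomous
#' means (the untracked comparator).
#'
#' @param result A `meal_simulation` run with `policy = "recommended"`.
#' @param baseline A `meal_simulation` run with `policy = "autonomous"` on
#'   the same cohort.
#' @return An `outcome_comparison` tibble with columns `group`, `indicator`,
#'   `autonomous_mean`, `autonomous_sd`, `recommended_mean`,
#'   `recommended_sd`, `t`, `df`, `p`.
#' @export
compare_outcomes <- function(result, baseline) {
  rec <- per_user_means(result)
  aut <- per_user_means(baseline)
  rows <- list()
  for (ind in c("quality", "dds")) {
    r_t <- rec[[ind]][rec$group == "tracked"]
    a_t <- aut[[ind]][match(rec$user_id[rec$group == "tracked"],
                            aut$user_id)]
    keep <- !is.na(a_t)
    r_t <- r_t[keep]; a_t <- a_t[keep]
    if (length(r_t) < 2) {
      abort("tracked group has fewer than 2 users with scores",
            class = "eldermeal_statistics_error")
    }
    d <- r_t - a_t
    if (sd(d) == 0) {
      # degenerate zero-variance differences: identical series give t = 0
      tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- t.test(r_t, a_t, paired = TRUE)
    }
    rows[[length(rows) + 1]] <- tibble(
      group = "tracked", indicator = ind,
      autonomous_mean = mean(a_t), autonomous_sd = sd(a_t),
      recommended_mean = mean(r_t), recommended_sd = sd(r_t),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
    r_u <- rec[[ind]][rec$group == "untracked"]
    if (length(r_u) >= 2) {
      tw <- t.test(r_u, a_t, var.equal = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        group = "untracked", indicator = ind,
        autonomous_mean = mean(a_t), autonomous_sd = sd(a_t),
        recommended_mean = mean(r_u), recommended_sd = sd(r_u),
        t = unname(tw$statistic), df = unname(tw$parameter),
        p = tw$p.value)
    }
  }
  structure(bind_rows(rows), class = c("outcome_comparison",
                                       class(tibble())))
}

#' @export
tidy.outcome_comparison <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.meal_simulation <- function(x, ...) {
  ok <- !is.na(x$selections$dds)
  tibble(policy = x$policy, seed = x$seed,
         n_users = dplyr::n_distinct(x$selections$user_id),
         n_days = dplyr::n_distinct(x$selections$day),
         mean_dds = mean(x$selections$dds[ok]),
         mean_quality = mean(x$selections$quality[ok]),
         infeasible_user_days = sum(!ok))
}

#' Required sample size per arm (repeated-measures design)
#'
#' `n = ceil( 2 * sigma^2 * (1 - rho) * (z_{1-alpha/2} + z_{1-beta})^2 /
#' delta^2 )` -- the repeated-measures formula for detecting a smallest
#' meaningful difference `delta` with within-subject correlation `rho`.
#'
#' @param delta Smallest meaningful difference (score units).
#' @param sigma Common standard deviation (score units).
#' @param rho Within-subject correlation among repeated measures.
#' @param alpha Two-sided type-I error rate. Default 0.05.
#' @param power Target power (1 - beta). Default 0.80.
#' @return Integer sample size per arm.
#' @export
#' @examples
#' required_sample_size(delta = 2, sigma = 6, rho = 0.5)  # 71
required_sample_size <- function(delta, sigma, rho, alpha = 0.05,
                                 power = 0.80) {
  assert_that(delta > 0 && sigma > 0, "delta and sigma must be positive")
  assert_that(alpha > 0 && alpha < 1 && power > 0 && power < 1,
              "alpha and power must lie in (0, 1)")
  assert_that(rho >= 0 && rho <= 1, "rho must lie in [0, 1]")
  if (rho == 1) {
    abort("rho = 1 gives a degenerate design (zero residual variance)",
          class = "eldermeal_design_error")
  }
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  as.integer(ceil_safe(2 * sigma^2 * (1 - rho) * z^2 / delta^2))
}

#' Inflate a sample size for expected attrition
#'
#' @param n Computed sample size.
#' @param rate Expected attrition fraction in `[0, 1)`.
#' @return Integer `ceil(n / (1 - rate))`.
#' @export
#' @examples
#' inflate_for_attrition(71, 0.20)  # 89
inflate_for_attrition <- function(n, rate) {
  assert_that(rate >= 0 && rate < 1, "attrition rate must lie in [0, 1)")
  as.integer(ceil_safe(n / (1 - rate)))
}
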