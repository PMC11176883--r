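#' Two-stage personalized combo-meal recommendation
#'
#' The pipeline mirrors a dual-stage design: candidate dish generation
#' (disease-based filtering then preference reranking under a hot- or
#' cold-boot regime) followed by combo meal recommendation (template
#' assembly, nutritional-constraint assessment and nutrient-adequacy
#' ranking).
#'
#' @name recommender
NULL

# ---- internal world state ---------------------------------------------------

# precomputes index structures over a built graph so the per-user-day
# pipeline runs on integer indices and dense matrices only
world_state <- function(kg, groups = default_dds_groups(),
                        templates = combo_templates()) {
  dishes <- kg$dishes
  DN <- kg$matrices$dish_nutrient
  DI <- kg$matrices$dish_ingredient
  cat_idx <- lapply(DISH_CATEGORIES, function(cc) {
    which(dishes$dish_category == cc)
  })
  names(cat_idx) <- DISH_CATEGORIES

  nut <- kg$nutrients
  g_lo <- setNames(nut$guideline_low, nut$nutrient_id)
  g_hi <- setNames(nut$guideline_high, nut$nutrient_id)

  cat_grp <- setNames(unname(groups[kg$categories$category_id]) %na% "none",
                      kg$categories$category_id)
  ing_grp <- unname(cat_grp[kg$ingredients$category_id]) %na% "none"
  GN <- DDS_GROUPS
  ind <- matrix(0, nrow(kg$ingredients), length(GN),
                dimnames = list(kg$ingredients$ingredient_id, GN))
  hit <- ing_grp %in% GN
  ind[cbind(which(hit), match(ing_grp[hit], GN))] <- 1
  dish_group_g <- DI %*% ind
  dish_mask <- as.integer((dish_group_g > 0) %*% (2^(seq_along(GN) - 1)))

  cat_levels <- sort(unique(dishes$dish_category))
  dish_cat_idx <- match(dishes$dish_category, cat_levels)
  tpl <- lapply(seq_len(nrow(templates)), function(i) {
    slots <- templates$slots[[i]]
    pair <- length(slots) >= 2 && identical(slots[[1]], slots[[2]])
    list(template_id = templates$template_id[i],
         price_tier = templates$price_tier[i], slots = slots,
         slot_ok = lapply(slots, function(cc) cat_levels %in% cc),
         pair_first = pair)
  })

  list(kg = kg, dish_ids = dishes$dish_id, n_dishes = nrow(dishes),
       dish_cat_idx = dish_cat_idx,
       cat_idx = cat_idx, DN = DN, DI = DI,
       di_norm = sqrt(rowSums(DI^2)),
       guide_lo = g_lo, guide_hi = g_hi,
       guide_any = !(is.na(g_lo) & is.na(g_hi)),
       dish_group_g = dish_group_g, dish_mask = dish_mask,
       popcnt = vapply(0:511, function(x) sum(bitwAnd(x, 2^(0:8)) > 0),
                       numeric(1)),
       templates = tpl)
}

# per-user static context: safe dishes, combined restrict rows, energy window
user_context <- function(st, user, budget) {
  kg <- st$kg
  dis <- diseases_of(user)
  bad <- unique(unlist(st$kg$discouraged[intersect(dis, names(kg$discouraged))],
                       use.names = FALSE))
  safe <- which(!(st$dish_ids %in% bad))

  frac <- resolve_budget(budget %||% energy_budget(), dis)
  lf <- frac$lf

  rr <- kg$rules[kg$rules$disease_id %in% dis &
                   kg$rules$relation == "restrict", , drop = FALSE]
  contrib <- list(); bound <- c(); dir <- c(); label <- c()
  if (nrow(rr) > 0) {
    for (i in seq_len(nrow(rr))) {
      tt <- rr$target_type[i]; tid <- rr$target_id[i]
      v <- switch(tt,
        nutrient = {
          u_rule <- rr$unit[i]
          u_nat <- kg$nutrients$unit[match(tid, kg$nutrients$nutrient_id)]
          st$DN[, tid] * unit_factor(u_nat, u_rule)
        },
        ingredient = st$DI[, tid],
        category = {
          ings <- kg$ingredients$ingredient_id[
            kg$ingredients$category_id == tid]
          rowSums(st$DI[, ings, drop = FALSE])
        },
        abort(paste0("unknown restrict target type '", tt, "'")))
      contrib[[length(contrib) + 1]] <- v
      bound <- c(bound, rr$amount[i] * lf)
      dir <- c(dir, (rr$bound_type[i] %na% "max"))
      label <- c(label, paste0(rr$disease_id[i], ":", tid))
    }
  }
  restr <- if (length(contrib)) do.call(rbind, contrib) else
    matrix(0, 0, st$n_dishes)

  energy <- NULL
  if (!is.null(budget) && budget$energy_nutrient %in% colnames(st$DN)) {
    w <- user$weight_kg
    if (is.null(w) || length(w) != 1 || is.na(w)) {
      abort("energy constraints require the user's weight_kg",
            class = "eldermeal_config_error")
    }
    energy <- list(
      lo = budget$kcal_per_kg_low * w * frac$lf_lo,
      hi = budget$kcal_per_kg_high * w * frac$lf_hi,
      e_col = budget$energy_nutrient,
      f_col = if (budget$fat_nutrient %in% colnames(st$DN))
        budget$fat_nutrient else NULL,
      fat_max = budget$fat_fraction_max,
      fat_kcal = budget$fat_kcal_per_g)
  }
  lo <- ifelse(is.na(st$guide_lo), -Inf, st$guide_lo * lf)
  hi <- ifelse(is.na(st$guide_hi), Inf, st$guide_hi * lf)
  adq_cols <- which(st$guide_any)
  list(safe = safe, restr = restr, restr_bound = bound, restr_dir = dir,
       restr_label = label, energy = energy, lf = lf, diseases = dis,
       adq_cols = adq_cols, adq_lo = lo[adq_cols], adq_hi = hi[adq_cols])
}

# convert an amount expressed in `from` to `to` (mass units only); identical
# units pass through
unit_factor <- function(native, rule) {
  if (is.na(rule) || identical(native, rule)) return(1)
  f <- c(g = 1, mg = 1e-3, ug = 1e-6, "µg" = 1e-6)
  if (!is.na(f[native]) && !is.na(f[rule])) return(unname(f[rule] / f[native]))
  abort(paste0("cannot convert restrict unit '", rule, "' to nutrient unit '",
               native, "'"), class = "eldermeal_validation_error")
}

# ---- rank-ordered combo enumeration ----------------------------------------

# full cross product of truncated position ranges in lexicographic order
# (last column varies fastest)
lex_grid_n <- function(lens) {
  n <- prod(lens)
  out <- matrix(0L, n, length(lens))
  each <- n
  for (j in seq_along(lens)) {
    each <- each %/% lens[j]
    out[, j] <- rep(rep(seq_len(lens[j]), each = each), length.out = n)
  }
  out
}

# enumerate up to `cap` distinct-dish combos of one template over ordered
# slot candidate lists, in rank-sum order: combos sorted by the sum of
# their slot positions (best aggregate position first, ties
# lexicographically), so the cap spreads over every slot's leading
# candidates instead of pinning early slots to a single top candidate. An
# infinite cap enumerates exhaustively. `pair_first` marks two leading
# slots drawing from one list (positions strictly increasing to avoid
# mirrored duplicates).
enum_template <- function(slot_lists, cap, pair_first = FALSE) {
  lens <- lengths(slot_lists)
  s <- length(slot_lists)
  if (any(lens == 0L) || (pair_first && lens[1] < 2L)) {
    return(matrix(integer(0), 0, s))
  }
  total <- if (pair_first) {
    choose(lens[1], 2) * prod(lens[-(1:2)], 1)
  } else prod(lens)
  K <- min(cap, total)
  # smallest rank-sum budget whose simplex holds K tuples (doubled for the
  # pair constraint), so the initial grid stays small
  S <- 1L
  need <- if (pair_first) 2 * K else K
  while (choose(S + s, s) < need && S < max(lens)) S <- S + 1L
  repeat {
    trunc <- pmin(lens, S + 1L)
    full <- all(trunc == lens)
    if (full) S <- sum(lens - 1L)  # complete grid: no rank-sum cut-off
    pos <- lex_grid_n(trunc)
    rs <- rowSums(pos) - s
    keep <- rs <= S
    if (pair_first) keep <- keep & pos[, 1] < pos[, 2]
    pos <- pos[keep, , drop = FALSE]
    if (nrow(pos) >= K || full) break
    S <- S * 2L
  }
  pos <- pos[order(rowSums(pos)), , drop = FALSE]  # stable: lex within sums
  pos <- pos[seq_len(min(K, nrow(pos))), , drop = FALSE]
  ids <- pos
  for (j in seq_len(s)) ids[, j] <- slot_lists[[j]][pos[, j]]
  ids
}

# deterministic low-discrepancy enumeration: the k-th combo takes slot j's
# candidate at a Kronecker-sequence position over the full list, so a small
# budget still spans every slot's complete candidate range (full dish
# support) instead of a top-rank prefix
LATTICE_ALPHA <- c(0.6180339887498949, 0.7548776662466927,
                   0.5698402909980532, 0.8566748838545029)

enum_lattice <- function(slot_lists, n, pair_first = FALSE) {
  lens <- lengths(slot_lists)
  s <- length(slot_lists)
  if (any(lens == 0L) || (pair_first && lens[1] < 2L) || n <= 0) {
    return(matrix(integer(0), 0, s))
  }
  k <- seq_len(4L * n + 8L)
  pos <- vapply(seq_len(s), function(j) {
    a <- LATTICE_ALPHA[(j - 1L) %% length(LATTICE_ALPHA) + 1L]
    as.integer(floor(((k * a) %% 1) * lens[j])) + 1L
  }, integer(length(k)))
  if (s == 1L) pos <- matrix(pos, ncol = 1L)
  if (pair_first) {
    sw <- pos[, 1] > pos[, 2]
    pos[sw, 1:2] <- pos[sw, 2:1, drop = FALSE]
    pos <- pos[pos[, 1] < pos[, 2], , drop = FALSE]
  }
  pos <- unique(pos)
  pos <- pos[seq_len(min(n, nrow(pos))), , drop = FALSE]
  ids <- pos
  for (j in seq_len(s)) ids[, j] <- slot_lists[[j]][pos[, j]]
  ids
}

# ---- pipeline core ----------------------------------------------------------

# cosine scores of every dish against a query ingredient-gram vector;
# zero-norm vectors score 0 by definition
cosine_scores <- function(st, centroid) {
  if (is.null(centroid)) return(rep(0, st$n_dishes))
  qn <- sqrt(sum(centroid^2))
  if (qn == 0) return(rep(0, st$n_dishes))
  num <- as.numeric(st$DI %*% centroid)
  den <- st$di_norm * qn
  ifelse(den > 0, num / den, 0)
}

# gram-weighted centroid of a user's frequent dishes (counts as weights)
history_centroid <- function(st, freq) {
  if (nrow(freq) == 0) return(NULL)
  idx <- match(freq$dish_id, st$dish_ids)
  ok <- !is.na(idx)
  if (!any(ok)) return(NULL)
  w <- freq$n_selected[ok]
  as.numeric(crossprod(st$DI[idx[ok], , drop = FALSE], w) / sum(w))
}

# candidate indices ordered by descending score, ties by dish id (== index
# order, dishes are sorted by id)
rank_candidates <- function(safe, scores) {
  safe[order(-scores[safe], safe)]
}

# exact numeric identity key of each combo row: its dish indices sorted
# ascending read as digits base (n_dishes + 1); unique per dish set and
# ordered like the sorted dish-id tuple
combo_key <- function(ids_mat, n_dishes) {
  m <- ids_mat
  m[is.na(m)] <- 0L
  s <- ncol(m)
  if (s >= 2) {
    for (p in seq_len(s - 1)) {
      for (j in seq_len(s - 1)) {
        a <- pmin(m[, j], m[, j + 1])
        m[, j + 1] <- pmax(m[, j], m[, j + 1])
        m[, j] <- a
      }
    }
  }
  b <- as.double(n_dishes + 1)
  key <- rep(0, nrow(m))
  for (j in seq_len(s)) key <- key * b + m[, j]
  key
}

# assemble the block structure (NA-padded slot matrix plus derived per-combo
# quantities) for a list of per-template id matrices
build_block <- function(st, ids_list, tpl_idx) {
  max_slots <- max(vapply(st$templates, function(t) length(t$slots),
                          integer(1)))
  n_each <- vapply(ids_list, nrow, integer(1))
  ids_all <- matrix(NA_integer_, sum(n_each), max_slots)
  at <- 0L
  for (k in seq_along(ids_list)) {
    if (n_each[k] == 0) next
    ids <- ids_list[[k]]
    ids_all[at + seq_len(n_each[k]), seq_len(ncol(ids))] <- ids
    at <- at + n_each[k]
  }
  tpl_all <- rep.int(tpl_idx, n_each)
  n <- nrow(ids_all)
  totals <- matrix(0, n, ncol(st$DN), dimnames = list(NULL, colnames(st$DN)))
  groups_g <- matrix(0, n, ncol(st$dish_group_g),
                     dimnames = list(NULL, colnames(st$dish_group_g)))
  mask <- integer(n)
  nslots <- numeric(n)
  for (j in seq_len(max_slots)) {
    sel <- which(!is.na(ids_all[, j]))
    if (length(sel) == 0) next
    totals[sel, ] <- totals[sel, , drop = FALSE] +
      st$DN[ids_all[sel, j], , drop = FALSE]
    groups_g[sel, ] <- groups_g[sel, , drop = FALSE] +
      st$dish_group_g[ids_all[sel, j], , drop = FALSE]
    mask[sel] <- bitwOr(mask[sel], st$dish_mask[ids_all[sel, j]])
    nslots[sel] <- nslots[sel] + 1
  }
  list(ids = ids_all, tpl = tpl_all, totals = totals, groups_g = groups_g,
       mask = mask, nslots = nslots,
       key = combo_key(ids_all, st$n_dishes))
}

# mean dish score per combo under the day's candidate scores
block_pref <- function(block, scores) {
  n <- nrow(block$ids)
  if (n == 0) return(numeric(0))
  pref <- numeric(n)
  for (j in seq_len(ncol(block$ids))) {
    sel <- which(!is.na(block$ids[, j]))
    if (length(sel)) pref[sel] <- pref[sel] + scores[block$ids[sel, j]]
  }
  pref / pmax(block$nslots, 1)
}

template_slot_lists <- function(st, ti, ord) {
  ci <- st$dish_cat_idx[ord]
  lapply(st$templates[[ti]]$slot_ok, function(ok) ord[ok[ci]])
}

# the preference-guided enumeration region: rank-sum prefixes over the
# day's candidate ranking, per template
pref_region_ids <- function(st, ranked, n_per_template) {
  lapply(seq_along(st$templates), function(ti) {
    t <- st$templates[[ti]]
    ids <- enum_template(template_slot_lists(st, ti, ranked),
                         n_per_template, pair_first = t$pair_first)
    if (t$pair_first && nrow(ids) > 0) {
      sw <- ids[, 1] > ids[, 2]
      if (any(sw)) ids[sw, 1:2] <- ids[sw, 2:1, drop = FALSE]
    }
    ids
  })
}

# the coverage region: a low-discrepancy lattice over the safe candidates
# in canonical dish order; static for a given safe set, so callers cache
# the assembled and assessed block per user
lattice_block <- function(st, ctx, n_per_template) {
  canon <- sort.int(ctx$safe)
  ids_list <- lapply(seq_along(st$templates), function(ti) {
    enum_lattice(template_slot_lists(st, ti, canon), n_per_template,
                 pair_first = st$templates[[ti]]$pair_first)
  })
  block <- build_block(st, ids_list, seq_along(st$templates))
  block$pass <- constraints_pass(st, ctx, block)
  block$adequacy <- adequacy_counts(ctx, block$totals)
  block
}

concat_blocks <- function(a, b) {
  list(ids = rbind(a$ids, b$ids), tpl = c(a$tpl, b$tpl),
       totals = rbind(a$totals, b$totals),
       groups_g = rbind(a$groups_g, b$groups_g),
       mask = c(a$mask, b$mask), nslots = c(a$nslots, b$nslots),
       key = c(a$key, b$key))
}

# merged enumeration (preference region plus coverage lattice) as one
# block, for callers that only need the combo set. Because the pipeline's
# final ranking is adequacy-first (preference only breaks ties), a finite
# per-template budget is split between a preference-guided region
# (rank-sum enumeration over the preference ranking) and a coverage
# region (a deterministic low-discrepancy lattice over the candidates in
# canonical dish order), keeping the capped enumeration an approximation
# of the exhaustive pipeline rather than a preference-local prefix; with
# an infinite cap enumeration is exhaustive over the ranked lists.
# Duplicate dish sets between the regions keep the first (preference) row.
enumerate_core <- function(st, ranked, cap, ctx = NULL) {
  if (is.finite(cap)) {
    pref_n <- ceiling(cap * 0.4)
    blk_p <- build_block(st, pref_region_ids(st, ranked, pref_n),
                         seq_along(st$templates))
    canon_ctx <- ctx %||% list(safe = ranked)
    canon <- sort.int(canon_ctx$safe)
    ids_list <- lapply(seq_along(st$templates), function(ti) {
      enum_lattice(template_slot_lists(st, ti, canon), cap - pref_n,
                   pair_first = st$templates[[ti]]$pair_first)
    })
    blk_l <- build_block(st, ids_list, seq_along(st$templates))
    block <- concat_blocks(blk_p, blk_l)
    keep <- which(!duplicated(block$key))
    block$ids <- block$ids[keep, , drop = FALSE]
    block$tpl <- block$tpl[keep]
    block$totals <- block$totals[keep, , drop = FALSE]
    block$groups_g <- block$groups_g[keep, , drop = FALSE]
    block$mask <- block$mask[keep]
    block$nslots <- block$nslots[keep]
    block$key <- block$key[keep]
    block
  } else {
    ids_list <- lapply(seq_along(st$templates), function(ti) {
      enum_template(template_slot_lists(st, ti, ranked), cap,
                    pair_first = st$templates[[ti]]$pair_first)
    })
    build_block(st, ids_list, seq_along(st$templates))
  }
}

# constraint assessment over an enumerated combo block; returns a logical
# pass vector (violation itemization happens in the public wrapper)
constraints_pass <- function(st, ctx, combos) {
  n <- nrow(combos$ids)
  pass <- rep(TRUE, n)
  if (n == 0) return(pass)
  # discouraged dishes can only appear when callers bypass the safety filter
  if (length(ctx$safe) < st$n_dishes) {
    unsafe <- setdiff(seq_len(st$n_dishes), ctx$safe)
    if (length(unsafe)) {
      hit <- matrix(combos$ids %in% unsafe, nrow = n)
      pass <- pass & rowSums(hit, na.rm = TRUE) == 0
    }
  }
  if (nrow(ctx$restr) > 0) {
    # combo value for restrict r = sum over dishes of contribution
    vals <- matrix(0, n, nrow(ctx$restr))
    for (j in seq_len(ncol(combos$ids))) {
      sel <- !is.na(combos$ids[, j])
      if (!any(sel)) next
      vals[sel, ] <- vals[sel, , drop = FALSE] +
        t(ctx$restr[, combos$ids[sel, j], drop = FALSE])
    }
    for (r in seq_len(nrow(ctx$restr))) {
      ok <- if (ctx$restr_dir[r] == "max") vals[, r] <= ctx$restr_bound[r]
      else vals[, r] >= ctx$restr_bound[r]
      pass <- pass & ok
    }
  }
  if (!is.null(ctx$energy)) {
    e <- combos$totals[, ctx$energy$e_col]
    pass <- pass & e >= ctx$energy$lo & e <= ctx$energy$hi
    if (!is.null(ctx$energy$f_col)) {
      fat_e <- combos$totals[, ctx$energy$f_col] * ctx$energy$fat_kcal
      pass <- pass & (e <= 0 | fat_e / pmax(e, 1e-12) <= ctx$energy$fat_max)
    }
  }
  pass
}

# nutrient-adequacy count: nutrients whose combo total lies within the
# lunch-scaled guideline band; one-sided guidelines count on their open side
adequacy_counts <- function(ctx, totals) {
  if (length(ctx$adq_cols) == 0) return(integer(nrow(totals)))
  tt <- t(totals[, ctx$adq_cols, drop = FALSE])
  as.integer(colSums(tt >= ctx$adq_lo & tt <= ctx$adq_hi))
}

# full pipeline on index structures; returns row indices of offered combos
# plus the enumerated block. `lattice` optionally supplies the user's
# cached coverage block (with `pass` and `adequacy` precomputed), which is
# static across days of a simulation; results are identical with or
# without the cache. Final order: adequacy desc among constraint-passing
# combos, ties by preference desc, then by smallest sorted dish-id tuple;
# duplicate dish sets keep their first (preference-region) occurrence.
pipeline_core <- function(st, ctx, centroid, n_options, cap,
                          lattice = NULL) {
  scores <- cosine_scores(st, centroid)
  ranked <- rank_candidates(ctx$safe, scores)
  if (is.finite(cap)) {
    pref_n <- ceiling(cap * 0.4)
    blk_p <- build_block(st, pref_region_ids(st, ranked, pref_n),
                         seq_along(st$templates))
    blk_l <- lattice %||% lattice_block(st, ctx, cap - pref_n)
    combos <- concat_blocks(blk_p, blk_l)
    pass <- c(constraints_pass(st, ctx, blk_p), blk_l$pass)
    adequacy <- c(adequacy_counts(ctx, blk_p$totals), blk_l$adequacy)
  } else {
    combos <- enumerate_core(st, ranked, cap)
    pass <- constraints_pass(st, ctx, combos)
    adequacy <- adequacy_counts(ctx, combos$totals)
  }
  n <- length(combos$tpl)
  if (n == 0) {
    return(list(combos = combos, offered = integer(0),
                adequacy = integer(0), pref = numeric(0)))
  }
  pref <- block_pref(combos, scores)
  live <- pass & !duplicated(combos$key)
  score <- ifelse(live, adequacy, -1L)
  ord <- order(-score, -pref, combos$key)
  ord <- ord[score[ord] >= 0]
  off <- ord[seq_len(min(n_options, length(ord)))]
  list(combos = combos, offered = off, adequacy = adequacy, pref = pref)
}

# ---- public operations ------------------------------------------------------

#' Dishes not contraindicated by a user's diseases
#'
#' Removes every dish discouraged -- directly or via the category-inheritance
#' inference -- for any of the user's diagnosed diseases.
#'
#' @param user One-row cohort tibble.
#' @param kg A `food_kg`.
#' @return Sorted character vector of safe dish ids.
#' @export
filter_by_disease <- function(user, kg) {
  dis <- intersect(diseases_of(user), names(kg$discouraged))
  bad <- unique(unlist(kg$discouraged[dis], use.names = FALSE))
  sort(setdiff(kg$dishes$dish_id, bad))
}

#' Rank candidate dishes by similarity to a user's frequent dishes (hot boot)
#'
#' Scores each candidate by the cosine similarity between its ingredient-gram
#' vector (over the global ingredient vocabulary) and the gram-weighted
#' centroid of the user's most frequently selected dishes. Zero-norm vectors
#' score 0 by definition.
#'
#' @param user One-row cohort tibble with non-empty eating history.
#' @param candidates Character vector of candidate dish ids.
#' @param kg A `food_kg`.
#' @param k_frequent Number of frequent dishes forming the preference
#'   centroid. Default 10.
#' @return Tibble with columns `dish_id`, `score`, in descending score order
#'   (ties by smallest dish id).
#' @export
cosine_rank <- function(user, candidates, kg, k_frequent = 10L) {
  st <- world_state(kg)
  centroid <- history_centroid(st, frequent_dishes(user, k_frequent))
  scores <- cosine_scores(st, centroid)
  idx <- match(candidates, st$dish_ids)
  if (anyNA(idx)) {
    abort(paste0("candidate dish ", candidates[which(is.na(idx))[1]],
                 " not present in the graph"),
          class = "eldermeal_validation_error")
  }
  ord <- idx[order(-scores[idx], idx)]
  tibble(dish_id = st$dish_ids[ord], score = unname(scores[ord]))
}

#' Rank candidate dishes via a similar user's history (cold boot)
#'
#' For users without sufficient tracked history, identifies the reference
#' pool member with the highest profile Jaccard similarity
#' ([find_reference_user()]) and ranks candidates exactly as
#' [cosine_rank()] would using the reference user's history.
#'
#' @inheritParams cosine_rank
#' @param pool Cohort tibble of potential reference users.
#' @param min_history Eligibility threshold for reference users. Default 5.
#' @return Tibble as in [cosine_rank()].
#' @export
cold_boot_rank <- function(user, pool, candidates, kg, min_history = 5,
                           k_frequent = 10L) {
  ref <- find_reference_user(user, pool, min_history = min_history)
  cosine_rank(ref, candidates, kg, k_frequent = k_frequent)
}

#' Enumerate combo-meal candidates over the six price-tier templates
#'
#' Every returned combo instantiates exactly one template with distinct
#' dishes of the required categories. A finite `per_template_cap` splits
#' each template's budget between combos following the candidate ranking
#' (best aggregate slot ranks first) and a deterministic coverage lattice
#' spanning the whole candidate range, so the downstream adequacy ranking
#' is not confined to a preference-local prefix; an infinite cap
#' enumerates exhaustively.
#'
#' @param candidates Ranked candidate tibble (`dish_id`, optionally `score`),
#'   e.g. from [cosine_rank()].
#' @param kg A `food_kg`.
#' @param templates Template tibble, see [combo_templates()].
#' @param per_template_cap Maximum combos enumerated per template
#'   (default 50; `Inf` enumerates exhaustively).
#' @return Tibble with columns `template_id`, `price_tier`, `dish_ids`
#'   (list-column), `preference_score`, `nutrient_totals`.
#' @export
enumerate_combos <- function(candidates, kg, templates = combo_templates(),
                             per_template_cap = 50) {
  st <- world_state(kg, templates = templates)
  idx <- match(candidates$dish_id, st$dish_ids)
  if (anyNA(idx)) {
    abort("candidate dish ids must resolve against the graph",
          class = "eldermeal_validation_error")
  }
  scores <- rep(0, st$n_dishes)
  if ("score" %in% names(candidates)) scores[idx] <- candidates$score
  combos <- enumerate_core(st, idx, per_template_cap)
  combo_block_to_tibble(st, combos, seq_along(combos$tpl),
                        pref = block_pref(combos, scores))
}

combo_block_to_tibble <- function(st, combos, rows, adequacy = NULL,
                                  pref = NULL) {
  if (is.null(pref)) pref <- rep(0, length(combos$tpl))
  tpl_ids <- vapply(st$templates, `[[`, "", "template_id")
  tiers <- vapply(st$templates, `[[`, "", "price_tier")
  out <- tibble(
    template_id = tpl_ids[combos$tpl[rows]],
    price_tier = tiers[combos$tpl[rows]],
    dish_ids = lapply(rows, function(i) {
      ids <- combos$ids[i, ]
      st$dish_ids[ids[!is.na(ids)]]
    }),
    preference_score = pref[rows],
    nutrient_totals = lapply(rows, function(i) combos$totals[i, ]))
  if (!is.null(adequacy)) out$adequacy_count <- adequacy[rows]
  out
}

#' Assess a combo against disease and guideline constraints
#'
#' A combo fails when (a) it contains a dish discouraged for the user, (b) a
#' restrict bound -- converted from per day to per lunch by the lunch
#' fraction -- is violated, (c) its energy falls outside the user's lunch
#' energy window (`kcal_per_kg * weight`, scaled by the lunch-share window),
#' or (d) its share of energy from fat exceeds the budget's cap. Every
#' violation is itemized.
#'
#' @param combos Combo tibble (rows from [enumerate_combos()] or
#'   [recommend()]).
#' @param user One-row cohort tibble.
#' @param kg A `food_kg`.
#' @param budget An [energy_budget()], or `NULL` to skip energy rules.
#' @return The combo tibble with logical `pass` and list-column `violations`
#'   (character descriptions, empty when passing).
#' @export
check_constraints <- function(combos, user, kg, budget = energy_budget()) {
  st <- world_state(kg)
  ctx <- user_context(st, user, budget)
  n <- nrow(combos)
  pass <- logical(n)
  viols <- vector("list", n)
  for (i in seq_len(n)) {
    ids <- match(combos$dish_ids[[i]], st$dish_ids)
    v <- character(0)
    unsafe <- setdiff(ids, ctx$safe)
    if (length(unsafe) > 0) {
      v <- c(v, paste0("discouraged dish: ",
                       paste(st$dish_ids[unsafe], collapse = ", ")))
    }
    tot <- colSums(st$DN[ids, , drop = FALSE])
    if (nrow(ctx$restr) > 0) {
      vals <- as.numeric(ctx$restr[, ids, drop = FALSE] %*% rep(1, length(ids)))
      for (r in seq_along(vals)) {
        bad <- if (ctx$restr_dir[r] == "max") vals[r] > ctx$restr_bound[r]
        else vals[r] < ctx$restr_bound[r]
        if (bad) {
          v <- c(v, sprintf("restrict %s: %.4g vs %s bound %.4g (per lunch)",
                            ctx$restr_label[r], vals[r], ctx$restr_dir[r],
                            ctx$restr_bound[r]))
        }
      }
    }
    if (!is.null(ctx$energy)) {
      e <- tot[ctx$energy$e_col]
      if (e < ctx$energy$lo || e > ctx$energy$hi) {
        v <- c(v, sprintf("energy %.0f kcal outside lunch window [%.0f, %.0f]",
                          e, ctx$energy$lo, ctx$energy$hi))
      }
      if (!is.null(ctx$energy$f_col) && e > 0) {
        ff <- tot[ctx$energy$f_col] * ctx$energy$fat_kcal / e
        if (ff > ctx$energy$fat_max) {
          v <- c(v, sprintf("fat energy share %.2f exceeds %.2f", ff,
                            ctx$energy$fat_max))
        }
      }
    }
    pass[i] <- length(v) == 0
    viols[[i]] <- v
  }
  combos$pass <- pass
  combos$violations <- viols
  combos
}

#' Rank feasible combos by nutrient adequacy
#'
#' Orders combos by descending adequacy count -- the number of nutrients
#' whose lunch-scaled total lies within its guideline range -- with ties
#' broken by higher preference score, then by the smallest sorted dish-id
#' tuple.
#'
#' @param combos Combo tibble (typically constraint-checked).
#' @param kg A `food_kg`.
#' @param budget An [energy_budget()] (supplies the lunch fraction used to
#'   scale daily guideline ranges).
#' @return The combo tibble with an `adequacy_count` column, reordered.
#' @export
adequacy_rank <- function(combos, kg, budget = energy_budget()) {
  st <- world_state(kg)
  lf <- budget$lunch_fraction
  lo <- ifelse(is.na(st$guide_lo), -Inf, st$guide_lo * lf)
  hi <- ifelse(is.na(st$guide_hi), Inf, st$guide_hi * lf)
  counts <- vapply(seq_len(nrow(combos)), function(i) {
    tot <- combos$nutrient_totals[[i]][names(st$guide_lo)]
    sum((tot >= lo & tot <= hi)[st$guide_any])
  }, numeric(1))
  combos$adequacy_count <- as.integer(counts)
  keys <- vapply(combos$dish_ids, function(x) paste(sort(x), collapse = ","), "")
  combos[order(-combos$adequacy_count, -combos$preference_score, keys), ]
}

#' Recommend top-N combo meals for a user
#'
#' Runs the full pipeline: disease-based dish filtering, preference
#' reranking (hot boot from the user's own history when it has at least
#' `min_history` recorded days, otherwise cold boot via the most similar
#' reference user in `pool`), template-based combo enumeration, nutritional
#' constraint assessment, and nutrient-adequacy ranking, truncated to
#' `n_options`. Deterministic for fixed inputs.
#'
#' @param user One-row cohort tibble.
#' @param kg A `food_kg`.
#' @param pool Cohort tibble used for cold-boot reference lookup (may be
#'   `NULL` for tracked users).
#' @param n_options Number of combos to return. Default 5.
#' @param budget An [energy_budget()], or `NULL` to skip energy rules.
#' @param templates Template tibble, see [combo_templates()].
#' @param per_template_cap Enumeration cap per template. Default 50.
#' @param min_history Tracked-history threshold separating hot from cold
#'   boot. Default 5.
#' @param k_frequent Frequent-dish count for the preference centroid.
#' @return Combo tibble (`option`, `template_id`, `price_tier`, `dish_ids`,
#'   `preference_score`, `nutrient_totals`, `adequacy_count`). When fewer
#'   than `n_options` combos are feasible, returns what exists and records
#'   a warning in `attr(, "warning")`.
#' @export
recommend <- function(user, kg, pool = NULL, n_options = 5,
                      budget = energy_budget(),
                      templates = combo_templates(), per_template_cap = 50,
                      min_history = 5, k_frequent = 10L) {
  st <- world_state(kg, templates = templates)
  ctx <- user_context(st, user, budget)
  centroid <- if (history_length(user) >= min_history) {
    history_centroid(st, frequent_dishes(user, k_frequent))
  } else {
    if (is.null(pool) || nrow(pool) == 0) {
      abort("cold boot failed: user has insufficient history and no pool given",
            class = "eldermeal_coldboot_error")
    }
    ref <- find_reference_user(user, pool, min_history = min_history)
    history_centroid(st, frequent_dishes(ref, k_frequent))
  }
  res <- pipeline_core(st, ctx, centroid, n_options, per_template_cap)
  out <- combo_block_to_tibble(st, res$combos, res$offered,
                               adequacy = res$adequacy, pref = res$pref)
  out <- mutate(out, option = row_number(), .before = 1)
  if (nrow(out) < n_options) {
    msg <- sprintf("only %d feasible combo(s) for user %s (requested %d)",
                   nrow(out), user$user_id, n_options)
    warn(msg)
    attr(out, "warning") <- msg
  }
  out
}
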