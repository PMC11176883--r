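---
title: "Knowledge-graph-based combo-meal recommendation for older adults: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph-based combo-meal recommendation for older adults: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eldermeal` implements a complete pipeline for disease-aware, preference-aware
lunch recommendation in a community-canteen setting for older adults, together
with the evaluation machinery used to study such a system: dietary scoring, a
seeded simulated intervention, and the associated power calculation. This
vignette is the package's own account of the underlying models, the tunable
parameters, and the design decisions taken where the design was genuinely open.

## The food knowledge graph

The knowledge base is a typed directed graph over five entity classes —
dishes, ingredients, ingredient categories, nutrients and diseases — with six
relation types:

* `consist_of` (dish → ingredient, grams per standard portion),
* `belong_to` (ingredient → category),
* `contain` (ingredient → nutrient, amount per 100 g; and, inferred,
  dish → nutrient per portion),
* `discourage`, `restrict`, `recommend` (disease → food entity): hard
  exclusion, quantitative daily bound, and soft positive signal.

Two first-order inference rules close the graph. Dish-level nutrient totals
follow from composition:
if an ingredient contains amount $M$ of a nutrient per 100 g and a dish uses
$P$ grams of that ingredient, the dish contains $Q = \sum_i M_i P_i / 100$ of
the nutrient. Disease-level dish exclusions follow from ingredient
discouragement: a dish is discouraged for a disease when it contains at least
one discouraged ingredient, where an ingredient inherits the discouragement of
its ingredient category (so discouraging, say, organ meats as a category
excludes every dish using any organ-meat ingredient).

Two standardization steps precede graph assembly:

* **Duplicate removal.** Two dishes are duplicates when their names match
  (case-folded) or the Jaccard similarity of their ingredient-id sets reaches
  0.85 (inclusive). Within a duplicate cluster the variant whose exact
  ingredient set occurs most often is kept; ties keep the smallest dish id.
  Jaccard over ingredient-id sets was chosen because ingredient sets are the
  only stated basis for similarity; the threshold is inclusive so a pair at
  exactly 85% merges.
* **Sodium standardization.** Each dish's sodium mass fraction is brought
  into the band 0.8%–1.0% of portion mass by rescaling its seasoning-category
  ingredients. The scale factor solves
  $(b + f\,s)/(M_b + f\,m) = t$ exactly — $b, M_b$ sodium and mass of the
  non-seasoning part, $s, m$ of the seasonings, $t$ the nearest band edge —
  so the portion mass stays equal to the summed composition after the
  adjustment. A dish whose non-seasoning part alone exceeds the band cannot
  be standardized and is reported as an error rather than silently altered.

Restrict bounds are stored per day in the rule's native unit; conversion to a
per-meal bound happens in the recommender (below). The graph serializes to a
single JSON document plus node/edge CSV exports; there is no database server.

## The recommendation pipeline

Recommendation is a two-stage pipeline: candidate dish generation, then combo
meal assembly.

**Stage 1 — candidates.** Dishes discouraged for any of the user's diseases
are removed. The remaining candidates are ranked by preference:

* *Hot boot* (users with at least 5 recorded eating days): each candidate is
  scored by the cosine similarity between its ingredient-gram vector and the
  gram-weighted centroid of the user's most frequently selected dishes
  (default: top 10, weighted by selection counts). Zero-norm vectors score 0.
* *Cold boot* (insufficient history): the reference pool member with the
  highest profile Jaccard similarity is found — profiles are encoded as
  categorical `dimension=value` tokens covering sex, age band (60–64 /
  65–79 / ≥80), BMI band (≤19.9 / 20.0–26.9 / ≥27.0), income band, activity
  level, the four dietary-preference dimensions, and one token per disease —
  and the candidates are ranked exactly as hot boot would rank them using the
  reference's history. Income participates in the encoding by default and can
  be toggled off; whether it should enter similarity is not settled, so the
  choice is exposed rather than fixed.

**Stage 2 — combos.** Combos instantiate one of six fixed price-tiered
templates (from one four-dish high tier down to a two-dish low tier). Each
returned combo uses distinct dishes of the required categories. Combos are
then assessed against the user's constraints and ranked by nutrient adequacy.

*Constraint assessment.* A combo fails when it contains a discouraged dish;
when a restrict bound, scaled from per-day to per-lunch by the lunch fraction,
is violated; when its energy falls outside the personal lunch window
(`kcal_per_kg × weight`, with the per-kg range 20–25 kcal/kg by default,
scaled by the lunch-share window); or when more than 25% of its energy comes
from fat. The default lunch fraction is 0.40, from the 3:4:3 split of daily
energy across three meals; a disease-specific override narrows the window
(diabetes: 30%–35%). Every violation is itemized.

*Adequacy ranking.* The adequacy count of a combo is the number of nutrients
whose total lies within the lunch-scaled guideline range; one-sided guidelines
count on their open side. Adequacy is judged against lunch-scaled ranges
(rather than full daily ranges) because the system recommends a single meal.
Ties are broken by higher preference score — the mean of the member dishes'
similarity scores — then by the smallest sorted dish-id tuple, making the
ranking a deterministic total order.

### Bounded enumeration

Exhaustive combo enumeration is quartic in the per-category candidate counts,
so the per-template enumeration is capped (default 50 combos per template,
configurable; an infinite cap enumerates exhaustively, which the test suite
exercises against a brute-force oracle). Because the final ranking is
adequacy-first — preference only breaks ties — a finite cap has to
approximate the *exhaustive* pipeline, not a preference-local prefix of it.
The budget is therefore split:

* a **preference region** (40% of the cap) enumerates combos in rank-sum
  order over the preference ranking — combos whose dishes have the best
  aggregate ranks come first, ties lexicographically — so the cap spreads
  over every slot's leading candidates;
* a **coverage region** (60%) enumerates a deterministic low-discrepancy
  (Kronecker) lattice over the candidate lists in canonical dish order, so a
  small budget still has full dish support in every slot.

Duplicate dish sets between the regions keep the preference-region row. The
split is the package's reconstruction of an underspecified assembly step; a
pure rank-prefix enumeration was measured to confine the adequacy reranker to
near-duplicates of the top-ranked dishes, which defeats the purpose of
ranking by adequacy.

## Dietary scoring

**Dietary diversity score (DDS).** The count of distinct food groups (0–9;
cereals/tubers, vegetables, fruits, meat, fish/seafood, eggs, dairy,
legumes/nuts, oils/fats) represented by at least one ingredient across the
day's selected combo. The category→group mapping ships as configuration;
categories outside the scheme (seasonings) map to `"none"`. When several
combos are eaten in a day the nonrepetitive count is taken over all of them.

**Quality index.** A guideline-adherence index in the 0–110 form: a component
table (data, not code) lists components with an optimal intake band and a
maximum point value; a component earns full points inside its band, with
linear decay to zero at zero intake and at twice the band's upper edge —
over-consumption is penalized linearly, a symmetric-in-spirit choice made
because the exact published component functions were not available. The
default table has eleven 10-point components following the food-pagoda
groups for Chinese seniors (eight food-group bands, an oil moderation band,
a sodium moderation band, and a daily energy band). `derive_quality_spec()`
recalibrates the food-group bands to a given world's food supply (see below);
the package makes no claim of numerical equivalence to any published index on
real survey data.

## The synthetic world

No food database or cohort is distributed with the package; a seeded
generator produces both, sized to the reference setting: 180 dishes over 112
ingredients in 20 categories, 27 nutrients, 30 diseases, and a 96-person
cohort of which 34 are "tracked" (≥5 recorded eating days). Everything is
deterministic given a seed.

Choices a reader should know about, all fixed at design time:

* **Dishes** concentrate one or two food groups each, as canteen dishes do
  (a stir-fry is meat+vegetable, plain rice is cereal only; staples and soups
  carry no cooking oil); plant-side variety (legumes, fruit, dairy) enters
  through vegan dishes, soups and one-plate meals. Dish compositions are
  rescaled to per-category energy windows chosen so that template combos span
  the 20–25 kcal/kg lunch windows of the cohort's weight range.
* **Nutrient composition** has source structure: each micronutrient's
  per-100 g prior is multiplied by category factors mirroring real food
  composition (vitamin D concentrated in fish, calcium in dairy and soy,
  iodine in marine foods, B1 in pork and whole grains, and so on). This is
  what makes nutrient adequacy reward food-group coverage, as it does under
  real reference intakes.
* **Guideline ranges** mirror how reference intakes are framed:
  micronutrients and protein carry a minimum only, set so that one standard
  portion of a source dish meets it (85% of the median contribution among
  upper-half source dishes) while background levels cannot; sodium and
  cholesterol carry upper bounds from the suitable-combo distribution; energy
  and fat carry no fixed band because both are prescribed per person and
  enforced as constraints. A fixed two-sided band for every nutrient was
  tried and rejected: combos covering many source groups sit in the upper
  tail of *every* source nutrient simultaneously and a two-sided band
  penalizes exactly the meals the guidelines mean to encourage.
* **Disease rules**: every disease carries at least one discourage and one
  restrict relation. The cholesterol bound for dyslipidemia is the canonical
  200 mg/day; other bounds sit at seeded quantiles (70th–95th) of sampled
  suitable-combo totals so that restriction is meaningful but not
  prohibitive. Discourage targets never include staple-critical categories,
  seasonings or oils.
* **Cohort**: ages 60–90 centered near 71, 47% female, heights and BMI in
  the range of older Chinese adults; diseases drawn from a Gaussian copula
  with fixed marginal prevalences (hypertension 0.59, arthritis 0.31,
  diabetes 0.24, a declining tail) and shared-frailty correlation 0.1, which
  yields roughly 38% of members with three or more conditions while keeping
  the marginals exact by construction.
* **Eating histories** are habitual: each tracked user repeatedly draws
  combos from a small taste-centred repertoire (per category, the few dishes
  most similar to a personal seed dish) with price tiers preferred at or
  below their income band. Real canteen logs are repetitive — observed
  autonomous diets in this population cover far fewer distinct dishes than a
  uniform draw would — and hot-boot preference centroids should reflect
  that.

### The autonomous baseline

The simulated intervention compares recommendations against *autonomous*
selection: per user-day, 2–4 dishes drawn uniformly from the user's
disease-safe dishes, with no template structure, constraint assessment or
adequacy ranking. The dish-level formulation matters: a uniform draw over
*template-valid combos* is near-maximally diverse by construction (one dish
per required category), which would make the baseline more diverse than any
real autonomous diet in this population; free dish-level selection reproduces
the observed character of autonomous eating (meals that repeat categories and
skip others).

Passing the directional tests on this synthetic world shows that the
pipeline's machinery — safety filtering, constraint handling, adequacy
ranking — systematically improves diversity and guideline adherence over
unstructured selection *in a world whose food supply has realistic
nutrient-source structure*. It does not show effect sizes for real
populations, real menus or real behavior, all of which are outside what a
synthetic world can establish.

## The simulated intervention and its statistics

`run_simulation()` offers each user 5 combo options per day over 30 days
(a weekdays-only switch restricts to 22 of 30 day indices, since the horizon
is described both as 30 days and as weekday-based); the participant takes one
option uniformly at random from the seeded stream. Tracked users' histories
grow with their selections so hot-boot rankings update over time; untracked
users follow their (possibly growing) reference history. Offered sets are
seed-invariant on day 1; from day 2 onward selections feed back into
preference scores, so strictly only the selections, not the offers, are
guaranteed identical across seeds at the start. Infeasible user-days (no
combo passes the constraints) are logged as skips, not errors.

Outcomes are compared in the two-group layout: a paired two-tailed t test of
per-user mean scores for the tracked group, and a Welch unequal-variance t
test of untracked users' recommended means against the tracked group's
autonomous means (the untracked comparator is the tracked group's autonomous
distribution, taken as a constant reference series rather than day-matched).
Welch's form is used because the reference comparison has unequal group
sizes and variances. Per-day series carry normal-approximation 95%
confidence intervals computed across that day's offered options.

The companion power calculation uses the repeated-measures form

$$ n = \left\lceil \frac{2\sigma^2 (1-\rho)\,(z_{1-\alpha/2} + z_{1-\beta})^2}{\delta^2} \right\rceil $$

with the smallest meaningful difference $\delta$, common SD $\sigma$,
within-subject correlation $\rho$; `inflate_for_attrition()` divides by one
minus the expected drop-out rate and rounds up. With $\delta = 2$,
$\sigma = 6$, $\rho = 0.5$, $\alpha = 0.05$ and power 0.80 this gives 71 per
arm, and 89 after 20% attrition.

## Numerical choices and degenerate inputs

* Ties everywhere are broken deterministically (smallest id, smallest sorted
  dish tuple), so all pipelines are reproducible bit-for-bit for fixed
  inputs and seed.
* The paired t statistic of two identical series is reported as 0 with
  p = 1 (the textbook limit) instead of the 0/0 form.
* Jaccard similarity of two empty sets, rank-0 worlds (no dishes of some
  category), dishes that cannot reach the sodium band, and cohorts with no
  tracked reference user all raise typed conditions rather than returning
  silent defaults.
* Problem sizes in the test suite: module tests run on worlds of roughly
  11–18 dishes; the safety property sweeps 1,000 such worlds; the
  directional property runs the full 96-user × 30-day × 100-seed design,
  reusing a precomputed simulation context across seeds.

## Command-line interface

The functions are the primary interface. A thin umbrella script
(`inst/cli/eldermeal`; run `system.file("cli", "eldermeal", package =
"eldermeal")` to locate it) exposes `synth`, `build-kg`, `recommend`,
`simulate`, `score` and `power` subcommands over the exported functions for
shell use.

## Known limitations

* The quality index's component table is a configurable stand-in in the
  published index's *form* (0–110, food-pagoda components); its default
  values are not the published table.
* Cold-boot quality depends entirely on profile similarity; with few tracked
  users the reference assignment is coarse.
* The synthetic generator emulates structure (source-concentrated nutrients,
  template combos, habitual histories, multimorbidity clustering), not any
  real menu or population; absolute score levels in the simulation are not
  comparable to survey values.
* Restrict bounds support `max` and `min` directions, but the shipped
  synthetic rules only exercise `max`; range bounds are expressed as a pair
  of rows.
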