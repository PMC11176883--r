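# internal helpers shared across modules

# stopifnot-style assertion with a typed condition
assert_that <- function(ok, msg, class = "eldermeal_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# Jaccard index of two id vectors (treated as sets). Both empty -> error.
set_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) abort("Jaccard similarity is undefined for two empty sets.",
                     class = "eldermeal_error")
  length(intersect(a, b)) / u
}

# deterministic RNG scope: runs `expr` under `seed` and restores the prior
# RNG state so callers' streams are never perturbed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a distinct child seed from a base seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629
}

# ceiling that tolerates floating noise at integer boundaries
ceil_safe <- function(x, eps = 1e-9) ceiling(x - eps)

`%na%` <- function(x, y) ifelse(is.na(x), y, x)

# sample that never treats a length-1 vector as 1:n
resample <- function(x, size = 1) x[sample.int(length(x), size)]
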