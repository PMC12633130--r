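# Shared fixtures: the default schema and small generated cohorts are
# cached per test run so individual tests stay fast.

.fixture_env <- new.env(parent = emptyenv())

test_schema <- function() {
  if (is.null(.fixture_env$schema)) .fixture_env$schema <- default_schema()
  .fixture_env$schema
}

test_params <- function() {
  if (is.null(.fixture_env$params)) {
    .fixture_env$params <- default_params(test_schema())
  }
  .fixture_env$params
}

# A small default-parameter cohort with planted truth (n = 200, seed 101).
test_cohort <- function() {
  if (is.null(.fixture_env$gen)) {
    .fixture_env$gen <- generate_cohort(test_params(), 200, seed = 101)
  }
  .fixture_env$gen
}

# Exhaustive minimum-cost permutation matching: the independent transport
# oracle for W1 between equal-size samples (n <= 6). For unequal sizes the
# samples are replicated to the least common multiple first (which leaves
# the empirical distributions unchanged) and matched after sorting.
oracle_w1 <- function(a, b) {
  if (length(a) == length(b) && length(a) <= 6) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      }
      out
    }
    return(min(vapply(perms(b), function(p) mean(abs(a - p)), numeric(1))))
  }
  l <- (length(a) * length(b)) / pracma_gcd(length(a), length(b))
  aa <- sort(rep(sort(a), each = l / length(a)))
  bb <- sort(rep(sort(b), each = l / length(b)))
  mean(abs(aa - bb))
}

pracma_gcd <- function(x, y) if (y == 0) x else pracma_gcd(y, x %% y)
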