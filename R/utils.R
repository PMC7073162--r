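# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`; the caller's
# global .Random.seed is restored on exit, so generators never leak state.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Normalize identifiers: trim whitespace and case-fold. Names are joined
# across heterogeneous sources, so "Breast Cancer " and "breast cancer"
# must collapse to one id.
normalize_ids <- function(x, normalize = TRUE) {
  x <- as.character(x)
  if (!normalize) return(x)
  tolower(trimws(x))
}

check_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

# Nearest-match suggestions for misspelled ids in error messages.
suggest_ids <- function(id, candidates, n = 3L) {
  d <- utils::adist(id, candidates, ignore.case = TRUE)
  paste(candidates[order(d)][seq_len(min(n, length(candidates)))],
        collapse = ", ")
}
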