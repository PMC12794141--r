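#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map_lgl imap pmap walk
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# Deterministic 31-bit polynomial hash of a string, for per-record RNG
# streams that do not shift when unrelated records are added.
stable_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a child seed below 2^31 from a master seed and a string tag.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 + as.numeric(stable_hash(tag))) %% 2147483647)
}

assert_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must be finite (got %s)", what,
                  paste(utils::head(x[!is.finite(x)], 3), collapse = ", ")))
  }
  invisible(x)
}
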