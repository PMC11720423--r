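#' @keywords internal
"_PACKAGE"

## Internal validation helpers -------------------------------------------

stop_digera <- function(..., class = "digera_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, what = deparse(substitute(x))) {
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    stop_digera(what, " contains non-finite values at index ",
                paste(utils::head(bad, 5L), collapse = ", "),
                class = "digera_validation_error")
  }
  invisible(x)
}

assert_scalar_number <- function(x, what = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_digera(what, " must be a single finite number",
                class = "digera_validation_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 31-bit integer hashing.  All arithmetic stays below 2^53
## so double precision is exact; used by the hashed fingerprints and the
## fallback embedding provider.
HASH_MOD <- 2147483647  # 2^31 - 1

hash_ints <- function(v, seed = 17) {
  h <- seed
  for (x in v) {
    h <- (h * 31 + (x %% HASH_MOD)) %% HASH_MOD
  }
  h
}

hash_string <- function(s, seed = 17) {
  hash_ints(utf8ToInt(s), seed = seed)
}

## Seeded RNG scope that restores the caller's RNG state.
with_seed <- function(seed, code) {
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
  code
}
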