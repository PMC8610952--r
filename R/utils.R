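#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop with the offending field name, used by config validators
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (x < lower || x > upper)
    abort_field(field, sprintf("must be in [%s, %s]", lower, upper))
  if (integer && x != round(x))
    abort_field(field, "must be an integer")
  invisible(x)
}

## seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a reproducible child seed (< 2^31) from a parent seed and a tag
child_seed <- function(seed, tag) {
  (as.double(seed) * 69069 + sum(utf8ToInt(tag)) * 2654435761) %% 2147483647
}
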