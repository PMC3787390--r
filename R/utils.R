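# internal helpers

#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (caller controls randomness).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict && x <= min)
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict && x < min)
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  invisible(x)
}
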