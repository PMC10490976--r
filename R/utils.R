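# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a private RNG state: seeds reproducibly without
# disturbing the caller's random stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# axis angles live on the 180-degree circle
wrap_axis <- function(a) a %% 180

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) stop_invalid("'%s' must be numeric", name)
  if (finite && any(!is.finite(x)))
    stop_invalid("'%s' contains non-finite values", name)
  invisible(x)
}
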