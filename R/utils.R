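# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded sampling inside the
#' package never disturbs the caller's RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Relative residual |lhs - rhs| / (1 + |lhs|), reduced over components.
rel_residual <- function(lhs, rhs) {
  if (length(lhs) != length(rhs)) return(Inf)
  max(abs(lhs - rhs) / (1 + abs(lhs)))
}

# Derive a valid 32-bit sub-seed from a base seed and a stream index.
sub_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 1000003 + as.numeric(k)) %% 2147483647)
}

stop_fd <- function(...) stop(..., call. = FALSE)

fmt_num <- function(x) paste(format(x, digits = 6), collapse = ", ")
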