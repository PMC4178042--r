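# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_pos <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0)
    stopf("`%s` must be a single positive finite number", name)
  invisible(x)
}

#' Evaluate an expression with a private RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# round-half-up, used for 8-bit channel quantisation (bit-exact testability)
round_half_up <- function(x) floor(x + 0.5)

# md5 of an in-memory character scalar (run-log config hash)
md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(x, f)
  unname(tools::md5sum(f))
}
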