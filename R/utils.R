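# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` uses the current stream (non-reproducible).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_param("`%s` must be strictly positive and finite", name)
  invisible(x)
}

# Named-list merge with strict key checking: keys of `user` not present in
# `defaults` are rejected (guards against silently ignored typos).
merge_config <- function(defaults, user, where = "config") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop_param("`%s` must be a named list", where)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop_param("unknown key(s) in %s: %s", where,
               paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

# Fraction-based log line used by the localization pipeline.
log_stage <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
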