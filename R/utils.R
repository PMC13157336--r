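`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded helpers do not perturb the global random stream. A `NULL`
#' seed evaluates `expr` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("priorelicit_domain_error", "error")))
}

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(name, " must be a single finite number")
  }
  if (open && (x <= 0 || x >= 1)) {
    stop_domain(name, " must lie strictly inside (0, 1); got ", format(x))
  }
  if (!open && (x < 0 || x > 1)) {
    stop_domain(name, " must lie in [0, 1]; got ", format(x))
  }
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain(name, " must be a single positive finite number")
  }
  x
}
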