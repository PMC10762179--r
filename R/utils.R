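#' @keywords internal
"_PACKAGE"

# Shared internal helpers: seeded evaluation, boundary reflection, small
# validation utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#'
#' All stochastic simulator code runs through this so that a `SceneSpec`
#' seed fixes output bit-exactly without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Symmetric boundary reflection of 1-based positions onto 1..n
# (edge pixel duplicated: ... c b a | a b c ...). Vectorised; handles
# positions arbitrarily far outside the range.
reflect_index <- function(p, n) {
  if (n == 1L) return(rep(1L, length(p)))
  q <- (p - 1L) %% (2L * n)
  q <- ifelse(q < 0L, q + 2L * n, q)
  as.integer(ifelse(q < n, q + 1L, 2L * n - q))
}

stop_lq <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_lq(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) stop_lq(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) stop_lq(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x)) stop_lq(sprintf("`%s` must be a matrix", name))
  invisible(x)
}

# logical foreground matrix from either a channel_mask or a plain matrix
as_mask_matrix <- function(m) {
  if (inherits(m, "channel_mask")) return(m$mask)
  if (is.matrix(m) && is.logical(m)) return(m)
  if (is.matrix(m) && is.numeric(m)) return(m != 0)
  stop_lq("expected a channel_mask or a logical matrix")
}

# Derive a reproducible child seed below 2^31 from a base seed and an index.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 2654435) %% 2147483647)
}
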