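# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
normalize_id <- function(x) tolower(trimws(x))

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sum rows of `msg` (m x d) into an n x d matrix by integer group `index`.
# Groups absent from `index` get zero rows.
agg_rows <- function(msg, index, n) {
  r <- rowsum(msg, group = index, reorder = TRUE)
  out <- matrix(0, n, ncol(msg))
  out[as.integer(rownames(r)), ] <- r
  out
}

# Sum scalar vector `x` into length-n vector by group `index`.
agg_vec <- function(x, index, n) {
  r <- rowsum(matrix(x, ncol = 1L), group = index, reorder = TRUE)
  out <- numeric(n)
  out[as.integer(rownames(r))] <- r[, 1L]
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
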