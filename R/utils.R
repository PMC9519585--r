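#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join across
#' @importFrom purrr map map_dbl map2 pmap imap
#' @importFrom stats cor prcomp cmdscale sd var qt pt qf pf ptukey rnorm runif
#'   median quantile setNames aggregate
NULL

# pairwise squared Euclidean distances between rows of X (dense, n x n)
sq_dists <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# derive a stream-specific child seed; keeps results < 2^31
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 104729) %% 2147483629
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# column-standardized copy used before correlation-based matching
check_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) abort(sprintf("`%s` must be a numeric matrix", name))
  if (anyNA(x) || any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values", name))
  x
}
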