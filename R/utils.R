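# Internal utilities shared across the package.

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators never disturb user code.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
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

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a channels-first 3D feature map
#'
#' A feature map is a dense numeric array indexed `(channel, depth, height,
#' width)`; it is the object every block-level operator transforms.  Plain
#' 4D arrays are accepted everywhere; this helper validates and tags one.
#'
#' @param values Numeric array with `dim` of length 4 (`C, D, H, W`), or a
#'   3D array which is promoted to a single channel.
#' @return The validated array (invisibly classed `feature_map`).
#' @examples
#' x <- feature_map(array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4)))
#' dim(x)
#' @export
feature_map <- function(values) {
  if (is.null(dim(values))) stopf("feature map values must be an array")
  if (length(dim(values)) == 3L) dim(values) <- c(1L, dim(values))
  if (length(dim(values)) != 4L)
    stopf("feature map must have 4 dimensions (C, D, H, W), got %d",
          length(dim(values)))
  if (any(dim(values) < 1L)) stopf("all feature map extents must be >= 1")
  if (!all(is.finite(values))) stopf("feature map values must be finite")
  class(values) <- c("feature_map", class(values))
  values
}

check_feature_map <- function(x, channels = NULL, what = "input") {
  if (is.null(dim(x)) || length(dim(x)) != 4L)
    stopf("%s must be a (C, D, H, W) array", what)
  if (!is.null(channels) && dim(x)[1] != channels)
    stopf("%s has %d channels, expected %d", what, dim(x)[1], channels)
  invisible(x)
}

# channels-first array <-> (C x N) matrix view
as_cmat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  x
}

# truncated normal on [-2sd, 2sd], the transformer-weight initializer
rtruncnorm2 <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2)
  hi <- stats::pnorm(2)
  sd * stats::qnorm(stats::runif(n, lo, hi))
}

# number of elements of a parameter leaf (array or shape stub)
leaf_size <- function(p) {
  if (inherits(p, "param_shape")) prod(unclass(p)) else length(p)
}

param_shape <- function(...) structure(as.integer(c(...)), class = "param_shape")

# sum of all parameter elements in a (possibly nested) list of leaves
tree_size <- function(tree) {
  if (is.null(tree)) return(0)
  if (!is.list(tree)) return(leaf_size(tree))
  sum(vapply(tree, tree_size, numeric(1)))
}

# walk two congruent trees, applying f to leaf pairs (used by the optimizer)
tree_map2 <- function(a, b, f) {
  if (!is.list(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
  out
}

tree_map <- function(a, f) {
  if (!is.list(a)) return(f(a))
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- tree_map(a[[nm]], f)
  out
}

# flatten a parameter tree into a named list of leaves
tree_leaves <- function(tree, prefix = "") {
  if (!is.list(tree)) {
    out <- list(tree)
    names(out) <- prefix
    return(out)
  }
  out <- list()
  nms <- names(tree) %||% as.character(seq_along(tree))
  for (i in seq_along(tree)) {
    child <- tree_leaves(tree[[i]],
                         if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i])
    out <- c(out, child)
  }
  out
}
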