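# Internal helpers shared across modules.

#' @importFrom rlang abort warn `%||%`
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic code in the package funnels
# through this so a single integer seed reproduces a run bit-identically.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %g.", name, min))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %g.", name, min))
  }
  invisible(x)
}

# Disjoint-set forest with path compression; used by the centroid buffer
# merge and by 8-connected component labeling. Environment-based so unions
# persist across calls.
uf_make <- function(n) {
  env <- new.env(parent = emptyenv())
  env$parent <- seq_len(n)
  env
}

uf_root <- function(uf, i) {
  p <- uf$parent
  root <- i
  while (p[root] != root) root <- p[root]
  # path compression
  while (p[i] != root) {
    nxt <- p[i]
    p[i] <- root
    i <- nxt
  }
  uf$parent <- p
  root
}

uf_union <- function(uf, i, j) {
  ri <- uf_root(uf, i)
  rj <- uf_root(uf, j)
  if (ri != rj) uf$parent[rj] <- ri
  invisible(NULL)
}

uf_groups <- function(uf) {
  roots <- vapply(seq_along(uf$parent), function(i) uf_root(uf, i), integer(1))
  match(roots, unique(roots))
}

round_half_up <- function(x) floor(x + 0.5)
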