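# Independent oracles used across the suite. They deliberately share no
# code with the implementation paths they check.

# Exhaustive simplex grid search minimizing the unmixing residual. `step`
# controls the grid pitch over the (k-1)-simplex.
grid_unmix_oracle <- function(pixel, em, step = 1e-3) {
  k <- ncol(em)
  stopifnot(k == 3)  # what the suite needs; keeps the oracle dumb
  f1 <- seq(0, 1, by = step)
  best <- c(NA, NA, NA); best_sse <- Inf
  # vectorize over f2 for each f1
  for (a in f1) {
    b <- seq(0, 1 - a, by = step)
    cvals <- 1 - a - b
    R <- outer(em[, 1], rep(a, length(b))) + outer(em[, 2], b) +
      outer(em[, 3], cvals)
    sse <- colSums((R - pixel)^2)
    i <- which.min(sse)
    if (sse[i] < best_sse) {
      best_sse <- sse[i]
      best <- c(a, b[i], cvals[i])
    }
  }
  best
}

# Dense QP solve of the one-class SVM dual with kernlab::ipop:
#   min 1/2 a'Ka  s.t.  sum(a) = 1, 0 <= a <= 1/(nu l)
ipop_ocsvm_oracle <- function(X, nu, gamma) {
  l <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-gamma * d2)
  res <- kernlab::ipop(
    c = rep(0, l), H = K,
    A = matrix(1, nrow = 1, ncol = l), b = 1, r = 0,
    l = rep(0, l), u = rep(1 / (nu * l), l),
    sigf = 9, maxiter = 200
  )
  kernlab::primal(res)
}

# Brute force over all one-to-one matchings with pair distance <= tol,
# maximizing pair count then minimizing total distance. Recursion over the
# smaller set; fine for <= 8 points per side.
brute_match_oracle <- function(a, b, tol) {
  na <- nrow(a); nb <- nrow(b)
  d <- sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2)
  best <- list(n = -1L, total = Inf)
  recurse <- function(i, used_b, n, total) {
    if (i > na) {
      if (n > best$n || (n == best$n && total < best$total - 1e-12)) {
        best <<- list(n = n, total = total)
      }
      return(invisible())
    }
    # leave a_i unmatched
    recurse(i + 1, used_b, n, total)
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, n + 1L, total + d[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, logical(nb), 0L, 0)
  best
}

# Spread points with pairwise spacing above `min_sep` in a square extent,
# mimicking post-merge crown sets.
spread_points <- function(n, extent, min_sep) {
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < n) {
    p <- stats::runif(2, 0, extent)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - p)^2))) > min_sep) {
      pts <- rbind(pts, p)
    }
  }
  tibble::tibble(id = seq_len(n), x = pts[, 1], y = pts[, 2])
}

tiny_scene_params <- function(...) {
  scene_params(width = 96, height = 96, n_crowns = 8, seed = 42L, ...)
}
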