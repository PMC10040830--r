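# Independent reference implementations used to validate the package's
# fast paths. Plain R against the textbook definitions; no code shared
# with the implementations they check.

# Global affine-gap score by the three-layer recurrence over explicit R
# matrices. rec(i,j,s): best score of aligning a[1..i] with b[1..j] whose
# last column has type s (M = substitution column, X = gap consuming a,
# Y = gap consuming b). A gap of length k costs open + k * ext.
oracle_global_score <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    ii <- i + 1; jj <- j + 1
    if (i > 0 && j > 0)
      M[ii, jj] <- max(M[ii - 1, jj - 1], X[ii - 1, jj - 1],
                       Y[ii - 1, jj - 1]) + mat[A[i], B[j]]
    if (i > 0)
      X[ii, jj] <- max(X[ii - 1, jj] - ext,
                       M[ii - 1, jj] - open - ext,
                       Y[ii - 1, jj] - open - ext)
    if (j > 0)
      Y[ii, jj] <- max(Y[ii, jj - 1] - ext,
                       M[ii, jj - 1] - open - ext,
                       X[ii, jj - 1] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Local score: best global score over all pairs of substrings (the
# definitional characterization of Smith-Waterman), floored at 0.
oracle_local_score <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(A)) for (i2 in i1:length(A))
    for (j1 in seq_along(B)) for (j2 in j1:length(B)) {
      sub_a <- paste(A[i1:i2], collapse = "")
      sub_b <- paste(B[j1:j2], collapse = "")
      best <- max(best, oracle_global_score(sub_a, sub_b, mat, open, ext))
    }
  best
}

# Producibility by explicit path enumeration: every directed path from the
# root to the metabolite, checked edge by edge.
oracle_predictable <- function(present, network) {
  edges <- network$edges
  reqs <- network$requirements
  paths_to <- function(node) {
    if (node == network$root) return(list(integer(0)))
    incoming <- which(edges$product == node)
    out <- list()
    for (e in incoming)
      for (p in paths_to(edges$substrate[e]))
        out[[length(out) + 1]] <- c(p, e)
    out
  }
  ok <- vapply(network$predictable, function(m) {
    any(vapply(paths_to(m), function(p)
      all(vapply(p, function(e) satisfies(reqs[[e]], present), logical(1))),
      logical(1)))
  }, logical(1))
  network$predictable[ok]
}

# Precomputed edge-index paths from the root to every predictable
# metabolite, for exhaustive subset sweeps with the same path-checking
# semantics as oracle_predictable.
oracle_paths <- function(network) {
  edges <- network$edges
  paths_to <- function(node) {
    if (node == network$root) return(list(integer(0)))
    incoming <- which(edges$product == node)
    out <- list()
    for (e in incoming)
      for (p in paths_to(edges$substrate[e]))
        out[[length(out) + 1]] <- c(p, e)
    out
  }
  setNames(lapply(network$predictable, paths_to), network$predictable)
}

oracle_predictable_from_paths <- function(present, network, paths) {
  sat <- vapply(network$requirements, satisfies, logical(1),
                present = present)
  ok <- vapply(paths, function(ps)
    any(vapply(ps, function(p) all(sat[p]), logical(1))), logical(1))
  names(paths)[ok]
}

# Spearman rho by explicit rank-then-Pearson
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# BH step-up by the definitional formula q_(i) = min_{j>=i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(pmin(1, m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact two-sided Mann-Whitney p by enumeration of all label assignments
oracle_mw_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  idx <- combn(na + nb, na)
  ustat <- function(sel) {
    ua <- sum(r[sel]) - na * (na + 1) / 2
    min(ua, na * nb - ua)
  }
  u_obs <- ustat(seq_len(na))
  us <- apply(idx, 2, ustat)
  mean(us <= u_obs + 1e-12)
}

# random unrooted topology with known branch lengths and its additive
# (path-length) distance matrix
random_additive_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  list(tree = tr, d = d[tr$tip.label, tr$tip.label])
}

# random protein-like test sequences over a reduced alphabet
random_reduced_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
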