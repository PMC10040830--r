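#' Pairwise global-identity distance matrix
#'
#' Distance between two homolog sequences is 1 - identity/100 under the
#' affine-gap global alignment of \code{\link{global_identity}}. Used as
#' input to \code{\link{neighbor_joining}}.
#'
#' @param seqs Named character vector of >= 3 protein sequences with unique
#'   ids.
#' @param scoring Scoring scheme.
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
distance_matrix <- function(seqs, scoring = default_scoring()) {
  if (length(seqs) < 3) stop("need at least 3 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique ids")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - global_identity(seqs[[i]], seqs[[j]],
                                              scoring) / 100
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical agglomeration (Saitou-Nei) with the standard Q criterion.
#' Ties in Q are broken by the lowest index pair, so the result is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch, preserving the path length
#' between the joined nodes.
#'
#' @param d Symmetric distance matrix with labels (>= 3 taxa).
#' @return An unrooted tree of class \code{phylo} (\pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(d)
  # each active node carries its newick subtree string
  nwk <- labels
  active <- seq_len(n)
  D <- d
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3) {
    r <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest index pair on ties: scan column-major over upper triangle
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      if (Q[i, j] < bestq - 1e-15) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    # distances from the new node to the remaining taxa
    rest <- active[-c(i, j)]
    newd <- (D[ai, rest] + D[aj, rest] - D[ai, aj]) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, rest] <- newd; D[rest, u] <- newd
    nwk[u] <- sprintf("(%s:%s,%s:%s)", nwk[ai], fmt(li), nwk[aj], fmt(lj))
    active <- c(rest, u)
  }
  # final three nodes joined in a star
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
  lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
  lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[a], fmt(la), nwk[b], fmt(lb),
                 nwk[c3], fmt(lc))
  ape::read.tree(text = txt)
}

# leaf label sets below each edge of an ape tree (child-side)
edge_leaf_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(ntip)) desc[[k]] <- tree$tip.label[k]
  # postorder guarantees children before parents
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2]]])
}

#' Detect species-exclusive clades
#'
#' Enumerates the clades induced by every internal edge of an unrooted tree
#' (both sides of each bipartition) and reports the maximal clades of two
#' or more leaves whose members all carry the same species label. This
#' operationalizes "independently clustered" homolog groups such as the
#' divergent indolelactate dehydrogenase types of \emph{L. salivarius}.
#'
#' @param tree A \code{phylo} tree.
#' @param species_of Named character vector leaf label -> species.
#' @return data.frame \code{species, size, leaves} (comma-separated),
#'   \code{support} (always "no support": branch support is not computed).
#' @export
exclusive_clades <- function(tree, species_of) {
  stopifnot(inherits(tree, "phylo"))
  unlabeled <- setdiff(tree$tip.label, names(species_of))
  if (length(unlabeled))
    stop("unlabeled leaves: ", paste(unlabeled, collapse = ", "))
  all_leaves <- tree$tip.label
  sides <- edge_leaf_sets(tree)
  cands <- unique(c(lapply(sides, sort),
                    lapply(sides, function(s) sort(setdiff(all_leaves, s)))))
  keep <- Filter(function(s) {
    length(s) >= 2 && length(s) < length(all_leaves) &&
      length(unique(species_of[s])) == 1
  }, cands)
  if (length(keep)) {
    maximal <- vapply(seq_along(keep), function(k)
      !any(vapply(seq_along(keep), function(l)
        l != k && all(keep[[k]] %in% keep[[l]]) &&
          length(keep[[l]]) > length(keep[[k]]), logical(1))),
      logical(1))
    keep <- keep[maximal]
    keep <- keep[order(vapply(keep, `[`, "", 1))]
  }
  data.frame(
    species = vapply(keep, function(s) unname(species_of[s[1]]), ""),
    size = vapply(keep, length, 0L),
    leaves = vapply(keep, paste, "", collapse = ","),
    support = rep("no support", length(keep)), stringsAsFactors = FALSE)
}

#' Write a distance matrix in PHYLIP square format
#' @param d Labelled symmetric matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phylip <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.8f", d[i, ])), collapse = "  "), con)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#' @param path Input path.
#' @return Labelled symmetric matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labels <- vapply(parts, `[`, "", 1)
  d <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}
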