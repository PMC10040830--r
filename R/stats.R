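#' Spearman rank correlation with small-sample exact p
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks). For n <= 9 the two-sided p-value is computed by full
#' enumeration of all n! permutations of one rank vector (valid under
#' ties); for larger n the t-approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom is
#' used, as in common statistical software.
#'
#' @param x,y Numeric vectors of equal length n >= 3; neither constant.
#' @return List \code{rho}, \code{p_value}, \code{n}, \code{method}.
#' @examples
#' spearman_assoc(c(1, 2, 2, 4), c(1, 3, 2, 4))
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector: rho undefined")
  rho <- cor(x, y, method = "spearman")
  if (n <= 9) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- permutations_of(n)
    # correlation of rx with every permutation of ry via sum of products
    sp <- perms_sumprod(perms, rx, ry)
    mx <- mean(rx); my <- mean(ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_perm <- (sp - n * mx * my) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin  # degenerate perfect correlation
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- max(2 * pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as an n! x n integer matrix, lexicographic
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

perms_sumprod <- function(perms, rx, ry) {
  ry_mat <- matrix(ry[perms], nrow(perms), ncol(perms))
  as.numeric(ry_mat %*% rx)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} with the input
#' validation the correlation family relies on: every p must lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-count / metabolite-concentration association screen
#'
#' Spearman correlation between every enzyme-family homolog count and every
#' metabolite concentration across strains, with Benjamini-Hochberg FDR
#' across the full family of pairs. An association is reported when
#' |rho| > \code{rho_screen} (strictly) and q < \code{alpha}. Pairs where
#' either vector is constant across strains have no defined rank
#' correlation; they are returned with NA and excluded from the BH family.
#'
#' @param counts Numeric matrix, strains x enzyme families.
#' @param concentrations Numeric matrix, strains x metabolites (ng/mL).
#' @param alpha FDR level (default 0.05).
#' @param rho_screen Minimum absolute correlation to report (default 0.3).
#' @return data.frame \code{enzyme, metabolite, n, rho, p_value, q_value,
#'   reported}.
#' @export
gene_metabolite_correlations <- function(counts, concentrations,
                                         alpha = 0.05, rho_screen = 0.3) {
  counts <- as.matrix(counts)
  concentrations <- as.matrix(concentrations)
  shared <- intersect(rownames(counts), rownames(concentrations))
  if (length(shared) < 3) stop("fewer than 3 shared strains")
  counts <- counts[shared, , drop = FALSE]
  concentrations <- concentrations[shared, , drop = FALSE]
  grid <- expand.grid(enzyme = colnames(counts),
                      metabolite = colnames(concentrations),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    x <- counts[, grid$enzyme[k]]
    y <- concentrations[, grid$metabolite[k]]
    if (length(unique(x)) == 1 || length(unique(y)) == 1)
      return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
    spearman_assoc(x, y)
  })
  out <- data.frame(
    enzyme = grid$enzyme, metabolite = grid$metabolite,
    n = vapply(res, `[[`, 0, "n"),
    rho = vapply(res, `[[`, 0, "rho"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    q_value = NA_real_, reported = FALSE, stringsAsFactors = FALSE)
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out$reported[ok] <- abs(out$rho[ok]) > rho_screen & out$q_value[ok] < alpha
  out
}

#' Mann-Whitney U comparison of two groups
#'
#' U is the smaller of the two rank-sum statistics (mid-ranks under ties).
#' The two-sided p-value is exact (full enumeration of label assignments,
#' via the exact Wilcoxon distribution) when n_a + n_b <= 12 and there are
#' no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections, as in common statistical software.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return List \code{U}, \code{p_value}, \code{n_a}, \code{n_b},
#'   \code{method}.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  Ub <- na * nb - Ua
  ties <- any(duplicated(c(a, b)))
  exact <- (na + nb <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = min(Ua, Ub), p_value = unname(wt$p.value), n_a = na, n_b = nb,
       method = if (exact) "exact" else "normal approximation")
}

#' Within-species source comparisons of metabolite levels
#'
#' For each species with strains from more than one isolation source,
#' compares every metabolite's concentrations between every pair of sources
#' with \code{\link{mann_whitney}}.
#'
#' @param concentrations Numeric matrix, strains x metabolites.
#' @param metadata data.frame with columns \code{strain}, \code{species},
#'   \code{source}.
#' @return data.frame \code{species, metabolite, source_a, source_b, n_a,
#'   n_b, U, p_value}; zero rows when no species is multi-source.
#' @export
source_comparisons <- function(concentrations, metadata) {
  stopifnot(all(c("strain", "species", "source") %in% names(metadata)))
  concentrations <- as.matrix(concentrations)
  out <- list()
  for (sp in unique(metadata$species)) {
    md <- metadata[metadata$species == sp &
                     metadata$strain %in% rownames(concentrations), ]
    sources <- unique(md$source)
    if (length(sources) < 2) next
    prs <- combn(sort(sources), 2)
    for (k in seq_len(ncol(prs))) {
      sa <- md$strain[md$source == prs[1, k]]
      sb <- md$strain[md$source == prs[2, k]]
      for (m in colnames(concentrations)) {
        va <- concentrations[sa, m]; vb <- concentrations[sb, m]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) == 0 || length(vb) == 0) next
        if (length(unique(c(va, vb))) == 1) next  # no variation to compare
        mw <- mann_whitney(va, vb)
        out[[length(out) + 1]] <- data.frame(
          species = sp, metabolite = m, source_a = prs[1, k],
          source_b = prs[2, k], n_a = mw$n_a, n_b = mw$n_b, U = mw$U,
          p_value = mw$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(species = character(0), metabolite = character(0),
                      source_a = character(0), source_b = character(0),
                      n_a = integer(0), n_b = integer(0), U = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
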