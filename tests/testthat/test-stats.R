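test_that("spearman handles monotone and tied inputs", {
  expect_equal(spearman_assoc(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_assoc(1:3, 3:1)$rho, -1)
  # tied case against the explicit rank-then-Pearson oracle
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_assoc(x, y)$rho, oracle_spearman_rho(x, y),
               tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
  expect_error(spearman_assoc(1:2, 1:2), "at least 3")
})

test_that("spearman rho equals the oracle and is transform-invariant", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE)  # forces ties
    y <- rnorm(n)
    r <- spearman_assoc(x, y)
    expect_equal(r$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(spearman_assoc(y, x)$rho, r$rho, tolerance = 1e-12)
    expect_equal(spearman_assoc(exp(x), y^3 + 5 * y)$rho,
                 spearman_assoc(x, y^3)$rho, tolerance = 1e-12)
  }
})

test_that("small-sample spearman p is an exact permutation probability", {
  set.seed(29)
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- spearman_assoc(x, y)
    expect_equal(r$method, "exact permutation")
    # brute-force enumeration over permutations of y
    perms <- indolepath:::permutations_of(n)
    obs <- abs(oracle_spearman_rho(x, y))
    rhos <- apply(perms, 1, function(p) oracle_spearman_rho(x, y[p]))
    expect_equal(r$p_value, mean(abs(rhos) >= obs - 1e-12),
                 tolerance = 1e-12)
    expect_gt(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
})

test_that("bh_fdr matches the step-up formula and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
    expect_true(all(q <= 1))
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("mann-whitney reproduces the textbook exact case", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 label assignments
  expect_equal(r$method, "exact")
  r2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$U, 8)  # n^2/2 under identical groups
  expect_gt(r2$p_value, 0.99)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact mann-whitney p equals full enumeration on tie-free inputs", {
  set.seed(37)
  for (rep in 1:12) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    v <- sample(1:50, na + nb)  # distinct values, no ties
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    r <- mann_whitney(a, b)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
    expect_gte(r$U, 0)
    expect_lte(r$U, na * nb)
  }
})

test_that("large-sample mann-whitney agrees with a permutation oracle", {
  set.seed(41)
  a <- rnorm(15, 0); b <- rnorm(15, 1.2)
  r <- mann_whitney(a, b)
  expect_equal(r$method, "normal approximation")
  # permutation reference on the same statistic
  pool <- c(a, b)
  rps <- replicate(4000, {
    sel <- sample(30, 15)
    ua <- sum(rank(pool)[sel]) - 15 * 16 / 2
    min(ua, 225 - ua)
  })
  p_perm <- mean(rps <= r$U + 1e-12)
  expect_lt(abs(r$p_value - p_perm), 0.02)
})

test_that("correlation screen reports planted associations and flags", {
  set.seed(43)
  n <- 60
  counts <- cbind(enzA = rpois(n, 3), enzB = rpois(n, 2),
                  enzC = rep(2, n))  # constant column
  rownames(counts) <- sprintf("s%02d", 1:n)
  conc <- cbind(metX = counts[, "enzA"] * 10 + rnorm(n, sd = 2),
                metY = rnorm(n, 50, 10))
  rownames(conc) <- rownames(counts)
  res <- gene_metabolite_correlations(counts, conc, alpha = 0.05)
  expect_equal(nrow(res), 6)
  planted <- res[res$enzyme == "enzA" & res$metabolite == "metX", ]
  expect_true(planted$reported)
  expect_gt(planted$rho, 0.3)
  # constant columns yield NA and are excluded from the BH family
  expect_true(all(is.na(res$q_value[res$enzyme == "enzC"])))
  expect_false(any(res$reported[res$enzyme == "enzC"]))
  # q >= p within the family
  ok <- !is.na(res$q_value)
  expect_true(all(res$q_value[ok] >= res$p_value[ok] - 1e-15))
  expect_error(gene_metabolite_correlations(counts[1:2, ], conc[1:2, ]),
               "fewer than 3")
})

test_that("identical count and concentration columns give rho 1", {
  n <- 20
  counts <- cbind(enz = 1:n)
  rownames(counts) <- sprintf("s%02d", 1:n)
  conc <- cbind(met = 1:n)
  rownames(conc) <- rownames(counts)
  res <- gene_metabolite_correlations(counts, conc)
  expect_equal(res$rho, 1)
  expect_true(res$reported)
})

test_that("source comparisons cover multi-source species only", {
  md <- data.frame(strain = sprintf("s%02d", 1:8),
                   species = rep(c("X", "Y"), each = 4),
                   source = c("a", "a", "b", "b", "c", "c", "c", "c"),
                   stringsAsFactors = FALSE)
  set.seed(47)
  conc <- matrix(runif(16, 1, 100), 8, 2,
                 dimnames = list(md$strain, c("ILA", "IAld")))
  res <- source_comparisons(conc, md)
  expect_true(all(res$species == "X"))  # Y has a single source
  expect_equal(sort(unique(res$metabolite)), c("IAld", "ILA"))
  expect_true(all(res$U >= 0 & res$U <= res$n_a * res$n_b))
})
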