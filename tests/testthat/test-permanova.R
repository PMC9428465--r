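test_that("Bray-Curtis matches the formula and vegan", {
  m <- rbind(a = c(2, 2), b = c(1, 3), c = c(2, 2))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  ## disjoint supports are maximally dissimilar
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 5)))[1, 2], 1)
  ## all-zero pairs are undefined
  expect_warning(dz <- bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_true(is.nan(dz[1, 2]))

  skip_if_not_installed("vegan")
  set.seed(13)
  mm <- matrix(runif(40), 8, 5)
  expect_equal(
    bray_curtis(mm),
    as.matrix(vegan::vegdist(mm, method = "bray")),
    ignore_attr = TRUE, tolerance = 1e-12
  )
})

test_that("pseudo-F agrees with the direct partition and with adonis2", {
  set.seed(19)
  mat <- matrix(runif(60), 12, 5)
  groups <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(mat)
  res <- permanova(d, groups, n_perm = 99, seed = 1)
  expect_equal(res$pseudo_f, direct_pseudo_f(d, groups), tolerance = 1e-10)
  expect_equal(unname(res$df), c(2, 9))

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(stats::as.dist(d) ~ g,
    data = data.frame(g = groups), permutations = 99
  )
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("far-separated tight clusters drive p to its attainable minimum", {
  set.seed(2)
  mat <- rbind(
    matrix(rep(c(1, 0, 0), 5), ncol = 3, byrow = TRUE) +
      matrix(runif(15, 0, 1e-3), 5, 3),
    matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE) +
      matrix(runif(15, 0, 1e-3), 5, 3)
  )
  d <- bray_curtis(mat)
  res <- permanova(d, rep(c("x", "y"), each = 5), n_perm = 199, seed = 2)
  ## the observed F is maximal, so only permutations that happen to map the
  ## two clusters onto the two labels tie with it; p sits at the floor up
  ## to those ties (expected ~199 * 2/252 of them)
  expect_gte(res$p_perm, 1 / 200)
  expect_lte(res$p_perm, (1 + 8) / 200)

  ## exact version: with 3+3 clusters, exhaustive enumeration counts the
  ## 2 * 3! * 3! cluster-preserving relabellings out of 6! exactly
  mat6 <- rbind(
    matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 3), ncol = 2, byrow = TRUE)
  ) + matrix(runif(12, 0, 1e-4), 6, 2)
  d6 <- bray_curtis(mat6)
  res6 <- permanova(d6, rep(c("x", "y"), each = 3), method = "exhaustive")
  expect_equal(res6$p_perm, 2 * factorial(3)^2 / factorial(6))
})

test_that("exhaustive enumeration matches an independent split-by-split oracle", {
  set.seed(23)
  mat <- matrix(runif(24), 6, 4)
  groups <- rep(c("g1", "g2"), each = 3)
  d <- bray_curtis(mat)
  res <- permanova(d, groups, method = "exhaustive")

  ## oracle: enumerate the 20 assignments of 3-of-6 to group 1 directly
  f_obs <- direct_pseudo_f(d, groups)
  splits <- combn(6, 3)
  f_all <- apply(splits, 2, function(idx) {
    g <- rep("g2", 6)
    g[idx] <- "g1"
    direct_pseudo_f(d, g)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  expect_equal(res$p_perm, p_exact)
  expect_equal(res$pseudo_f, f_obs, tolerance = 1e-10)
})

test_that("p is invariant to group relabelling and distance isometry", {
  set.seed(29)
  mat <- matrix(runif(50), 10, 5)
  groups <- rep(c("a", "b"), each = 5)
  d <- bray_curtis(mat)
  r1 <- permanova(d, groups, n_perm = 99, seed = 7)
  relab <- ifelse(groups == "a", "zzz", "aaa")
  r2 <- permanova(d, relab, n_perm = 99, seed = 7)
  expect_equal(r1$pseudo_f, r2$pseudo_f)
  expect_equal(r1$p_perm, r2$p_perm)
  ## doubling every distance rescales SS but not F or p
  r3 <- permanova(2 * d, groups, n_perm = 99, seed = 7)
  expect_equal(r1$pseudo_f, r3$pseudo_f, tolerance = 1e-10)
  expect_equal(r1$p_perm, r3$p_perm)
})

test_that("continuous predictors give a 1-df regression on distances", {
  set.seed(37)
  mat <- matrix(runif(60), 12, 5)
  temp <- rep(c(10, 15, 20, 25, 30, 35), each = 2)
  d <- bray_curtis(mat)
  res <- permanova(d, temp, n_perm = 99, seed = 3)
  expect_equal(unname(res$df), c(1, 10))
  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(stats::as.dist(d) ~ t,
    data = data.frame(t = temp), permutations = 99
  )
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("singleton groups are rejected", {
  d <- bray_curtis(matrix(runif(15), 5, 3))
  expect_error(permanova(d, c("a", "a", "a", "a", "b")), "singleton")
})

test_that("pairwise tests apply the Bonferroni factor C(k,2)", {
  set.seed(41)
  mat <- matrix(runif(180), 36, 5)
  groups <- rep(c(10, 15, 20, 25, 30, 35), each = 6)
  d <- bray_curtis(mat)
  out <- pairwise_permanova(d, factor(groups), n_perm = 99, seed = 5)
  expect_identical(nrow(out), 15L)
  expect_equal(out$p_adj, pmin(out$p_raw * 15, 1))
  expect_true(all(out$p_adj >= out$p_raw))
  expect_true(all(out$p_adj <= 1))
})

test_that("composition PCA has the promised structure", {
  ## identical rows: nothing to explain
  flat <- pca_composition(matrix(0.25, 6, 4))
  expect_true(all(flat$scores == 0))
  expect_true(all(flat$var_explained == 0))

  ## two taxa on the simplex line: one component carries everything
  pa <- seq(0.1, 0.9, length.out = 8)
  line <- cbind(pa, 1 - pa)
  res <- pca_composition(line)
  expect_equal(res$var_explained[1], 1)

  ## full-rank reconstruction returns the centered input
  set.seed(43)
  mat <- matrix(runif(40), 10, 4)
  r <- pca_composition(mat)
  centered <- scale(mat, center = TRUE, scale = FALSE)
  expect_equal(
    unname(r$scores %*% t(r$loadings)), unname(centered[, ]),
    tolerance = 1e-10
  )
  ## loadings orthonormal, variance fractions non-increasing and <= 1
  expect_equal(
    crossprod(r$loadings), diag(ncol(r$loadings)),
    ignore_attr = TRUE, tolerance = 1e-10
  )
  expect_true(all(diff(r$var_explained) <= 1e-12))
  expect_lte(sum(r$var_explained), 1 + 1e-12)
  ## sign convention: the dominant loading of each component is positive
  for (j in seq_len(ncol(r$loadings))) {
    l <- r$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
})
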