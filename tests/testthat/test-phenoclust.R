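test_that("standardization centers, scales, and handles constant columns", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(m)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  # idempotence
  expect_equal(standardize(z), z, tolerance = 1e-12)

  mc <- cbind(a = c(1, 2, 3), const = c(5, 5, 5))
  expect_warning(z2 <- standardize(mc), "const")
  expect_identical(colnames(z2), "a")
  expect_error(suppressWarnings(standardize(cbind(k = c(1, 1, 1)))),
               "constant")
})

test_that("PCA ratios match an independent eigendecomposition", {
  # exactly collinear features: rank 1
  m <- cbind(a = c(-1, 0, 1, 2), b = 2 * c(-1, 0, 1, 2))
  z <- standardize(m)
  expect_equal(pca_features(z)$var_ratio[1], 1)

  # isotropic 2D Gaussian: both ratios near 1/2
  set.seed(8)
  iso <- standardize(matrix(rnorm(4000), 2000, 2,
                            dimnames = list(NULL, c("a", "b"))))
  expect_equal(pca_features(iso)$var_ratio, c(0.5, 0.5), tolerance = 0.05)

  # synthetic growth matrix vs direct covariance eigensolve
  co <- gen_growth_cohort(seed = 11)
  z3 <- standardize(growth_feature_matrix(co$tables))
  got <- pca_features(z3)$var_ratio
  ev <- eigen(stats::cov(z3), symmetric = TRUE)$values
  expect_equal(got, ev / sum(ev), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
})

test_that("PCA sign convention is deterministic under row shuffles", {
  set.seed(9)
  m <- standardize(matrix(rnorm(60), 20, 3,
                          dimnames = list(NULL, c("a", "b", "c"))))
  p1 <- pca_features(m)
  perm <- sample(20)
  p2 <- pca_features(m[perm, ])
  expect_equal(p2$scores[order(perm), ], p1$scores, tolerance = 1e-9)
  expect_true(all(apply(p1$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("Ward.D2 groups well-separated pairs and renumbers by size", {
  m <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10, 10.1), c(10.2, 10))
  wd <- ward_d2(m, k = 2)
  expect_identical(wd$labels, c(2L, 2L, 1L, 1L, 1L))  # big cluster first
  expect_error(ward_d2(m, k = 6), "exceeds")
})

test_that("Ward.D2 equals the exhaustive greedy-merge oracle for n <= 7", {
  set.seed(30)
  for (i in 1:30) {
    n <- sample(3:7, 1)
    m <- matrix(rnorm(n * 2), n, 2)
    hc <- ward_d2(m, k = 2)$hclust
    orc <- oracle_ward(m)
    expect_equal(hc$height, orc$heights, tolerance = 1e-9)
    for (k in 2:(n - 1)) {
      expect_equal(ari(cutree(hc, k), orc$partitions[[n - k]]), 1)
    }
  }
})

test_that("linkage heights are non-decreasing and clustering is
           permutation-equivariant", {
  set.seed(14)
  m <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, letters[1:4]))
  wd <- ward_d2(m, k = 3)
  expect_true(all(diff(wd$height) >= -1e-12))
  perm <- sample(20)
  wd2 <- ward_d2(m[perm, ], k = 3)
  expect_equal(ari(wd2$labels[order(perm)], wd$labels), 1)
})

test_that("rank-sum comparisons match exhaustive enumeration and stars", {
  cmp <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(1:2, each = 3))
  # most extreme of the C(6,3) = 20 rank splits, two-sided: 2/20
  expect_equal(cmp$p_value, 0.1)
  expect_identical(cmp$stars, "ns")

  same <- compare_groups(rep(5, 8), rep(1:2, each = 4))
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "ns")

  expect_error(compare_groups(1:9, rep(1:3, each = 3)), "2 groups")

  expect_identical(p_stars(0.00005), "****")
  expect_identical(p_stars(0.03), "*")
})

test_that("the pipeline recovers planted structure in all three analyses", {
  co <- gen_growth_cohort(seed = 11)
  pg <- phenocluster(growth_feature_matrix(co$tables), k = 3)
  expect_gte(ari(pg$labels, co$archetype), 0.9)

  ce <- gen_trajectory_cohort(seed = 3)
  fe <- t(vapply(ce$trajectories, eversion_features, numeric(14)))
  pe <- phenocluster(fe, k = 2)
  expect_gte(ari(pe$labels, ce$mode), 0.9)
  # displacers move farther and have more variable headings than statics
  disp <- ce$mode == "displacer"
  expect_gt(mean(fe[disp, "mean_linear_distance"]),
            mean(fe[!disp, "mean_linear_distance"]))

  cd <- gen_decay_cohort(seed = 9)
  fd <- degradation_feature_matrix(cd$series, untrackable_below = 40)
  pd <- phenocluster(fd, k = 2)
  expect_gte(ari(pd$labels, cd$size_class), 0.9)
  large <- cd$size_class == "large"
  expect_gt(mean(fd[large, "time_to_disintegrate"]),
            mean(fd[!large, "time_to_disintegrate"]))
})

test_that("clustering in PCA space is available and labeled deterministically", {
  co <- gen_growth_cohort(seed = 11)
  fm <- growth_feature_matrix(co$tables)
  p1 <- phenocluster(fm, k = 3, cluster_space = "pca")
  p2 <- phenocluster(fm, k = 3, cluster_space = "pca")
  expect_identical(p1$labels, p2$labels)
  expect_identical(sort(unique(p1$labels)), 1:3)
})
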