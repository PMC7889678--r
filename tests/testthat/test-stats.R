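test_that("paired t-test matches hand arithmetic and is antisymmetric", {
  tt <- paired_t(c(1, 2, 3), c(2, 3, 5))
  expect_equal(tt$statistic, 4)
  expect_equal(tt$df, 2)
  # independent CDF oracle for the two-sided p
  expect_equal(tt$p_value, 2 * pt(4, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  rev <- paired_t(c(2, 3, 5), c(1, 2, 3))
  expect_equal(rev$statistic, -tt$statistic)
  expect_equal(rev$p_value, tt$p_value)

  expect_error(paired_t(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5) + 2), "degenerate")
  expect_error(paired_t(1, 2), "pairs")

  named <- paired_t(c(a = 1, b = 2, c = 3), c(c = 5, a = 2, b = 3))
  expect_equal(named$statistic, 4)   # aligned by patient name
})

test_that("Holm-Sidak adjustment matches the closed-form example", {
  expect_equal(holm_sidak(c(0.01, 0.02, 0.03, 0.04)),
               c(0.03940399, 0.058808, 0.0591, 0.0591), tolerance = 1e-6)
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(rep(1, 5)), rep(1, 5))
  p <- c(0.04, 0.01, 0.03, 0.02)
  o <- order(p)
  expect_equal(holm_sidak(p)[o], sort(holm_sidak(sort(p))))
  expect_true(all(holm_sidak(p) >= p))
})

test_that("BH q-values match the step-up example and dominate p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(31)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # invariant to input ordering
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("Pearson chi-square reproduces printed contingency p-values", {
  t1 <- pearson_chi2(matrix(c(4, 1, 7, 17), 2))
  expect_equal(round(t1$p_value, 4), 0.0331)
  expect_equal(t1$statistic, 29 * (4 * 17 - 7 * 1)^2 / (11 * 18 * 5 * 24),
               tolerance = 1e-10)

  t2 <- pearson_chi2(matrix(c(58, 4, 42, 29), 2))
  expect_lt(t2$p_value, 0.0001)

  t0 <- pearson_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("2x2 chi-square equals the closed form on random tables", {
  set.seed(32)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    closed <- sum(m) * (a * d - b * c)^2 /
      (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
    expect_equal(pearson_chi2(m)$statistic, closed, tolerance = 1e-10)
  }
})

test_that("exact McNemar matches printed values and the enumeration oracle", {
  expect_equal(round(mcnemar_test(10, 3)$p_value, 4), 0.0923)
  expect_equal(mcnemar_test(10, 3)$p_value, 2 * 378 / 8192, tolerance = 1e-12)
  expect_equal(mcnemar_test(9, 1)$p_value, 22 / 1024, tolerance = 1e-12)
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(0, 0)$p_value, 1)

  for (b in 0:6) {
    for (cc in 0:6) {
      expect_equal(mcnemar_test(b, cc)$p_value, oracle_mcnemar(b, cc),
                   tolerance = 1e-12)
    }
  }
  # larger discordance totals up to 12
  for (pair in list(c(12, 0), c(11, 1), c(8, 4), c(7, 5))) {
    expect_equal(mcnemar_test(pair[1], pair[2])$p_value,
                 oracle_mcnemar(pair[1], pair[2]), tolerance = 1e-12)
  }

  # chi-square variant
  mc <- mcnemar_test(10, 3, exact = FALSE)
  expect_equal(mc$statistic, 49 / 13, tolerance = 1e-12)
})

test_that("exact McNemar never exceeds its nominal level under the null", {
  set.seed(33)
  rejections <- vapply(1:1000, function(i) {
    bl <- sample(1:2, 29, replace = TRUE)
    pg <- sample(1:2, 29, replace = TRUE)
    b <- sum(bl == 1 & pg == 2)
    cc <- sum(bl == 2 & pg == 1)
    mcnemar_test(b, cc)$p_value < 0.05
  }, logical(1))
  # the exact binomial test is conservative: size <= alpha (+ MC noise)
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 1000))
})

test_that("sample clustering separates shifted groups deterministically", {
  set.seed(34)
  e <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%02d", 1:12)))
  e[, 7:12] <- e[, 7:12] + 6
  cl <- cluster_samples(e, k = 2)
  expect_equal(length(unique(cl$labels[1:6])), 1)
  expect_equal(length(unique(cl$labels[7:12])), 1)
  expect_false(cl$labels[1] == cl$labels[7])

  # duplicated sample: identical labels, adjacent leaves
  e2 <- cbind(e, dup = e[, 1])
  cl2 <- cluster_samples(e2, k = 2)
  expect_equal(unname(cl2$labels["dup"]), unname(cl2$labels[1]))
  pos <- match(c(colnames(e)[1], "dup"), cl2$leaf_order)
  expect_equal(abs(diff(pos)), 1)

  # permutation invariance of the partition
  perm <- sample(12)
  cl3 <- cluster_samples(e[, perm], k = 2)
  agree <- outer(cl$labels, cl$labels, "==")
  agree3 <- outer(cl3$labels[names(cl$labels)], cl3$labels[names(cl$labels)], "==")
  expect_true(all(agree == agree3))

  expect_error(cluster_samples(e, k = 13), "exceeds")
})

test_that("neighbour pairs are exactly the two-leaf clades", {
  set.seed(35)
  e <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%02d", 1:10)))
  e[, 2] <- e[, 1] + rnorm(20, 0, 1e-4)   # s01/s02 near-duplicates
  cl <- cluster_samples(e, k = 2, scale_genes = FALSE)
  nb <- neighbour_pairs(cl$dendrogram,
                        baseline = c("s01", "s03"),
                        progression = c("s02", "s04"))
  expect_true(nb[1])
  expect_error(neighbour_pairs(cl$dendrogram, "s01", "nope"), "not in dendrogram")
})

test_that("planted tight pairs are the ones called neighbours", {
  calls <- vapply(1:20, function(seed) {
    set.seed(seed)
    n_pairs <- 29
    e_bl <- matrix(rnorm(40 * n_pairs), 40, n_pairs)
    e_pg <- matrix(rnorm(40 * n_pairs), 40, n_pairs)
    tight <- 1:5
    e_pg[, tight] <- e_bl[, tight] + rnorm(40 * 5, 0, 0.05)
    e <- cbind(e_bl, e_pg)
    colnames(e) <- c(sprintf("P%02d_BL", 1:n_pairs), sprintf("P%02d_PG", 1:n_pairs))
    rownames(e) <- sprintf("g%d", 1:40)
    cl <- cluster_samples(e, k = 2, scale_genes = FALSE)
    nb <- neighbour_pairs(cl$dendrogram,
                          baseline = sprintf("P%02d_BL", 1:n_pairs),
                          progression = sprintf("P%02d_PG", 1:n_pairs))
    all(nb[tight]) && !any(nb[-tight])
  }, logical(1))
  expect_gte(mean(calls), 0.5)
  expect_gte(median(as.numeric(calls)), 1)   # exact call set in most seeds
})

test_that("paired cluster contingency feeds McNemar and the arm chi-square", {
  labels <- stats::setNames(rep(c(1, 2), each = 6),
                            c(sprintf("b%d", 1:6), sprintf("p%d", 1:6)))
  # all pairs concordant: both members in cluster 1
  conc <- stats::setNames(rep(1, 12), names(labels))
  conc[c("p5", "p6", "b5", "b6")] <- 2
  res <- paired_cluster_contingency(conc, sprintf("b%d", 1:6), sprintf("p%d", 1:6))
  expect_equal(res$mcnemar$p_value, 1)

  # all pairs discordant 1 -> 2
  res2 <- paired_cluster_contingency(labels, sprintf("b%d", 1:6),
                                     sprintf("p%d", 1:6))
  expect_equal(res2$cluster_table[1, 2], 6)
  expect_equal(res2$mcnemar$p_value, 2 * (0.5^6), tolerance = 1e-12)
})

test_that("the printed neighbour-by-arm table reproduces its chi-square p", {
  # 29 pairs: 11 in one arm (4 neighbours), 18 in the other (1 neighbour)
  arm <- rep(c("A", "B"), c(11, 18))
  neighbour <- c(rep(TRUE, 4), rep(FALSE, 7), TRUE, rep(FALSE, 17))
  tab <- table(arm = arm, neighbour = factor(neighbour, c(TRUE, FALSE)))
  expect_equal(unclass(tab), matrix(c(4, 1, 7, 17), 2), ignore_attr = TRUE)
  expect_equal(round(pearson_chi2(unclass(tab))$p_value, 4), 0.0331)
})

test_that("paired t type-I error is nominal on null eigengenes", {
  set.seed(36)
  rejections <- vapply(1:2000, function(i) {
    d <- rnorm(29)
    paired_t(d, d + rnorm(29))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})
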