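make_raw <- function(values, classes) {
  raw_counts(values, stats::setNames(classes, rownames(values)))
}

test_that("background threshold is negative-control mean plus 2 sample SDs", {
  expect_equal(background_threshold(c(2, 4, 6)), 8)
  expect_equal(background_threshold(c(7, 7, 7, 7)), 7)
  x <- 1:8
  expect_equal(background_threshold(x), mean(x) + 2 * sd(x))
  m <- cbind(s1 = c(2, 4, 6), s2 = c(7, 7, 7))
  expect_equal(background_threshold(m), c(s1 = 8, s2 = 7))
  expect_error(background_threshold(5), "SD undefined")
})

test_that("background subtraction floors at 1 and drops control probes", {
  v <- matrix(c(5, 90, 10, 3, 40000,
                10, 100, 8, 5, 40000), ncol = 2,
              dimnames = list(c("g1", "g2", "hk1", "neg1", "pos1"),
                              c("s1", "s2")))
  raw <- make_raw(v, c("endogenous", "endogenous", "norm_candidate",
                       "negative", "positive"))
  thr <- c(s1 = 10, s2 = 8)
  corr <- apply_background(raw, thr)
  expect_equal(rownames(corr), c("g1", "g2", "hk1"))
  expect_equal(corr["g1", "s1"], 1)     # 5 - 10 < 0 -> set to 1
  expect_equal(corr["g2", "s2"], 92)    # 100 - 8
  expect_equal(corr["g2", "s1"], 80)
  expect_equal(corr["hk1", "s1"], 1)    # count equal to threshold -> 1
  expect_true(all(corr >= 1))
})

test_that("detection uses a strict threshold and QC removal a strict fraction", {
  v <- matrix(c(10, 11, 9, 3), ncol = 1,
              dimnames = list(c("g1", "g2", "neg1", "neg2"), "s1"))
  raw <- make_raw(v, c("endogenous", "endogenous", "negative", "negative"))
  thr <- c(s1 = 10)
  det <- detection_calls(raw, thr)
  expect_false(det["g1", "s1"])   # count == threshold -> not detected
  expect_true(det["g2", "s1"])

  det201 <- matrix(TRUE, 201, 3,
                   dimnames = list(sprintf("g%d", 1:201), c("a", "b", "c")))
  det201[1:101, "a"] <- FALSE     # 101/201 undetected: removed
  det201[1:100, "b"] <- FALSE     # 100/201 = 49.75%: kept
  expect_equal(qc_filter_samples(det201), c("b", "c"))
  # idempotence
  kept <- qc_filter_samples(det201)
  expect_equal(qc_filter_samples(det201[, kept]), kept)
})

test_that("geNorm M matches the brute-force pairwise log-ratio oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(2^runif(5 * 8, 4, 10), 5, 8,
                dimnames = list(sprintf("c%d", 1:5), sprintf("s%d", 1:8)))
    gn <- genorm_rank(x)
    expect_equal(gn$stability_M, oracle_genorm_M(x), tolerance = 1e-10)
  }
})

test_that("proportional candidates have zero mutual variation", {
  s <- 2^runif(6, 5, 9)
  x <- rbind(a = s, b = 3 * s, c = 2^runif(6, 5, 9))
  gn <- genorm_rank(x)
  # V_ab = sd(log2(a/b)) = sd(const) = 0, so M_a = M_b = mean(0, V_ac-ish)/2
  lx <- log2(x)
  expect_equal(unname(gn$stability_M["a"] - gn$stability_M["b"]), 0,
               tolerance = 1e-12)
  expect_equal(sd(lx["a", ] - lx["b", ]), 0, tolerance = 1e-12)
  expect_error(genorm_rank(rbind(a = s, b = -s, c = s)), "positive")
})

test_that("a noisy candidate is eliminated first", {
  n_first <- vapply(1:100, function(seed) {
    set.seed(seed)
    base <- runif(10, 6, 9)
    stable <- t(replicate(3, 2^(base + rnorm(10, 0, 0.1))))
    noisy <- 2^(base + rnorm(10, 0, 1.0))
    x <- rbind(stable, noisy)
    rownames(x) <- c("k1", "k2", "k3", "noisy")
    genorm_rank(x)$elimination_order[1] == "noisy"
  }, logical(1))
  expect_gte(mean(n_first), 0.95)
})

test_that("geNorm selection follows the V cutoff stopping rule", {
  gn <- structure(list(ranking = c("a", "b", "c", "d"),
                       V = c("2:3" = 0.05, "3:4" = 0.05)),
                  class = "genorm")
  expect_equal(genorm_select(gn), c("a", "b"))
  gn$V[] <- c(0.3, 0.3)
  expect_equal(genorm_select(gn), c("a", "b", "c", "d"))
  gn$V[] <- c(0.3, 0.05)
  expect_equal(genorm_select(gn), c("a", "b", "c"))
  expect_equal(genorm_select(gn, n_ref_genes = 2), c("a", "b"))
  expect_error(genorm_select(gn, n_ref_genes = 1), "between 2")
})

test_that("unstable synthetic candidates are excluded from the selection", {
  hits <- vapply(1:100, function(seed) {
    sim <- simulate_panel(simulation_config(seed = seed))
    norm <- suppressWarnings(nanostring_normalize(sim$counts))
    !any(setdiff(sprintf("HK%02d", 1:6), sim$truth$stable_reference_genes) %in%
           norm$reference_genes)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("geometric-mean scaling behaves on constructed inputs", {
  # identical NF in every sample: output = log2(corrected)
  corr <- matrix(c(4, 16, 4, 16), 2, dimnames = list(c("g", "ref"), c("a", "b")))
  out <- normalize_counts(corr, "ref")
  expect_equal(out$values, log2(corr))
  expect_equal(unname(out$scale_factors), c(1, 1))

  # single reference gene with values [2, 8]: NF = [2, 8], scale = [2, 0.5]
  corr2 <- matrix(c(10, 2, 40, 8), 2, dimnames = list(c("g", "ref"), c("a", "b")))
  out2 <- normalize_counts(corr2, "ref")
  expect_equal(unname(out2$normalization_factors), c(2, 8))
  expect_equal(unname(out2$scale_factors), c(2, 0.5))
  expect_equal(unname(out2$values["g", ]), log2(c(20, 20)))
})

test_that("a doubled sample normalizes back to its twin", {
  sim <- simulate_panel(simulation_config(seed = 8, n_pairs = 6))
  raw <- sim$counts
  v <- raw$values
  v[, 2] <- 2 * v[, 1]          # sample 2 := doubled copy of sample 1
  raw2 <- raw_counts(v, raw$probe_class)
  norm <- suppressWarnings(nanostring_normalize(raw2))
  e <- norm$values
  # identical up to the floor rule: compare probes clear of the floor in both
  clear <- e[, 1] > 1 & e[, 2] > 1
  expect_gt(sum(clear), 150)
  expect_equal(e[clear, 2], e[clear, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("scale equivariance: scaling one sample leaves it unchanged", {
  sim <- simulate_panel(simulation_config(seed = 9, n_pairs = 6))
  norm1 <- suppressWarnings(nanostring_normalize(sim$counts))
  v <- sim$counts$values
  v[, 3] <- v[, 3] * 3          # controls included
  norm2 <- suppressWarnings(nanostring_normalize(raw_counts(v, sim$counts$probe_class)))
  e1 <- norm1$values[, 3]
  e2 <- norm2$values[, 3]
  clear <- e1 > 1 & e2 > 1      # floor rule exempted
  expect_gt(mean(clear), 0.8)
  # the sample itself is restored up to the global reference, which moves by
  # c^(1/n_samples) because the scaled sample contributes to the grand
  # geometric mean: a constant log2(3)/12 offset on 12 samples
  expect_equal(unname(e2[clear] - e1[clear]),
               rep(log2(3) / 12, sum(clear)), tolerance = 1e-6)
})

test_that("normalization preserves within-sample rank order", {
  sim <- simulate_panel(simulation_config(seed = 10, n_pairs = 5))
  norm <- suppressWarnings(nanostring_normalize(sim$counts))
  thr <- norm$thresholds
  corrected <- apply_background(sim$counts, thr)
  endo <- probes_of_class(sim$counts, "endogenous")
  for (s in colnames(norm$values)[1:4]) {
    expect_equal(order(norm$values[endo, s]), order(corrected[endo, s]))
  }
})
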