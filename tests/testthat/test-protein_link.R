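test_that("intensity transforms are monotone and validated", {
  x <- c(0, 10, 150, 2000)
  expect_equal(transform_intensity(x, "identity"), x)
  expect_equal(transform_intensity(0)[1], 0)
  expect_equal(transform_intensity(x), asinh(x / 150))
  expect_equal(transform_intensity(x, "log10p"), log10(1 + x))
  set.seed(2)
  r <- runif(50, 0, 1e4)
  expect_equal(rank(transform_intensity(r)), rank(r))
  expect_error(transform_intensity(c(1, -2)), "non-negative")
})

test_that("stain groups follow explicit cutpoints", {
  tab <- data.frame(cell_id = c("a", "b", "c"), PE = c(5, 50, 500))
  g <- assign_stain_groups(tab, "PE", cutpoints = c(10, 100),
                           transform = "identity")
  expect_equal(as.character(g$group), c("negative", "low", "high"))
  expect_true(is.ordered(g$group))
})

test_that("1-D k-means recovers well-separated mixtures and orders labels", {
  set.seed(5)
  y <- c(rnorm(200, 100, 10), rnorm(150, 1000, 80), rnorm(100, 8000, 500))
  truth <- rep(c("negative", "low", "high"), c(200, 150, 100))
  tab <- data.frame(cell_id = sprintf("c%03d", 1:450), PE = pmax(y, 0))
  g <- assign_stain_groups(tab, "PE", method = "kmeans1d", k = 3, seed = 1)
  expect_gte(mean(as.character(g$group) == truth), 0.98)
  expect_error(assign_stain_groups(data.frame(cell_id = c("a", "b"),
                                              PE = c(5, 5)),
                                   "PE", method = "kmeans1d", k = 3),
               "distinct")
})

test_that("protein-deviation correlation has exact r = 1 on linear coupling", {
  set.seed(6)
  x <- runif(40, 10, 1000)
  z <- matrix(rep(2 * x, 3), 3, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3"), sprintf("c%02d", 1:40)))
  ct <- correlate_protein_deviation(z, setNames(x, colnames(z)))
  expect_equal(ct$r, rep(1, 3), tolerance = 1e-12)
  expect_true(all(ct$q_value < 1e-10))
  expect_error(correlate_protein_deviation(z, setNames(rep(3, 40), colnames(z))),
               "zero variance")
  expect_error(correlate_protein_deviation(z[, 1:5], setNames(x[1:5],
                                                              colnames(z)[1:5])),
               "at least 10")
})

test_that("rank-sum group comparisons use the exact small-sample distribution", {
  z <- matrix(c(1, 2, 3, 4, 5, 6), 1,
              dimnames = list("f1", sprintf("c%d", 1:6)))
  groups <- data.frame(cell_id = sprintf("c%d", 1:6),
                       group = factor(rep(c("g1", "g2"), each = 3),
                                      ordered = TRUE))
  out <- compare_stain_groups(z, groups)
  # exact two-sided rank-sum p for {1,2,3} vs {4,5,6} is 2/20 = 0.1
  expect_equal(out$p_value, 0.1)

  # identical groups: p = 1
  z2 <- matrix(rep(c(1, 2, 3), 2), 1, dimnames = list("f1", sprintf("c%d", 1:6)))
  out2 <- compare_stain_groups(z2, groups)
  expect_equal(out2$p_value, 1)

  groups_bad <- groups; groups_bad$cell_id[1] <- "zz"
  expect_error(compare_stain_groups(z, groups_bad), "missing")
  g_small <- data.frame(cell_id = sprintf("c%d", 1:6),
                        group = factor(c("g1", "g1", "g1", "g1", "g1", "g2"),
                                       ordered = TRUE))
  expect_error(compare_stain_groups(z, g_small), "fewer than 3")
})

test_that("planted group shifts are detected with BH control", {
  set.seed(7)
  n <- 50
  z <- rbind(shifted = c(rnorm(n, 1), rnorm(n, 0)),
             null = rnorm(2 * n))
  colnames(z) <- sprintf("c%03d", 1:(2 * n))
  groups <- data.frame(cell_id = colnames(z),
                       group = factor(rep(c("hi", "lo"), each = n),
                                      ordered = TRUE))
  out <- compare_stain_groups(z, groups)
  expect_lt(out$q_value[out$feature == "shifted"], 0.05)
  expect_gt(out$p_value[out$feature == "null"], 0.05)
})

test_that("the dip statistic matches hand-derivable values and the oracle", {
  # two equal point masses: the closest unimodal CDF misses by 1/4
  expect_equal(dip_stat(c(0, 0, 1, 1)), 0.25)
  # equally spaced points are compatible with unimodality up to the step
  # quantisation floor of 1/(2n)
  expect_equal(dip_stat(1:4), 1 / 8)
  expect_equal(dip_stat(1:50), 1 / 100)
  expect_equal(dip_stat(c(0, 0, 0, 1)), 1 / 8)
  # shift/scale invariance
  set.seed(8)
  x <- c(rnorm(60, -2), rnorm(60, 2))
  expect_equal(dip_stat(5 + 3 * x), dip_stat(x))
  # agreement with the independent feasibility-bisection oracle
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    y <- switch(sample(3, 1), runif(n), rnorm(n),
                c(rnorm(ceiling(n / 2), -2), rnorm(floor(n / 2), 2)))
    if (seed %% 3 == 0) y <- round(y, 1)  # ties
    expect_equal(dip_stat(y), dip_oracle(y), tolerance = 1e-9)
  }
})

test_that("the dip test is calibrated on unimodal input and errors on n < 4", {
  expect_error(dip_test(c(1, 2, 3)), "at least 4")
  # an equal-spaced grid is maximally unimodal-compatible
  d <- dip_test(seq(0, 1, length.out = 100), n_boot = 500, seed = 1)
  expect_gt(d$p_value, 0.2)
  # determinism
  d2 <- dip_test(seq(0, 1, length.out = 100), n_boot = 500, seed = 1)
  expect_identical(d$p_value, d2$p_value)
  # clear bimodality is detected
  set.seed(9)
  x <- c(rnorm(100, -2), rnorm(100, 2))
  expect_lt(dip_test(x, n_boot = 500, seed = 2)$p_value, 0.05)
})

test_that("down-sampled variability reduces to the full group at target size", {
  set.seed(10)
  z <- matrix(rnorm(5 * 80), 5, 80,
              dimnames = list(sprintf("f%d", 1:5), sprintf("c%02d", 1:80)))
  groups <- data.frame(cell_id = colnames(z),
                       group = factor(rep(c("g1", "g2"), each = 40),
                                      ordered = TRUE))
  out <- downsampled_variability(z, groups, target_n = 40, n_sim = 5, seed = 1)
  full_v <- apply(z[, 1:40], 1, sd)
  g1 <- out[out$group == "g1", ]
  expect_equal(g1$median, unname(full_v), tolerance = 1e-12)
  expect_equal(g1$lo, g1$hi, tolerance = 1e-12)

  out_a <- downsampled_variability(z, groups, target_n = 20, n_sim = 10, seed = 4)
  out_b <- downsampled_variability(z, groups, target_n = 20, n_sim = 10, seed = 4)
  expect_identical(out_a, out_b)
  expect_error(downsampled_variability(z, groups, target_n = 41), "smaller")
})

test_that("subgroup enrichment reproduces the closed-form chi-squared", {
  # perfectly separated 2x2 table: chisq = 20, p = pchisq(20, 1, lower = FALSE)
  sg <- rep(c("s1", "s2"), each = 10)
  lb <- rep(c("pos", "neg"), each = 10)
  out <- subgroup_enrichment(sg, lb)
  row <- out[out$subgroup == "s1" & out$label == "pos", ]
  expect_equal(row$chisq, 20)
  expect_equal(row$p_value, pchisq(20, 1, lower.tail = FALSE))
  expect_equal(signif(row$p_value, 2), 7.7e-6)

  # independence: chisq = 0, p = 1
  sg2 <- rep(c("s1", "s2"), each = 10)
  lb2 <- rep(c("pos", "neg"), 10)
  out2 <- subgroup_enrichment(sg2, lb2)
  expect_equal(out2$chisq, rep(0, 4))
  expect_equal(out2$p_value, rep(1, 4))

  # planted 90%-pure subgroup is significant after BH
  set.seed(11)
  sg3 <- rep(c("a", "b", "c"), each = 60)
  lb3 <- ifelse(sg3 == "a", ifelse(runif(180) < 0.9, "pos", "neg"),
                sample(c("pos", "neg"), 180, TRUE))[seq_along(sg3)]
  out3 <- subgroup_enrichment(sg3, lb3)
  expect_lt(out3$q_value[out3$subgroup == "a" & out3$label == "pos"], 0.05)
})

test_that("tests are invariant to cell reordering", {
  set.seed(12)
  z <- matrix(rnorm(3 * 60), 3, 60,
              dimnames = list(c("f1", "f2", "f3"), sprintf("c%02d", 1:60)))
  x <- setNames(runif(60, 0, 1000), colnames(z))
  groups <- data.frame(cell_id = colnames(z),
                       group = factor(rep(c("g1", "g2"), 30), ordered = TRUE))
  perm <- sample(60)
  ct1 <- correlate_protein_deviation(z, x)
  ct2 <- correlate_protein_deviation(z[, perm], x)
  expect_equal(ct1$r, ct2$r)
  w1 <- compare_stain_groups(z, groups)
  w2 <- compare_stain_groups(z[, perm], groups)
  expect_equal(w1$p_value, w2$p_value)
})
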