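test_that("expected counts follow the row-share x column-total rule", {
  X <- matrix(1, 4, 3, dimnames = list(paste0("p", 1:4), paste0("c", 1:3)))
  E <- expected_counts(X)
  expect_equal(unname(E), matrix(1, 4, 3))
  # column sums preserved exactly
  set.seed(8)
  X2 <- matrix(rpois(50, 4), 10, 5)
  E2 <- expected_counts(X2)
  expect_equal(colSums(E2), colSums(X2))
  # homogeneity: doubling the counts doubles the expectation
  expect_equal(expected_counts(2 * X2), 2 * E2)
  # a single cell: expectation is the cell itself redistributed by row share,
  # which reproduces the column exactly
  E1 <- expected_counts(X2[, 1, drop = FALSE])
  expect_equal(E1[, 1], X2[, 1] / sum(X2[, 1]) * sum(X2[, 1]))
  expect_error(expected_counts(matrix(0, 2, 2)), "all-zero")
})

test_that("raw deviations match hand arithmetic and conserve totals", {
  # 2 peaks x 2 cells, feature = {p1}:
  # X = [3 1; 1 3]; row shares 0.5, 0.5; col totals 4, 4 -> E = 2 everywhere
  X <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("c1", "c2")))
  M <- matrix(c(1, 0), 2, 1, dimnames = list(rownames(X), "f1"))
  Y <- raw_deviations(X, M)
  expect_equal(unname(Y[1, ]), c((3 - 2) / 2, (1 - 2) / 2))

  # a feature covering all peaks has deviation exactly 0 in every cell
  Mall <- matrix(1, 2, 1, dimnames = list(rownames(X), "all"))
  expect_equal(unname(raw_deviations(X, Mall)[1, ]), c(0, 0))

  expect_error(raw_deviations(X, matrix(0, 2, 1)), "zero member")
})

test_that("background sampling is deterministic and matches covariates", {
  cfg <- sim_config(n_peaks = 1000, n_cells = 100, n_features = 10,
                    peaks_per_feature = 80, gc_confound_r = 0.5,
                    feature_gc_skew = 1, seed = 14)
  ex <- generate_accessibility_experiment(cfg)
  bg1 <- sample_background_peaks(ex$peaks, B = 20, k_nn = 30, seed = 9)
  bg2 <- sample_background_peaks(ex$peaks, B = 20, k_nn = 30, seed = 9)
  expect_identical(bg1$idx, bg2$idx)

  # matched sampling: member and pooled-background gc distributions agree
  M <- as.matrix(ex$annotation)
  for (k in c(1, 5, 10)) {
    mem <- which(M[, k] > 0)
    ks <- suppressWarnings(stats::ks.test(ex$peaks$gc[mem],
                                          ex$peaks$gc[bg1$idx[mem, ]]))
    expect_lt(unname(ks$statistic), 0.15)
  }

  expect_warning(sample_background_peaks(ex$peaks, B = 2, k_nn = 5000, seed = 1),
                 "clamped")
})

test_that("k_nn = 1 backgrounds equal the member set and flag all entries", {
  inst <- random_tiny_instance(5)
  bg <- sample_background_peaks(inst$peaks, B = 5, k_nn = 1, seed = 2)
  # the nearest neighbour of a peak in covariate space is itself
  expect_true(all(bg$idx == row(bg$idx)))
  dev <- corrected_deviations(inst$X, inst$M, bg)
  expect_true(all(dev$undefined))
  expect_true(all(is.na(dev$z)))
})

test_that("corrected deviations equal the brute-force oracle on tiny instances", {
  for (seed in 1:10) {
    inst <- random_tiny_instance(seed)
    bg <- sample_background_peaks(inst$peaks, B = 4,
                                  k_nn = min(10, nrow(inst$peaks)),
                                  seed = seed)
    dev <- corrected_deviations(inst$X, inst$M, bg)
    ora <- oracle_corrected_deviations(inst$X, inst$M, bg)
    ok <- !dev$undefined
    expect_equal(dev$raw[ok], ora$raw[ok], tolerance = 1e-12)
    expect_equal(dev$corrected[ok], ora$corrected[ok], tolerance = 1e-12)
    expect_equal(dev$z[ok], ora$z[ok], tolerance = 1e-12)
  }
})

test_that("permuting cells permutes z-score columns identically", {
  inst <- random_tiny_instance(11)
  bg <- sample_background_peaks(inst$peaks, B = 6, k_nn = 5, seed = 3)
  dev <- corrected_deviations(inst$X, inst$M, bg)
  perm <- sample(ncol(inst$X))
  dev_p <- corrected_deviations(inst$X[, perm], inst$M, bg)
  expect_equal(dev_p$z, dev$z[, perm])
})

test_that("B < 2 is rejected", {
  inst <- random_tiny_instance(2)
  bg <- sample_background_peaks(inst$peaks, B = 1, k_nn = 4, seed = 1)
  expect_error(corrected_deviations(inst$X, inst$M, bg), "at least 2")
})

test_that("variability is calibrated on iid normal z-scores", {
  set.seed(123)
  z <- matrix(rnorm(60 * 500), 60, 500,
              dimnames = list(sprintf("f%02d", 1:60), NULL))
  dev <- structure(list(z = z, undefined = matrix(FALSE, 60, 500)),
                   class = "deviation_matrix")
  vt <- motif_variability(dev)
  expect_true(all(vt$variability > 0.85 & vt$variability < 1.15))
  expect_gt(mean(vt$variability), 0.9)
  expect_lt(mean(vt$variability), 1.1)
  # p-values roughly uniform: no mass collapse at either end
  expect_gt(mean(vt$p_value > 0.1), 0.7)
  expect_equal(vt$q_value >= vt$p_value, rep(TRUE, 60))

  # constant z: zero variability, p ~ 1
  zc <- matrix(1, 3, 100, dimnames = list(c("a", "b", "c"), NULL))
  devc <- structure(list(z = zc, undefined = matrix(FALSE, 3, 100)),
                    class = "deviation_matrix")
  vtc <- motif_variability(devc)
  expect_equal(vtc$variability, rep(0, 3))
  expect_true(all(vtc$p_value > 0.999))
})

test_that("background-resampling p-values agree in rank with the analytic null", {
  cfg <- sim_config(n_peaks = 300, n_cells = 50, n_features = 8,
                    peaks_per_feature = 30, seed = 2)
  ex <- generate_accessibility_experiment(cfg)
  bg <- sample_background_peaks(ex$peaks, B = 10, k_nn = 20, seed = 1)
  dev <- corrected_deviations(ex$counts, ex$annotation, bg)
  vt_chi <- motif_variability(dev)
  vt_bg <- motif_variability(dev, method = "background", X = ex$counts,
                             M = ex$annotation, bg = bg)
  expect_true(all(vt_bg$p_value >= 1 / 11 - 1e-12))  # resolution 1/(B+1)
  expect_true(all(vt_bg$p_value <= 1))
  # the two nulls broadly order features the same way
  expect_gt(cor(vt_chi$p_value, vt_bg$p_value, method = "spearman"), 0.5)
})

test_that("feature selection applies BH ordering and thresholds", {
  tab <- data.frame(feature = letters[1:4], variability = c(2, 3, 1.5, 1.2),
                    p_value = c(0.01, 0.02, 0.03, 0.04),
                    q_value = p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                    n_cells = 100)
  class(tab) <- c("variability_table", "data.frame")
  # hand BH: q = (0.04, 0.04, 0.04, 0.04) -> all selected, ordered by v
  expect_equal(tab$q_value, rep(0.04, 4))
  sel <- significant_features(tab, alpha = 0.05)
  expect_equal(sel$feature, c("b", "a", "c", "d"))

  tab$q_value <- rep(1, 4)
  expect_equal(nrow(significant_features(tab)), 0L)

  tab1 <- tab[1, ]; tab1$p_value <- 0.03; tab1$q_value <- 0.03
  expect_equal(significant_features(tab1)$feature, "a")
})
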