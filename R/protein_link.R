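#' Transform fluorescence intensities
#'
#' Flow-cytometry intensities span decades; the default inverse hyperbolic
#' sine with a cofactor behaves like a log at high intensity while staying
#' defined (and near-linear) around zero. All methods are monotone.
#'
#' @param x Non-negative finite intensities.
#' @param method `"asinh"` (default), `"log10p"` (`log10(1 + x)`) or
#'   `"identity"`.
#' @param cofactor Divisor for the asinh transform. Default 150.
#' @return Transformed values, same length and order.
#' @export
transform_intensity <- function(x, method = c("asinh", "log10p", "identity"),
                                cofactor = 150) {
  method <- match.arg(method)
  assert_that(all(is.finite(x)), "intensities must be finite")
  assert_that(all(x >= 0), "intensities must be non-negative")
  switch(method,
         asinh = asinh(x / cofactor),
         log10p = log10(1 + x),
         identity = x)
}

#' Assign cells to stain groups
#'
#' Either labels cells by explicit cutpoints on the transformed intensity
#' (the default, mirroring gates drawn on the sorter), or fits a 1-D k-means
#' with deterministic seeded initialisation and orders the cluster labels by
#' cluster mean.
#'
#' @param table An `index_sort_table` (or data.frame with `cell_id` and the
#'   channel column).
#' @param channel Channel column name.
#' @param method `"thresholds"` or `"kmeans1d"`.
#' @param cutpoints Increasing numeric cutpoints on the *transformed* scale
#'   (thresholds mode); `length(cutpoints) + 1` groups.
#' @param k Number of clusters (kmeans1d mode).
#' @param labels Ordered group labels, lowest first; defaults to
#'   `negative/low/high` for 3 groups, `group_1..k` otherwise.
#' @param transform,cofactor Passed to [transform_intensity()].
#' @param seed Integer seed (kmeans1d mode).
#' @return data.frame of class `stain_groups`: `cell_id`, `intensity`
#'   (transformed), `group` (ordered factor); attributes record the method
#'   and its parameters.
#' @export
assign_stain_groups <- function(table, channel,
                                method = c("thresholds", "kmeans1d"),
                                cutpoints = NULL, k = 3L, labels = NULL,
                                transform = "asinh", cofactor = 150,
                                seed = 1L) {
  method <- match.arg(method)
  assert_that(channel %in% colnames(table),
              paste0("channel '", channel, "' not in table"))
  y <- transform_intensity(table[[channel]], transform, cofactor)
  if (method == "thresholds") {
    assert_that(!is.null(cutpoints) && !is.unsorted(cutpoints),
                "thresholds mode needs increasing cutpoints")
    n_groups <- length(cutpoints) + 1L
    grp <- findInterval(y, cutpoints) + 1L
  } else {
    assert_that(length(unique(y)) >= k,
                "k exceeds the number of distinct intensities")
    n_groups <- k
    centers <- with_substream(seed, 51L, {
      init <- quantile(y, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      km <- kmeans(y, centers = matrix(init, ncol = 1), iter.max = 100L)
      km
    })
    ord <- order(centers$centers[, 1])
    grp <- match(centers$cluster, ord)
  }
  if (is.null(labels)) {
    labels <- if (n_groups == 3L) c("negative", "low", "high")
              else paste0("group_", seq_len(n_groups))
  }
  assert_that(length(labels) == n_groups, "labels length must match groups")
  out <- data.frame(cell_id = table$cell_id, intensity = y,
                    group = factor(labels[grp], levels = labels, ordered = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "channel") <- channel
  attr(out, "method") <- method
  attr(out, "cutpoints") <- cutpoints
  attr(out, "transform") <- transform
  class(out) <- c("stain_groups", "data.frame")
  out
}

#' Correlate protein intensity with deviation z-scores
#'
#' Per feature, the Pearson correlation between the (transformed) protein
#' intensity and the deviation z-score across cells with defined entries,
#' with a two-sided p-value from the t distribution on n - 2 degrees of
#' freedom, BH-adjusted across features.
#'
#' @param dev A [corrected_deviations()] result or a feature-by-cell z
#'   matrix.
#' @param intensities Named (by cell id) or column-aligned intensity vector.
#' @param alpha Significance level recorded for convenience. Default 0.05.
#' @return data.frame of class `correlation_table`: `feature`, `r`,
#'   `p_value`, `q_value`, `n`, `significant`.
#' @export
correlate_protein_deviation <- function(dev, intensities, alpha = 0.05) {
  z <- if (inherits(dev, "deviation_matrix")) dev$z else dev
  x <- align_cells(intensities, colnames(z))
  assert_that(length(x) >= 10L, "need at least 10 cells")
  assert_that(sd(x) > 0, "intensity has zero variance")
  n_feat <- nrow(z)
  r <- p <- rep(NA_real_, n_feat)
  n_used <- integer(n_feat)
  for (k in seq_len(n_feat)) {
    ok <- !is.na(z[k, ])
    n <- sum(ok)
    n_used[k] <- n
    if (n < 3L || sd(z[k, ok]) == 0) next
    rk <- cor(x[ok], z[k, ok])
    tt <- rk * sqrt((n - 2) / max(1 - rk^2, 1e-300))
    r[k] <- rk
    p[k] <- 2 * pt(-abs(tt), df = n - 2)
  }
  q <- rep(NA_real_, n_feat)
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- data.frame(feature = rownames(z), r = r, p_value = p, q_value = q,
                    n = n_used, significant = !is.na(q) & q < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("correlation_table", "data.frame")
  out
}

align_cells <- function(x, cells) {
  if (!is.null(names(x))) {
    idx <- match(cells, names(x))
    assert_that(!anyNA(idx), "intensities missing for some cells")
    x <- x[idx]
  } else {
    assert_that(length(x) == length(cells),
                "unnamed intensities must align with z columns")
  }
  as.numeric(x)
}

#' Wilcoxon rank-sum comparisons of deviations between stain groups
#'
#' Two-sided rank-sum test per (feature, group pair): exact distribution when
#' both groups have at most 10 cells and no ties, normal approximation with
#' continuity correction otherwise. BH adjustment over one pooled family of
#' all features x pairs.
#'
#' @param dev A [corrected_deviations()] result or z matrix.
#' @param groups A [assign_stain_groups()] result covering the z columns.
#' @param features Optional subset of feature names. Default all.
#' @return data.frame of class `group_comparison`: `feature`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `delta_median`, `p_value`, `q_value`.
#' @export
compare_stain_groups <- function(dev, groups, features = NULL) {
  z <- if (inherits(dev, "deviation_matrix")) dev$z else dev
  if (!is.null(features)) {
    assert_that(all(features %in% rownames(z)), "unknown feature name(s)")
    z <- z[features, , drop = FALSE]
  }
  g <- groups$group[match(colnames(z), groups$cell_id)]
  assert_that(!anyNA(g), "stain groups missing for some cells")
  lev <- levels(droplevels(g))
  assert_that(length(lev) >= 2L, "need at least two non-empty groups")
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  rows <- list()
  for (k in seq_len(nrow(z))) {
    for (pr in pairs) {
      ia <- which(g == pr[1] & !is.na(z[k, ]))
      ib <- which(g == pr[2] & !is.na(z[k, ]))
      if (length(ia) < 3L || length(ib) < 3L) {
        stop("group ", pr[which.min(c(length(ia), length(ib)))],
             " has fewer than 3 usable cells for feature ", rownames(z)[k],
             call. = FALSE)
      }
      za <- z[k, ia]; zb <- z[k, ib]
      exact <- length(za) <= 10L && length(zb) <= 10L &&
        !anyDuplicated(c(za, zb))
      wt <- suppressWarnings(wilcox.test(za, zb, exact = exact,
                                         correct = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = rownames(z)[k], group_a = pr[1], group_b = pr[2],
        n_a = length(za), n_b = length(zb),
        delta_median = median(za) - median(zb),
        p_value = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Hartigans' dip test of unimodality
#'
#' The dip statistic is the maximum distance between the empirical CDF and
#' the closest unimodal CDF (greatest convex minorant / least concave
#' majorant construction). The p-value is the fraction of `n_boot` uniform
#' samples of the same size whose dip is at least the observed one, the
#' calibration Hartigan & Hartigan recommend.
#'
#' @param values Numeric sample, n >= 4.
#' @param n_boot Bootstrap replicates for the null. Default 2000.
#' @param seed Integer seed.
#' @return List of class `dip_result`: `dip`, `p_value`, `n`, `n_boot`,
#'   `seed`.
#' @export
dip_test <- function(values, n_boot = 2000L, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) stop("dip test needs at least 4 observations", call. = FALSE)
  d <- dip_stat(values)
  null_d <- with_substream(seed, 61L, {
    vapply(seq_len(n_boot), function(i) dip_stat(runif(n)), numeric(1))
  })
  structure(list(dip = d, p_value = mean(null_d >= d), n = n,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigans' dip test: dip = %.4f, p = %.4f (n = %d, %d bootstrap draws)\n",
              x$dip, x$p_value, x$n, x$n_boot))
  invisible(x)
}

#' Dip statistic
#'
#' @param values Numeric sample, n >= 4.
#' @return The dip statistic (a number in `[1/(2n), 1/4]`).
#' @export
dip_stat <- function(values) {
  x <- sort(as.numeric(values[!is.na(values)]))
  if (length(x) < 4L) stop("dip statistic needs at least 4 observations",
                           call. = FALSE)
  dip_stat_cpp(x)
}

#' Down-sampled variability distributions per stain group
#'
#' Removes the artifact of unequal group sizes: for each simulation,
#' `target_n` cells are drawn without replacement from every group and the
#' per-feature variability is recomputed on that subset of z-scores.
#'
#' @param dev A [corrected_deviations()] result or z matrix.
#' @param groups A [assign_stain_groups()] result.
#' @param target_n Cells per group per simulation. Default 42.
#' @param n_sim Number of simulations. Default 100.
#' @param seed Integer seed.
#' @return data.frame of class `downsampled_variability`: per (group,
#'   feature) the `median`, `lo` and `hi` (central 90% interval) of the
#'   down-sampled variability, plus `n_sim`, `target_n`.
#' @export
downsampled_variability <- function(dev, groups, target_n = 42L,
                                    n_sim = 100L, seed = 1L) {
  z <- if (inherits(dev, "deviation_matrix")) dev$z else dev
  g <- groups$group[match(colnames(z), groups$cell_id)]
  assert_that(!anyNA(g), "stain groups missing for some cells")
  lev <- levels(droplevels(g))
  sizes <- table(g)[lev]
  small <- lev[sizes < target_n]
  if (length(small)) {
    stop("group(s) ", paste(small, collapse = ", "), " smaller than target_n = ",
         target_n, call. = FALSE)
  }
  rows <- list()
  with_substream(seed, 71L, {
    for (lv in lev) {
      cells <- which(g == lv)
      vmat <- matrix(NA_real_, nrow(z), n_sim)
      for (s in seq_len(n_sim)) {
        pick <- cells[sample.int(length(cells), target_n)]
        vmat[, s] <- apply(z[, pick, drop = FALSE], 1, sd, na.rm = TRUE)
      }
      qs <- t(apply(vmat, 1, quantile, probs = c(0.5, 0.05, 0.95),
                    na.rm = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        group = lv, feature = rownames(z), median = qs[, 1], lo = qs[, 2],
        hi = qs[, 3], stringsAsFactors = FALSE, row.names = NULL)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "target_n") <- target_n
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  class(out) <- c("downsampled_variability", "data.frame")
  out
}

#' Chi-squared enrichment of stain labels in cell subgroups
#'
#' For every (subgroup, label) pair a 2x2 table (in/out of subgroup x
#' label/other) is tested by Pearson chi-squared without continuity
#' correction; BH adjustment across all tested tables. Tables with a zero
#' expected cell are flagged and not tested.
#'
#' @param subgroups Per-cell subgroup labels (named by cell id, or aligned
#'   with `labels`).
#' @param labels Per-cell stain labels.
#' @return data.frame of class `enrichment_table`: `subgroup`, `label`,
#'   `n_in`, `n_label_in`, `prop_label_in`, `chisq`, `p_value`, `q_value`,
#'   `tested`.
#' @export
subgroup_enrichment <- function(subgroups, labels) {
  if (!is.null(names(subgroups)) && !is.null(names(labels))) {
    labels <- labels[match(names(subgroups), names(labels))]
  }
  assert_that(length(subgroups) == length(labels),
              "subgroups and labels must align")
  sg <- as.character(subgroups); lb <- as.character(labels)
  assert_that(length(unique(sg)) >= 2L, "need at least 2 subgroups")
  assert_that(length(unique(lb)) >= 2L, "need at least 2 labels")
  rows <- list()
  for (s in sort(unique(sg))) {
    for (l in sort(unique(lb))) {
      t11 <- sum(sg == s & lb == l); t12 <- sum(sg == s & lb != l)
      t21 <- sum(sg != s & lb == l); t22 <- sum(sg != s & lb != l)
      tab <- matrix(c(t11, t21, t12, t22), 2)
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      tested <- all(expd > 0)
      if (tested) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        chisq <- unname(ct$statistic); p <- ct$p.value
      } else {
        chisq <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = s, label = l, n_in = t11 + t12, n_label_in = t11,
        prop_label_in = if (t11 + t12 > 0) t11 / (t11 + t12) else NA_real_,
        chisq = chisq, p_value = p, tested = tested,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  out$q_value[out$tested] <- bh_adjust(out$p_value[out$tested])
  class(out) <- c("enrichment_table", "data.frame")
  out
}
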