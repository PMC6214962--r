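#' Expected fragment counts under the depth-and-popularity null
#'
#' The expectation for peak i in cell j is
#' `E_ij = (row_i total / grand total) * column_j total`, i.e. the cell's
#' depth spread over peaks proportional to each peak's overall popularity.
#' Column sums of E equal the observed column sums exactly.
#'
#' Note the result is a dense rank-1 matrix; downstream deviation code uses
#' the factored form and never materialises it, so this function is intended
#' for small matrices and for checking.
#'
#' @param X Peak-by-cell count matrix (sparse or dense).
#' @return Dense matrix E of the same dimension.
#' @export
expected_counts <- function(X) {
  total <- sum(X)
  assert_that(total > 0, "all-zero count matrix")
  r <- Matrix::rowSums(X) / total
  cs <- Matrix::colSums(X)
  E <- outer(as.numeric(r), as.numeric(cs))
  dimnames(E) <- dimnames(X)
  E
}

# factored expectation pieces shared by the deviation computations
expectation_parts <- function(X) {
  total <- sum(X)
  assert_that(total > 0, "all-zero count matrix")
  list(r = as.numeric(Matrix::rowSums(X)) / total,
       cs = as.numeric(Matrix::colSums(X)))
}

#' Raw per-feature accessibility deviations
#'
#' For feature k and cell j the raw deviation is
#' `Y_kj = (obs_kj - exp_kj) / exp_kj`, where `obs` sums the observed counts
#' over the feature's member peaks and `exp` sums the expectations from
#' [expected_counts()]. Entries with zero expected counts are flagged
#' undefined (`NA`), never silently zeroed.
#'
#' @param X Peak-by-cell count matrix.
#' @param M Peak-by-feature membership matrix (0/1, possibly with
#'   multiplicities for background sets).
#' @param E Optional precomputed expectation (dense); by default the factored
#'   form is used.
#' @return Feature-by-cell matrix of raw deviations with `NA` where
#'   undefined.
#' @export
raw_deviations <- function(X, M, E = NULL) {
  M <- methods::as(Matrix::Matrix(M, sparse = TRUE), "CsparseMatrix")
  assert_that(nrow(M) == nrow(X), "M and X disagree on the number of peaks")
  if (any(Matrix::colSums(M != 0) == 0)) {
    stop("feature with zero member peaks; prune the annotation first",
         call. = FALSE)
  }
  obs <- as.matrix(Matrix::t(M) %*% X)
  if (is.null(E)) {
    parts <- expectation_parts(X)
    mr <- as.numeric(Matrix::t(M) %*% parts$r)   # features
    expc <- outer(mr, parts$cs)                  # features x cells
  } else {
    expc <- as.matrix(Matrix::t(M) %*% E)
  }
  Y <- (obs - expc) / expc
  Y[expc == 0] <- NA_real_
  rownames(Y) <- colnames(M)
  colnames(Y) <- colnames(X)
  Y
}

#' Sample GC- and accessibility-matched background peaks
#'
#' Standardises `(gc, log1p(mean_access))` to zero mean and unit variance,
#' then, for every peak and every background iteration, samples uniformly
#' (with replacement across iterations) from the peak's `k_nn` nearest peaks
#' in that 2-D space (self allowed). A feature's background set at iteration
#' b is the multiset of background draws of its member peaks, so background
#' sets automatically have the member set's size and covariate profile.
#' Peaks with undefined GC (all-ambiguous sequence) are never sampled as
#' backgrounds; if such a peak needs a background it draws uniformly from
#' the defined peaks.
#'
#' @param peaks A [peak_set()] with `gc` and `mean_access` computed.
#' @param B Number of background iterations. Default 50.
#' @param k_nn Neighbourhood size; clamped (with a warning) to the number of
#'   GC-defined peaks. Default 250. Setting `k_nn` to the total number of
#'   peaks makes the sampling uniform, i.e. a deliberately unmatched
#'   (GC-blind) background for control runs.
#' @param seed Integer seed; sampling is fully deterministic given it.
#' @return Object of class `background_sets`: list with `idx` (peaks x B
#'   integer matrix of background peak indices), `B`, `k_nn`, `seed` and the
#'   standardisation parameters.
#' @export
sample_background_peaks <- function(peaks, B = 50L, k_nn = 250L, seed = 1L) {
  assert_that(B >= 1L, "B must be >= 1")
  assert_that(k_nn >= 1L, "k_nn must be >= 1")
  n <- nrow(peaks)
  assert_that(all(!is.na(peaks$mean_access)),
              "mean_access missing; run compute_mean_access() first")
  defined <- which(!is.na(peaks$gc))
  assert_that(length(defined) >= 1L, "no peak has defined GC")
  if (k_nn > length(defined)) {
    warning("k_nn larger than the number of GC-defined peaks; clamped to ",
            length(defined))
    k_nn <- length(defined)
  }
  z1 <- scale_or_zero(peaks$gc[defined])
  z2 <- scale_or_zero(log1p(peaks$mean_access[defined]))
  idx <- matrix(NA_integer_, nrow = n, ncol = B)
  with_substream(seed, 101L, {
    if (k_nn == length(defined)) {
      # neighbourhood covers every peak: sampling is uniform (the GC-blind
      # control configuration), no distances needed
      for (i in seq_len(n)) {
        idx[i, ] <- defined[sample.int(length(defined), B, replace = TRUE)]
      }
    } else {
      # brute-force kNN in 2-D, chunked to bound memory
      chunk <- 512L
      for (s in seq(1L, length(defined), by = chunk)) {
        e <- min(s + chunk - 1L, length(defined))
        d2 <- outer(z1[s:e], z1, "-")^2 + outer(z2[s:e], z2, "-")^2
        for (ii in seq_len(e - s + 1L)) {
          nn <- defined[order(d2[ii, ], method = "radix")[seq_len(k_nn)]]
          idx[defined[s + ii - 1L], ] <- nn[sample.int(k_nn, B, replace = TRUE)]
        }
      }
      undef <- setdiff(seq_len(n), defined)
      for (i in undef) {
        idx[i, ] <- defined[sample.int(length(defined), B, replace = TRUE)]
      }
    }
  })
  structure(list(idx = idx, B = as.integer(B), k_nn = as.integer(k_nn),
                 seed = as.integer(seed),
                 standardization = list(
                   gc_mean = mean(peaks$gc[defined]),
                   gc_sd = sd(peaks$gc[defined]),
                   access_mean = mean(log1p(peaks$mean_access[defined])),
                   access_sd = sd(log1p(peaks$mean_access[defined])))),
            class = "background_sets")
}

scale_or_zero <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

# membership matrix for background iteration b: member peak i of feature k is
# replaced by its background draw idx[i, b], keeping multiplicities
background_membership <- function(M, bg, b) {
  tm <- methods::as(methods::as(M, "CsparseMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = bg$idx[tm@i + 1L, b], j = tm@j + 1L, x = tm@x,
                       dims = dim(M), dimnames = dimnames(M))
}

#' Bias-corrected deviations and z-scores
#'
#' For each feature the raw deviation is centred by the mean raw deviation of
#' its B matched background sets and scaled by their standard deviation
#' (n-1 denominator):
#' `z_kj = (Y_kj - mean_b Ytilde^b_kj) / sd_b(Ytilde^b_kj)`.
#' Entries whose background standard deviation is zero, or whose expected
#' counts are zero, are flagged undefined.
#'
#' @param X Peak-by-cell count matrix.
#' @param M Peak-by-feature membership matrix.
#' @param bg A [sample_background_peaks()] result (B >= 2).
#' @return Object of class `deviation_matrix`: list with feature-by-cell
#'   matrices `raw`, `corrected`, `z`, logical `undefined`, and the
#'   background parameters.
#' @export
corrected_deviations <- function(X, M, bg) {
  assert_that(inherits(bg, "background_sets"), "bg must be background_sets")
  assert_that(bg$B >= 2L, "at least 2 background iterations are required")
  assert_that(nrow(bg$idx) == nrow(X), "background sets and X disagree on peaks")
  M <- methods::as(Matrix::Matrix(M, sparse = TRUE), "CsparseMatrix")
  Y <- raw_deviations(X, M)
  sum_b <- matrix(0, nrow(Y), ncol(Y))
  sumsq_b <- matrix(0, nrow(Y), ncol(Y))
  any_na <- matrix(FALSE, nrow(Y), ncol(Y))
  # background iterations are independent sparse products; stack a chunk of
  # iterations into one wide membership matrix and multiply once
  parts <- expectation_parts(X)
  tm <- methods::as(M, "TsparseMatrix")
  i0 <- tm@i + 1L; j0 <- tm@j + 1L; x0 <- tm@x
  K <- ncol(M)
  chunk <- max(1L, min(bg$B, as.integer(ceiling(2e6 / max(1, K * ncol(X))))))
  for (b0 in seq(1L, bg$B, by = chunk)) {
    bs <- b0:min(b0 + chunk - 1L, bg$B)
    Mall <- Matrix::sparseMatrix(
      i = as.vector(bg$idx[i0, bs, drop = FALSE]),
      j = rep(j0, times = length(bs)) +
        rep((seq_along(bs) - 1L) * K, each = length(j0)),
      x = rep(x0, times = length(bs)),
      dims = c(nrow(M), K * length(bs)))
    obs <- as.matrix(Matrix::t(Mall) %*% X)
    mr <- as.numeric(Matrix::t(Mall) %*% parts$r)
    expc <- outer(mr, parts$cs)
    Yb_all <- (obs - expc) / expc
    Yb_all[expc == 0] <- NA_real_
    for (bi in seq_along(bs)) {
      Yb <- Yb_all[(bi - 1L) * K + seq_len(K), , drop = FALSE]
      nab <- is.na(Yb)
      any_na <- any_na | nab
      Yb[nab] <- 0
      sum_b <- sum_b + Yb
      sumsq_b <- sumsq_b + Yb^2
    }
  }
  mean_b <- sum_b / bg$B
  var_b <- (sumsq_b - bg$B * mean_b^2) / (bg$B - 1)
  sd_b <- sqrt(pmax(var_b, 0))
  corrected <- Y - mean_b
  z <- corrected / sd_b
  undefined <- is.na(Y) | any_na | (sd_b == 0)
  corrected[undefined] <- NA_real_
  z[undefined] <- NA_real_
  structure(list(raw = Y, corrected = corrected, z = z,
                 undefined = undefined, B = bg$B, k_nn = bg$k_nn,
                 seed = bg$seed),
            class = "deviation_matrix")
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat("deviation_matrix: ", nrow(x$z), " features x ", ncol(x$z), " cells; B = ",
      x$B, ", k_nn = ", x$k_nn, "; ", sum(x$undefined),
      " undefined entries\n", sep = "")
  invisible(x)
}

#' Per-feature variability of deviation z-scores
#'
#' Variability is the standard deviation (n-1 denominator) of a feature's
#' z-scores over cells with defined entries; it is close to 1 when the
#' feature is no more variable than its matched background peaks. The default
#' significance test treats `(n-1) v^2` as chi-squared with `n-1` degrees of
#' freedom under H0 `v = 1` (upper tail); `method = "background"` instead
#' compares the observed variability with the variabilities of the feature's
#' own background-set deviations (requires `bg`, `X`, `M`).
#'
#' @param dev A [corrected_deviations()] result.
#' @param method `"chisq"` (default) or `"background"`.
#' @param X,M,bg Only for `method = "background"`: the inputs used for `dev`.
#' @return data.frame of class `variability_table`: `feature`, `variability`,
#'   `p_value`, `q_value`, `n_cells`, ordered as the input features.
#' @export
motif_variability <- function(dev, method = c("chisq", "background"),
                              X = NULL, M = NULL, bg = NULL) {
  method <- match.arg(method)
  z <- dev$z
  n_cells <- rowSums(!is.na(z))
  v <- apply(z, 1, sd, na.rm = TRUE)
  v[n_cells < 2] <- NA_real_
  p <- rep(NA_real_, nrow(z))
  usable <- n_cells >= 3
  if (method == "chisq") {
    p[usable] <- pchisq((n_cells[usable] - 1) * v[usable]^2,
                        df = n_cells[usable] - 1, lower.tail = FALSE)
  } else {
    assert_that(!is.null(X) && !is.null(M) && !is.null(bg),
                "background method needs X, M and bg")
    vb <- background_variabilities(X, M, bg)
    for (k in which(usable)) {
      p[k] <- (1 + sum(vb[k, ] >= v[k])) / (ncol(vb) + 1)
    }
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- data.frame(feature = rownames(z), variability = v, p_value = p,
                    q_value = q, n_cells = n_cells,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("variability_table", "data.frame")
  out
}

# variability of each background iteration's z-analogue: centre/scale each
# background set's raw deviation by the remaining sets (leave-one-out mean/sd)
background_variabilities <- function(X, M, bg) {
  M <- methods::as(Matrix::Matrix(M, sparse = TRUE), "CsparseMatrix")
  Yb_all <- vector("list", bg$B)
  for (b in seq_len(bg$B)) {
    Yb_all[[b]] <- raw_deviations(X, background_membership(M, bg, b))
  }
  sum_b <- Reduce(`+`, lapply(Yb_all, function(m) { m[is.na(m)] <- 0; m }))
  sumsq_b <- Reduce(`+`, lapply(Yb_all, function(m) { m[is.na(m)] <- 0; m^2 }))
  vapply(seq_len(bg$B), function(b) {
    Yb <- Yb_all[[b]]
    mean_loo <- (sum_b - ifelse(is.na(Yb), 0, Yb)) / (bg$B - 1)
    ss_loo <- sumsq_b - ifelse(is.na(Yb), 0, Yb)^2
    var_loo <- (ss_loo - (bg$B - 1) * mean_loo^2) / (bg$B - 2)
    zb <- (Yb - mean_loo) / sqrt(pmax(var_loo, 1e-12))
    apply(zb, 1, sd, na.rm = TRUE)
  }, numeric(ncol(M)))
}

#' Select significantly variable features
#'
#' @param tab A [motif_variability()] table.
#' @param alpha BH-adjusted q-value cutoff. Default 0.05.
#' @return The subset of `tab` with `q_value < alpha`, ordered by
#'   variability descending.
#' @export
significant_features <- function(tab, alpha = 0.05) {
  keep <- !is.na(tab$q_value) & tab$q_value < alpha
  out <- tab[keep, , drop = FALSE]
  out <- out[order(-out$variability), , drop = FALSE]
  rownames(out) <- NULL
  out
}
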