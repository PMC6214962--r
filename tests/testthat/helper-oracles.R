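# Independent oracles, written against the definitions rather than the
# package's implementation paths.

# Brute-force bias-corrected deviations: explicit loops over features,
# background iterations and cells.
oracle_corrected_deviations <- function(X, M, bg) {
  X <- as.matrix(X)
  M <- as.matrix(M)
  n_ft <- ncol(M)
  n_cl <- ncol(X)
  total <- sum(X)
  r <- rowSums(X) / total
  cs <- colSums(X)
  rawdev <- function(members) {
    vapply(seq_len(n_cl), function(j) {
      e <- sum(r[members]) * cs[j]
      if (e == 0) NA_real_ else (sum(X[members, j]) - e) / e
    }, numeric(1))
  }
  raw <- corrected <- z <- matrix(NA_real_, n_ft, n_cl)
  for (k in seq_len(n_ft)) {
    mem <- rep(seq_len(nrow(M)), times = M[, k])
    Y <- rawdev(mem)
    Yb <- matrix(NA_real_, bg$B, n_cl)
    for (b in seq_len(bg$B)) {
      Yb[b, ] <- rawdev(bg$idx[mem, b])
    }
    mb <- colMeans(Yb)
    sb <- apply(Yb, 2, sd)
    raw[k, ] <- Y
    corrected[k, ] <- Y - mb
    z[k, ] <- (Y - mb) / sb
  }
  list(raw = raw, corrected = corrected, z = z)
}

# random small count-matrix instance with annotation, for oracle comparisons
random_tiny_instance <- function(seed, max_peaks = 20L, max_cells = 10L,
                                 max_features = 5L) {
  set.seed(seed)
  n_pk <- sample(5:max_peaks, 1)
  n_cl <- sample(4:max_cells, 1)
  n_ft <- sample(2:max_features, 1)
  X <- matrix(rpois(n_pk * n_cl, lambda = 3), n_pk, n_cl)
  X[1, ] <- X[1, ] + 1  # guard against an all-zero matrix
  dimnames(X) <- list(sprintf("p%02d", 1:n_pk), sprintf("c%02d", 1:n_cl))
  M <- matrix(0, n_pk, n_ft,
              dimnames = list(rownames(X), sprintf("f%02d", 1:n_ft)))
  for (k in 1:n_ft) M[sample(n_pk, sample(2:4, 1)), k] <- 1
  peaks <- peak_set(chrom = "chrT", start = (1:n_pk - 1) * 1000,
                    end = (1:n_pk - 1) * 1000 + 500,
                    summit = (1:n_pk - 1) * 1000 + 250,
                    score = runif(n_pk, 1, 100), name = rownames(X),
                    gc = runif(n_pk, 0.3, 0.6))
  peaks$mean_access <- rowMeans(X)
  list(X = Matrix::Matrix(X, sparse = TRUE), M = Matrix::Matrix(M, sparse = TRUE),
       peaks = peaks)
}

# Exact dip oracle: bisection on t over the feasibility question "does a
# unimodal CDF lie within sup-distance t of the empirical CDF?", decided via
# convex/concave box-interpolation certificates. Independent of the C++
# modal-interval algorithm.
dip_oracle <- function(values, iters = 60L) {
  x <- sort(values)
  n <- length(x)
  u <- unique(x)
  P <- length(u)
  cnt <- cumsum(tabulate(match(x, u), nbins = P))
  feasible <- function(t) {
    lo <- pmax(cnt / n - t, 0)
    hi <- pmin(c(0, cnt[-P]) / n + t, 1)
    m <- rep(-Inf, P)
    for (j in seq_len(P)) if (j > 1) {
      m[j] <- max((lo[j] - hi[seq_len(j - 1)]) / (u[j] - u[seq_len(j - 1)]))
    }
    cert_at <- function(j, xq) lo[j] + max(m[j], 0) * (xq - u[j])
    minVal <- function(s, xq) {
      if (s == 0L) return(0)
      max(vapply(seq_len(s), cert_at, numeric(1), xq = xq))
    }
    cvxF <- function(s) {
      if (s >= 1L && any(lo[seq_len(s)] > hi[seq_len(s)] + 1e-12)) return(FALSE)
      if (s <= 1L) return(TRUE)
      hull <- c(1L)
      for (i in 2:s) {
        while (length(hull) >= 2L) {
          a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
          if ((hi[i] - hi[a]) * (u[b] - u[a]) <= (hi[b] - hi[a]) * (u[i] - u[a]))
            hull <- hull[-length(hull)] else break
        }
        hull <- c(hull, i)
      }
      hv <- approx(u[hull], hi[hull], xout = u[seq_len(s)])$y
      all(hv >= lo[seq_len(s)] - 1e-12)
    }
    w <- rep(-Inf, P)
    for (j in seq_len(P)) if (j < P) {
      w[j] <- max((lo[(j + 1):P] - hi[j]) / (u[(j + 1):P] - u[j]))
    }
    ccert_at <- function(j, xq) hi[j] - max(w[j], 0) * (u[j] - xq)
    maxVal <- function(p, xq, skip_hi_p = FALSE) {
      if (p > P) return(1)
      js <- p:P
      if (skip_hi_p) js <- js[js != p]
      if (length(js) == 0L) return(1)
      min(1, min(vapply(js, ccert_at, numeric(1), xq = xq)))
    }
    cavF <- function(p, skip_hi_p = FALSE) {
      if (p <= P) {
        js0 <- p:P
        if (skip_hi_p) js0 <- js0[js0 != p]
        if (length(js0) && any(lo[js0] > hi[js0] + 1e-12)) return(FALSE)
      }
      if (p >= P) return(TRUE)
      js <- p:P
      hull <- c(js[1])
      for (i in js[-1]) {
        while (length(hull) >= 2L) {
          a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
          if ((lo[i] - lo[a]) * (u[b] - u[a]) >= (lo[b] - lo[a]) * (u[i] - u[a]))
            hull <- hull[-length(hull)] else break
        }
        hull <- c(hull, i)
      }
      hv <- approx(u[hull], lo[hull], xout = u[js])$y
      chk <- hv <= hi[js] + 1e-12
      if (skip_hi_p) chk[1] <- TRUE
      all(chk)
    }
    for (s in 0:P) {
      if (!cvxF(s)) break
      if (!cavF(s + 1L)) next
      if (s == P) return(TRUE)
      ok1 <- minVal(s, u[s + 1L]) <= maxVal(s + 1L, u[s + 1L]) + 1e-12
      ok2 <- if (s >= 1L) minVal(s, u[s]) <= maxVal(s + 1L, u[s]) + 1e-12 else TRUE
      if (ok1 || ok2) return(TRUE)
    }
    for (p in seq_len(P)) {
      if (p >= 2L && !cvxF(p - 1L)) break
      if (!cavF(p, skip_hi_p = TRUE)) next
      v <- minVal(p - 1L, u[p])
      if (v <= hi[p] + 1e-12 && v <= maxVal(p, u[p], skip_hi_p = TRUE) + 1e-12)
        return(TRUE)
    }
    FALSE
  }
  lo_t <- 0
  hi_t <- 0.25
  for (i in seq_len(iters)) {
    mid <- (lo_t + hi_t) / 2
    if (feasible(mid)) hi_t <- mid else lo_t <- mid
  }
  hi_t
}
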