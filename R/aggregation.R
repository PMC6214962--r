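#' Aggregate cells into a pseudo-bulk profile
#'
#' @param X Peak-by-cell count matrix.
#' @param cells Character ids or integer indices of the cells to sum.
#' @return Named per-peak summed count vector.
#' @export
aggregate_cells <- function(X, cells) {
  assert_that(length(cells) >= 1L, "cell subset must be non-empty")
  if (is.character(cells)) {
    idx <- match(cells, colnames(X))
    if (anyNA(idx)) {
      stop("unknown cell id(s): ", paste(cells[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(cells)
    assert_that(all(idx >= 1L & idx <= ncol(X)), "cell index out of range")
  }
  setNames(as.numeric(Matrix::rowSums(X[, idx, drop = FALSE])), rownames(X))
}

#' Downsample a cell's fragments without replacement
#'
#' Multivariate hypergeometric draw of exactly `n` fragments from the cell's
#' per-peak counts, mirroring subsampling reads from an alignment.
#'
#' @param column Non-negative integer per-peak count vector.
#' @param n Number of fragments to keep. Default 500.
#' @param seed Integer seed (ignored when the total already equals `n`).
#' @return Integer vector of the same length summing exactly to `n`.
#' @export
subsample_fragments <- function(column, n = 500L, seed = 1L) {
  total <- sum(column)
  if (total < n) {
    stop("cell has ", total, " fragments, fewer than the requested ", n,
         call. = FALSE)
  }
  if (total == n) return(column)
  with_substream(seed, 41L, subsample_fragments_impl(column, n))
}

# internal: draw under the current RNG state (callers manage streams)
subsample_fragments_impl <- function(column, n) {
  total <- sum(column)
  cs <- cumsum(column)
  pos <- sample.int(total, n)
  peak <- findInterval(pos - 0.5, cs) + 1L
  out <- tabulate(peak, nbins = length(column))
  names(out) <- names(column)
  out
}

#' Information-content curve: aggregate-vs-bulk correlation by group size
#'
#' For each group size and each simulation, draws that many cells uniformly
#' without replacement, downsamples each cell to `frags` fragments in peaks
#' (equalising contribution), aggregates, and computes the Pearson
#' correlation (with p-value) against the bulk reference over all peaks.
#'
#' @param X Peak-by-cell count matrix.
#' @param bulk Per-peak bulk reference vector (same peak order).
#' @param sizes Group sizes. Default `c(5, 10, 20, 50, 100, 150)`.
#' @param n_sim Simulations per size. Default 1000.
#' @param frags Fragments retained per cell; cells with fewer are excluded
#'   from drawing. Default 500.
#' @param seed Integer seed.
#' @return data.frame of class `info_content_curve` in long format:
#'   `size`, `sim`, `r`, `p`.
#' @export
information_content_curve <- function(X, bulk, sizes = c(5, 10, 20, 50, 100, 150),
                                      n_sim = 1000L, frags = 500L, seed = 1L) {
  assert_that(length(bulk) == nrow(X), "bulk reference length must match peaks")
  Xd <- as.matrix(X)
  totals <- colSums(Xd)
  eligible <- which(totals >= frags)
  assert_that(length(eligible) >= 1L,
              paste0("no cell has >= ", frags, " fragments in peaks"))
  res <- list()
  with_substream(seed, 42L, {
    for (size in sizes) {
      if (size > length(eligible)) {
        warning("group size ", size, " exceeds the ", length(eligible),
                " eligible cells; skipped")
        next
      }
      r <- numeric(n_sim); p <- numeric(n_sim)
      for (s in seq_len(n_sim)) {
        pick <- eligible[sample.int(length(eligible), size)]
        agg <- rowSums(vapply(pick, function(j) {
          subsample_fragments_impl(Xd[, j], frags)
        }, numeric(nrow(Xd))))
        ct <- suppressWarnings(cor.test(agg, bulk, method = "pearson"))
        r[s] <- unname(ct$estimate); p[s] <- ct$p.value
      }
      res[[length(res) + 1L]] <- data.frame(size = size, sim = seq_len(n_sim),
                                            r = r, p = p)
    }
  })
  out <- do.call(rbind, res)
  attr(out, "n_sim") <- n_sim
  attr(out, "frags") <- frags
  attr(out, "seed") <- seed
  class(out) <- c("info_content_curve", "data.frame")
  out
}

#' @export
print.info_content_curve <- function(x, ...) {
  med <- vapply(split(x$r, x$size), median, numeric(1))
  cat("information-content curve (", attr(x, "n_sim"), " sims, ",
      attr(x, "frags"), " fragments/cell)\n", sep = "")
  cat("  median Pearson r by group size:\n")
  for (s in names(med)) cat(sprintf("    %5s cells: %.3f\n", s, med[[s]]))
  invisible(x)
}

#' Mimic single cells from a bulk profile
#'
#' Each mimic cell is an independent multinomial draw of `frags` fragments
#' from the bulk per-peak proportions (bulk depth is much larger than
#' `frags`, so with- vs without-replacement is immaterial).
#'
#' @param bulk Per-peak bulk count vector.
#' @param n_cells Number of mimic cells. Default 50.
#' @param frags Fragments per mimic cell. Default 500.
#' @param seed Integer seed.
#' @return Sparse peak-by-cell count matrix with columns `mimic_##`.
#' @export
mimic_cells_from_bulk <- function(bulk, n_cells = 50L, frags = 500L,
                                  seed = 1L) {
  assert_that(sum(bulk) >= frags, "bulk total smaller than frags")
  pr <- bulk / sum(bulk)
  m <- with_substream(seed, 43L, rmultinom(n_cells, frags, pr))
  dimnames(m) <- list(names(bulk), sprintf("mimic_%02d", seq_len(n_cells)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}
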