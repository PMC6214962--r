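make_peaks <- function(start, end, score = seq_along(start), chrom = "chr1") {
  peak_set(chrom = chrom, start = start, end = end,
           summit = (start + end) %/% 2L, score = score,
           name = sprintf("pk%03d", seq_along(start)))
}

test_that("region filtering removes 1-bp overlaps and respects half-open ends", {
  peaks <- make_peaks(100L, 600L)
  expect_equal(nrow(filter_regions(peaks,
    data.frame(chrom = "chr1", start = 599L, end = 700L))), 0L)
  expect_equal(nrow(filter_regions(peaks,
    data.frame(chrom = "chr1", start = 600L, end = 700L))), 1L)
  expect_equal(filter_regions(peaks, list()), peaks)
  # multiple exclusion lists act jointly
  peaks2 <- make_peaks(c(0L, 1000L, 2000L), c(500L, 1500L, 2500L))
  kept <- filter_regions(peaks2, list(
    data.frame(chrom = "chr1", start = 10L, end = 20L),
    data.frame(chrom = "chr1", start = 2400L, end = 2600L)))
  expect_equal(kept$name, "pk002")
})

test_that("summit-centred selection windows, ranks and resolves overlaps", {
  p <- peak_set(chrom = "chr1", start = 1100L, end = 1400L, summit = 1250L,
                score = 10, name = "pk")
  out <- select_summit_peaks(p, width = 500L, top_n = 10L)
  expect_equal(c(out$start, out$end), c(1000L, 1500L))
  expect_error(select_summit_peaks(p, width = 501L), "even")

  # top_n keeps exactly the best-scoring peaks before overlap resolution
  n <- 600L
  far <- peak_set(chrom = "chr1", start = (1:n) * 2000L,
                  end = (1:n) * 2000L + 400L, summit = (1:n) * 2000L + 200L,
                  score = sample(n), name = sprintf("pk%03d", 1:n))
  out2 <- select_summit_peaks(far, width = 500L, top_n = 500L)
  expect_equal(nrow(out2), 500L)
  expect_setequal(out2$name, far$name[order(-far$score)][1:500])

  # two summits 100 bp apart: only the better-scoring window survives
  near <- peak_set(chrom = "chr1", start = c(1000L, 1100L),
                   end = c(1400L, 1500L), summit = c(1200L, 1300L),
                   score = c(5, 9), name = c("lo", "hi"))
  out3 <- select_summit_peaks(near, width = 500L, top_n = 10L)
  expect_equal(out3$name, "hi")

  # greedy resolution follows score order (oracle on a sorted list)
  set.seed(21)
  chain <- peak_set(chrom = "chr1", start = (0:49) * 300L,
                    end = (0:49) * 300L + 200L, summit = (0:49) * 300L + 100L,
                    score = runif(50), name = sprintf("c%02d", 0:49))
  out4 <- select_summit_peaks(chain, width = 500L, top_n = 50L)
  ord <- order(-chain$score, chain$chrom, chain$summit - 250L)
  keep <- character()
  kept_iv <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    s <- chain$summit[i] - 250L; e <- chain$summit[i] + 250L
    if (s < 0) next  # windows running off the chromosome start are dropped
    if (!nrow(kept_iv) || all(e <= kept_iv[, 1] | s >= kept_iv[, 2])) {
      keep <- c(keep, chain$name[i])
      kept_iv <- rbind(kept_iv, c(s, e))
    }
  }
  expect_setequal(out4$name, keep)
})

test_that("fragment counting matches a hand tally and keeps per-cell totals", {
  peaks <- peak_set(chrom = "chr1", start = c(1000L, 3000L),
                    end = c(1500L, 3500L), summit = c(1250L, 3250L),
                    score = c(1, 2), name = c("pkA", "pkB"))
  frags <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1100L, 1499L, 3100L, 9000L, 1200L, 1200L),
    end   = c(1200L, 1600L, 3200L, 9100L, 1300L, 1300L),
    cell_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    stringsAsFactors = FALSE)
  out <- count_fragments_in_peaks(frags, peaks)
  expect_equal(as.matrix(out$counts),
               matrix(c(2, 0, 0, 1, 1, 0), 2,
                      dimnames = list(c("pkA", "pkB"), c("c1", "c2", "c3"))))
  expect_equal(out$totals, c(c1 = 2L, c2 = 2L, c3 = 2L))

  overlapping <- peak_set(chrom = "chr1", start = c(1000L, 1200L),
                          end = c(1500L, 1700L), summit = c(1250L, 1450L),
                          score = c(1, 2), name = c("a", "b"))
  expect_error(count_fragments_in_peaks(frags, overlapping),
               "select_summit_peaks")
})

test_that("species classification applies the fragment and purity cutoffs", {
  counts <- data.frame(cell_id = c("w1", "w2", "w3", "w4"),
                       human = c(480L, 990L, 520L, 40L),
                       mouse = c(0L, 10L, 480L, 960L))
  calls <- classify_species(counts, min_fragments = 500L, purity = 0.96)
  expect_equal(calls$label, c("low_quality", "human", "hybrid", "mouse"))
  expect_equal(calls$n_fragments_total, c(480L, 1000L, 1000L, 1000L))
})

test_that("the cell filter implements the 0.5 x median FRiP rule exactly", {
  # cohort engineered so the median FRiP over eligible cells is 0.4
  frip <- c(0.5, 0.4, 0.3, 0.19, 0.21, 0.9)
  totals <- c(1000, 1000, 1000, 1000, 1000, 499)
  in_peaks <- frip * totals
  counts <- Matrix::Matrix(diag(in_peaks), sparse = TRUE)
  dimnames(counts) <- list(sprintf("pk%d", 1:6), sprintf("cell%d", 1:6))
  totals <- setNames(totals, colnames(counts))
  qcr <- filter_cells(counts, totals, min_fragments = 500L, frip_factor = 0.5)
  # eligible FRiPs are 0.5 0.4 0.3 0.19 0.21 -> median 0.3, cutoff 0.15;
  # cell6 fails on fragments alone despite FRiP 0.9
  expect_equal(attr(qcr, "median_frip"), 0.3)
  expect_equal(qcr$pass, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))

  # a cohort whose median is 0.4 checks the 0.19 / 0.21 boundary
  frip2 <- c(0.4, 0.4, 0.4, 0.19, 0.21)
  t2 <- rep(1000, 5)
  counts2 <- Matrix::Matrix(diag(frip2 * t2), sparse = TRUE)
  dimnames(counts2) <- list(sprintf("p%d", 1:5), sprintf("c%d", 1:5))
  qcr2 <- filter_cells(counts2, setNames(t2, colnames(counts2)))
  expect_equal(attr(qcr2, "median_frip"), 0.4)
  expect_equal(qcr2$pass, c(TRUE, TRUE, TRUE, FALSE, TRUE))

  # identical cells all pass (FRiP equals the median)
  counts3 <- Matrix::Matrix(matrix(rep(200, 8), 2), sparse = TRUE)
  dimnames(counts3) <- list(c("p1", "p2"), sprintf("c%d", 1:4))
  qcr3 <- filter_cells(counts3, setNames(rep(800, 4), colnames(counts3)))
  expect_true(all(qcr3$pass))

  expect_error(filter_cells(counts3, setNames(rep(450, 4), colnames(counts3))),
               "cohort unusable")
})

test_that("the cell filter is invariant to cell order and zero-row duplication", {
  set.seed(77)
  n <- 30
  counts <- Matrix::Matrix(matrix(rpois(20 * n, 5), 20, n), sparse = TRUE)
  dimnames(counts) <- list(sprintf("p%02d", 1:20), sprintf("c%02d", 1:n))
  totals <- setNames(Matrix::colSums(counts) + rpois(n, 400) + 300,
                     colnames(counts))
  rep1 <- filter_cells(counts, totals)
  perm <- sample(n)
  rep2 <- filter_cells(counts[, perm], totals)
  expect_equal(rep2$pass[match(rep1$cell_id, rep2$cell_id)], rep1$pass)
  # appending all-zero peak rows changes nothing
  zeros <- Matrix::Matrix(0, 5, n, sparse = TRUE,
                          dimnames = list(sprintf("z%d", 1:5), colnames(counts)))
  rep3 <- filter_cells(rbind(counts, zeros), totals)
  expect_equal(rep3$pass, rep1$pass)
})
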