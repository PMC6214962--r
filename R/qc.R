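#' Remove peaks overlapping exclusion regions
#'
#' Drops any peak overlapping (by at least 1 bp) an interval in any of the
#' supplied exclusion lists, e.g. the ENCODE blacklist and nuclear
#' mitochondrial (NumtS) regions.
#'
#' @param peaks A [peak_set()].
#' @param exclude A single data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or a list of them, as read by [read_bed()].
#' @return The filtered peak set.
#' @export
filter_regions <- function(peaks, exclude) {
  if (is.data.frame(exclude)) exclude <- list(exclude)
  if (length(exclude) == 0L) return(peaks)
  ex <- do.call(rbind, lapply(exclude, function(b) b[, c("chrom", "start", "end")]))
  if (nrow(ex) == 0L) return(peaks)
  ex_gr <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start + 1L, ex$end))
  hits <- GenomicRanges::findOverlaps(peaks_granges(peaks), ex_gr,
                                      minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) peaks <- peaks[-drop, , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Summit-centred fixed-width peak selection
#'
#' Re-windows every peak to a fixed width around its summit, keeps the
#' `top_n` best-scoring peaks, then resolves overlaps among the re-windowed
#' peaks by keeping the better-scoring one. Ranking is a stable sort by
#' (score descending, chrom, start) so results are deterministic.
#'
#' @param peaks A [peak_set()] with summits.
#' @param width Window width in bp; must be even. Default 500.
#' @param top_n Number of peaks to keep by score before overlap resolution.
#' @return A non-overlapping fixed-width [peak_set()].
#' @export
select_summit_peaks <- function(peaks, width = 500L, top_n = 50000L) {
  assert_that(width %% 2L == 0L, "width must be even")
  half <- width %/% 2L
  peaks$start <- peaks$summit - half
  peaks$end <- peaks$summit + half
  # summit-centring can run off the chromosome start; such windows are invalid
  peaks <- peaks[peaks$start >= 0L, , drop = FALSE]
  ord <- order(-peaks$score, peaks$chrom, peaks$start, method = "radix")
  peaks <- peaks[ord, , drop = FALSE]
  peaks <- head(peaks, top_n)
  # greedy scan in score order: keep a peak unless it overlaps an already
  # kept one (adjacency precomputed once)
  gr <- peaks_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  nbr <- split(sh[qh != sh], qh[qh != sh])
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ni <- nbr[[as.character(i)]]
    keep[i] <- is.null(ni) || !any(keep[ni])
  }
  out <- peaks[keep, , drop = FALSE]
  ord2 <- order(out$chrom, out$start, method = "radix")
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count fragments in peaks per cell
#'
#' Assigns a fragment to a peak when their intervals overlap by at least 1 bp
#' (midpoint assignment available via `rule = "midpoint"`); each fragment is
#' counted at most once. Peaks must be non-overlapping (run
#' [select_summit_peaks()] first).
#'
#' @param fragments data.frame from [read_fragments()].
#' @param peaks Non-overlapping [peak_set()].
#' @param cells Optional character vector fixing cell order; defaults to
#'   sorted unique fragment cell ids.
#' @param rule Overlap rule: any 1 bp overlap (default) or fragment midpoint.
#' @return List with `counts` (sparse peak-by-cell matrix) and `totals`
#'   (named per-cell total fragment counts).
#' @export
count_fragments_in_peaks <- function(fragments, peaks, cells = NULL,
                                     rule = c("overlap", "midpoint")) {
  rule <- match.arg(rule)
  pk_gr <- peaks_granges(peaks)
  if (any(GenomicRanges::countOverlaps(pk_gr, pk_gr, minoverlap = 1L) > 1L)) {
    stop("peaks overlap; run select_summit_peaks() first", call. = FALSE)
  }
  cells <- cells %||% sort(unique(fragments$cell_id))
  cell_idx <- match(fragments$cell_id, cells)
  assert_that(!anyNA(cell_idx), "fragments contain cell ids missing from 'cells'")
  if (rule == "midpoint") {
    mid <- (fragments$start + fragments$end) %/% 2L
    fr_gr <- GenomicRanges::GRanges(fragments$chrom,
                                    IRanges::IRanges(mid + 1L, mid + 1L))
  } else {
    fr_gr <- GenomicRanges::GRanges(fragments$chrom,
                                    IRanges::IRanges(fragments$start + 1L,
                                                     fragments$end))
  }
  hits <- GenomicRanges::findOverlaps(fr_gr, pk_gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # non-overlapping peaks: a long fragment may still touch two adjacent
  # windows; count it once, for its first peak
  first <- !duplicated(qh)
  qh <- qh[first]; sh <- sh[first]
  counts <- Matrix::sparseMatrix(i = sh, j = cell_idx[qh], x = 1,
                                 dims = c(nrow(peaks), length(cells)),
                                 dimnames = list(peaks$name, cells))
  totals <- setNames(tabulate(cell_idx, nbins = length(cells)), cells)
  list(counts = methods::as(counts, "CsparseMatrix"), totals = totals)
}

#' Classify cells in a barnyard species-mixing experiment
#'
#' Cells with fewer than `min_fragments` total fragments are `low_quality`;
#' otherwise a cell is assigned to a species when that species holds at least
#' `purity` of its fragments, and called `hybrid` (presumed doublet or sorting
#' error) otherwise.
#'
#' @param species_counts data.frame with columns `cell_id` and one fragment
#'   count column per species (exactly two species columns).
#' @param min_fragments Total-fragment cutoff. Default 500.
#' @param purity Species-specificity fraction. Default 0.96.
#' @return data.frame of class `species_calls`: `cell_id`,
#'   `n_fragments_total`, per-species counts, `label`.
#' @export
classify_species <- function(species_counts, min_fragments = 500L,
                             purity = 0.96) {
  sp_cols <- setdiff(colnames(species_counts), "cell_id")
  assert_that(length(sp_cols) == 2L,
              "species_counts must have exactly two species count columns")
  a <- species_counts[[sp_cols[1L]]]
  b <- species_counts[[sp_cols[2L]]]
  total <- a + b
  frac_a <- ifelse(total > 0, a / total, NA_real_)
  label <- ifelse(total < min_fragments, "low_quality",
                  ifelse(frac_a >= purity, sp_cols[1L],
                         ifelse(1 - frac_a >= purity, sp_cols[2L], "hybrid")))
  out <- data.frame(cell_id = species_counts$cell_id,
                    n_fragments_total = total,
                    stringsAsFactors = FALSE)
  out[[paste0("n_", sp_cols[1L])]] <- a
  out[[paste0("n_", sp_cols[2L])]] <- b
  out$label <- label
  attr(out, "min_fragments") <- min_fragments
  attr(out, "purity") <- purity
  class(out) <- c("species_calls", "data.frame")
  out
}

#' Per-cell quality filter
#'
#' A cell passes when it has at least `min_fragments` fragments mapped to the
#' genome and its fraction of fragments in peaks (FRiP) is at least
#' `frip_factor` times the cohort median FRiP, where the median is taken over
#' cells meeting the fragment cutoff.
#'
#' @param counts Peak-by-cell count matrix.
#' @param totals Named per-cell total fragment counts covering all columns.
#' @param min_fragments Fragment cutoff. Default 500.
#' @param frip_factor Multiplier on the cohort median FRiP. Default 0.5.
#' @return data.frame of class `qc_report` with per-cell `n_fragments`,
#'   `n_in_peaks`, `frip`, `pass`, plus attributes `median_frip`,
#'   `min_fragments`, `frip_factor`.
#' @export
filter_cells <- function(counts, totals, min_fragments = 500L,
                         frip_factor = 0.5) {
  cells <- colnames(counts)
  assert_that(all(cells %in% names(totals)),
              "totals must cover all cells in the count matrix")
  totals <- totals[cells]
  in_peaks <- Matrix::colSums(counts)
  frip <- ifelse(totals > 0, in_peaks / totals, 0)
  assert_that(all(frip <= 1 + 1e-12),
              "more fragments in peaks than total; totals are inconsistent")
  eligible <- totals >= min_fragments
  if (!any(eligible)) {
    stop("no cell reaches the ", min_fragments,
         "-fragment cutoff; cohort unusable", call. = FALSE)
  }
  med <- median(frip[eligible])
  pass <- eligible & (frip >= frip_factor * med)
  out <- data.frame(cell_id = cells, n_fragments = as.numeric(totals),
                    n_in_peaks = as.numeric(in_peaks), frip = as.numeric(frip),
                    pass = as.logical(pass), stringsAsFactors = FALSE)
  attr(out, "median_frip") <- med
  attr(out, "min_fragments") <- min_fragments
  attr(out, "frip_factor") <- frip_factor
  class(out) <- c("qc_report", "data.frame")
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Pi-ATAC cell QC report: ", nrow(x), " cells, ", sum(x$pass),
      " passing (", sprintf("%.1f%%", 100 * mean(x$pass)), ")\n", sep = "")
  cat("  thresholds: >= ", attr(x, "min_fragments"), " fragments, FRiP >= ",
      attr(x, "frip_factor"), " x median FRiP (median = ",
      sprintf("%.3f", attr(x, "median_frip")), ")\n", sep = "")
  invisible(x)
}

#' Write a QC or species-call table as TSV with a threshold header
#'
#' @param x A `qc_report` or `species_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_table <- function(x, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  hdr <- vapply(names(attributes(x))[names(attributes(x)) %in%
                                       c("median_frip", "min_fragments",
                                         "frip_factor", "purity")],
                function(a) paste0(a, "=", format(attr(x, a))), "")
  if (length(hdr)) writeLines(paste0("# ", paste(hdr, collapse = " ")), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
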