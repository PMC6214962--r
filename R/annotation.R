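#' Read position weight matrices in JASPAR text format
#'
#' Parses the JASPAR count-matrix dialect (`>id name` header followed by four
#' `A [ ... ]` rows). Counts are converted to per-position base probabilities
#' with a pseudocount.
#'
#' @param path JASPAR-format text file, optionally gzipped.
#' @param pseudocount Added to every count before normalisation. Default 0.8
#'   (split across bases proportional to background at normalisation time).
#' @return A named list of PWMs; each PWM is a list with `name`, `matrix`
#'   (4 x L probability matrix, rows A,C,G,T) and `background` (uniform
#'   placeholder, replaced at scan time).
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  lines <- trimws(open_text_close_path(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  assert_that(length(starts) >= 1L, "no JASPAR records found")
  pwms <- list()
  for (s in starts) {
    header <- sub("^>", "", lines[s])
    name <- strsplit(header, "[ \t]+")[[1]]
    name <- if (length(name) >= 2L) name[2L] else name[1L]
    rows <- lines[(s + 1L):(s + 4L)]
    mat <- t(vapply(rows, function(r) jaspar_row_counts(r),
                    numeric(length(jaspar_row_counts(rows[1L])))))
    rownames(mat) <- c("A", "C", "G", "T")
    prob <- sweep(mat + pseudocount / 4, 2, colSums(mat) + pseudocount, "/")
    pwms[[name]] <- pwm(name, prob)
  }
  pwms
}

jaspar_row_counts <- function(row) {
  s <- sub("^[ACGT]", "", row)
  as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
}

open_text_close_path <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con)
}

#' Construct a position weight matrix
#'
#' @param name Motif name.
#' @param matrix 4 x L matrix of per-position base probabilities, rows
#'   A, C, G, T; columns must sum to 1.
#' @param background Background base frequencies (A, C, G, T).
#' @return A list of class `pwm`.
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4)) {
  assert_that(nrow(matrix) == 4L, "PWM must have 4 rows (A, C, G, T)")
  assert_that(ncol(matrix) >= 4L, "PWM must have length >= 4")
  assert_that(all(abs(colSums(matrix) - 1) < 1e-6),
              "PWM columns must sum to 1")
  rownames(matrix) <- c("A", "C", "G", "T")
  out <- list(name = name, matrix = matrix,
              background = background / sum(background))
  class(out) <- "pwm"
  out
}

# reverse complement of a probability PWM: reverse columns, swap A<->T, C<->G
pwm_revcomp <- function(mat) mat[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(mat))), drop = FALSE]

# Exact null distribution of the integerised log-odds score of one scan
# position under iid background bases, by dynamic-programming convolution.
# Returns the smallest integer score whose null exceedance probability is
# <= p_threshold, together with the integerised score matrix.
pwm_score_threshold <- function(prob, background, p_threshold, n_bins = 4000L) {
  lo <- log(pmax(prob, 1e-12)) - log(background)
  span <- sum(apply(lo, 2, max) - apply(lo, 2, min))
  delta <- max(span / n_bins, 1e-9)
  si <- round(lo / delta)
  si <- sweep(si, 2, apply(si, 2, min))  # shift each column to min 0
  max_total <- sum(apply(si, 2, max))
  p <- numeric(max_total + 1L)
  p[1L] <- 1
  for (j in seq_len(ncol(si))) {
    pn <- numeric(max_total + 1L)
    for (b in 1:4) {
      s <- si[b, j]
      idx <- seq_len(max_total + 1L - s)
      pn[idx + s] <- pn[idx + s] + p[idx] * background[b]
    }
    p <- pn
  }
  tail_p <- rev(cumsum(rev(p)))
  exceed <- which(tail_p <= p_threshold)
  thr <- if (length(exceed)) exceed[1L] - 1L else max_total + 1L
  list(score_int = si, threshold = thr)
}

# max integerised PWM score over all scan positions of one integer-coded
# sequence (codes 1..4, NA for ambiguous bases); -Inf if no valid window
scan_max_score <- function(codes, si) {
  L <- ncol(si)
  W <- length(codes)
  if (W < L) return(-Inf)
  n_pos <- W - L + 1L
  total <- numeric(n_pos)
  for (j in seq_len(L)) {
    total <- total + si[codes[j:(j + n_pos - 1L)], j]
  }
  if (all(is.na(total))) -Inf else max(total, na.rm = TRUE)
}

seq_codes <- function(seqs) {
  lapply(as.character(seqs), function(s) {
    m <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    m
  })
}

#' Annotate peaks by motif matches
#'
#' A peak is a member of a motif feature when some position on either strand
#' scores at least the log-odds threshold whose null exceedance probability
#' (exact, by dynamic programming over the integerised score distribution
#' under an iid background base model) is at most `p_threshold`. The
#' background is the peak-set average base composition by default.
#'
#' @param pwms List of [pwm()] objects (e.g. from [read_jaspar()]).
#' @param peaks A [peak_set()].
#' @param genome FASTA path or `DNAStringSet`.
#' @param p_threshold Per-position null exceedance probability. Default 5e-5.
#' @param background `"peakset"` (average base frequencies over all peak
#'   sequences) or `"even"`.
#' @param prune Drop motifs with zero member peaks. Default TRUE.
#' @return Sparse 0/1 peak-by-motif membership matrix (`dgCMatrix`) with
#'   attribute `kind = "motif"`.
#' @export
match_motifs <- function(pwms, peaks, genome, p_threshold = 5e-5,
                         background = c("peakset", "even"), prune = TRUE) {
  background <- match.arg(background)
  seqs <- peak_sequences(peaks, genome)
  bg <- if (background == "peakset") {
    f <- colSums(Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[,
                   c("A", "C", "G", "T"), drop = FALSE])
    if (sum(f) == 0) rep(0.25, 4) else pmax(f / sum(f), 1e-3)
  } else rep(0.25, 4)
  bg <- bg / sum(bg)
  codes <- seq_codes(seqs)
  width_min <- min(nchar(as.character(seqs)))
  cols <- list()
  kept_names <- character()
  for (w in pwms) {
    if (ncol(w$matrix) > width_min) {
      warning("PWM ", w$name, " longer than the narrowest peak; skipped")
      next
    }
    fwd <- pwm_score_threshold(w$matrix, bg, p_threshold)
    rev_ <- pwm_score_threshold(pwm_revcomp(w$matrix), bg, p_threshold)
    member <- vapply(codes, function(cd) {
      scan_max_score(cd, fwd$score_int) >= fwd$threshold ||
        scan_max_score(cd, rev_$score_int) >= rev_$threshold
    }, logical(1))
    cols[[w$name]] <- member
    kept_names <- c(kept_names, w$name)
  }
  assert_that(length(cols) > 0L, "no PWM could be scanned")
  m <- do.call(cbind, cols)
  annotation_from_logical(m, peaks$name, kept_names, "motif", prune)
}

annotation_from_logical <- function(m, peak_names, feat_names, kind, prune) {
  dimnames(m) <- list(peak_names, feat_names)
  if (prune) {
    nz <- colSums(m) > 0
    m <- m[, nz, drop = FALSE]
  }
  sm <- methods::as(Matrix::Matrix(m * 1, sparse = TRUE), "CsparseMatrix")
  attr(sm, "kind") <- kind
  sm
}

#' Annotate peaks by k-mer occurrence
#'
#' One feature per canonical k-mer (a k-mer and its reverse complement
#' collapsed, since accessibility is unstranded); a peak is a member when the
#' k-mer occurs at least once in its sequence on either strand. Features with
#' zero member peaks are pruned.
#'
#' @param peaks A [peak_set()].
#' @param genome FASTA path or `DNAStringSet`.
#' @param k K-mer length; the analysis convention is 6, 7 or 8.
#' @param collapse Collapse reverse complements (default TRUE).
#' @param prune Drop zero-member features. Default TRUE.
#' @return Sparse 0/1 peak-by-kmer membership matrix with attribute
#'   `kind = "kmer"`.
#' @export
match_kmers <- function(peaks, genome, k, collapse = TRUE, prune = TRUE) {
  assert_that(k >= 4L, "k must be >= 4")
  seqs <- peak_sequences(peaks, genome)
  assert_that(min(Biostrings::width(seqs)) >= k,
              "k larger than the narrowest peak width")
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  kmers <- colnames(counts)
  if (collapse) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- ifelse(kmers <= rc, kmers, rc)
    groups <- split(seq_along(kmers), canon)
    member <- vapply(groups, function(ix) {
      rowSums(counts[, ix, drop = FALSE]) > 0
    }, logical(nrow(counts)))
    if (nrow(counts) == 1L) member <- matrix(member, nrow = 1L,
                                             dimnames = list(NULL, names(groups)))
  } else {
    member <- counts > 0
  }
  annotation_from_logical(member, peaks$name, colnames(member), "kmer", prune)
}

#' Write / read an annotation matrix (boolean MTX + feature sidecar)
#'
#' @param annotation Sparse peak-by-feature membership matrix.
#' @param path_matrix,path_features,path_peaks Output paths.
#' @return `path_matrix`, invisibly.
#' @export
write_annotation_matrix <- function(annotation, path_matrix, path_features,
                                    path_peaks) {
  write_count_matrix(annotation, path_matrix, path_peaks, path_features)
}

#' @rdname write_annotation_matrix
#' @param kind Feature kind to record (`"motif"` or `"kmer"`).
#' @export
read_annotation_matrix <- function(path_matrix, path_features, path_peaks,
                                   kind = "motif") {
  m <- read_count_matrix(path_matrix, path_peaks, path_features)
  attr(m, "kind") <- kind
  m
}
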