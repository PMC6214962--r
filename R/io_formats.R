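#' Read a fragment file
#'
#' Reads a BED-like tab-separated fragment file (chrom, start, end, cell
#' barcode, further columns ignored). Coordinates are 0-based half-open.
#' Fragments are assumed deduplicated and mitochondria-free upstream;
#' `drop_chroms` removes fragments on user-listed chromosomes (e.g. "chrM").
#'
#' @param path Path to a tab-separated file, optionally gzip-compressed.
#' @param drop_chroms Character vector of chromosome names to drop.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `cell_id`,
#'   one row per fragment, in file order.
#' @export
read_fragments <- function(path, drop_chroms = character()) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), cell_id = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("fragment file ", path, ": line ", which(nf < 4L)[1L],
         " has fewer than 4 tab-separated columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  cell_id <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("fragment file ", path, ": line ", bad[1L],
         " has non-integer coordinates", call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("fragment file ", path, ": line ", bad[1L],
         " has start >= end (", start[bad[1L]], " >= ", end[bad[1L]], ")",
         call. = FALSE)
  }
  bad <- which(!nzchar(chrom) | !nzchar(cell_id))
  if (length(bad)) {
    stop("fragment file ", path, ": line ", bad[1L],
         " has an empty chrom or cell id", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    cell_id = cell_id, stringsAsFactors = FALSE)
  if (length(drop_chroms)) out <- out[!(out$chrom %in% drop_chroms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write fragments to a BED-like TSV
#'
#' @param fragments data.frame as returned by [read_fragments()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(fragments$chrom, fragments$start, fragments$end,
                   fragments$cell_id, sep = "\t"), con)
  invisible(path)
}

#' Construct a peak set
#'
#' A peak set holds fixed genomic peak intervals (0-based half-open) with an
#' absolute summit position and the caller's -log10 q-value score. GC fraction
#' and mean accessibility start out `NA` until computed by [compute_gc()] and
#' a count matrix.
#'
#' @param chrom,start,end,summit,score,name Per-peak vectors; `name` must be
#'   unique. `summit` must lie inside `[start, end)`.
#' @param gc,mean_access Optional per-peak covariates.
#' @return A `data.frame` of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, summit, score,
                     name = sprintf("peak_%05d", seq_along(chrom)),
                     gc = NA_real_, mean_access = NA_real_) {
  ps <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), summit = as.integer(summit),
                   score = as.numeric(score), name = as.character(name),
                   gc = as.numeric(gc), mean_access = as.numeric(mean_access),
                   stringsAsFactors = FALSE)
  validate_peak_set(ps)
  class(ps) <- c("peak_set", "data.frame")
  ps
}

validate_peak_set <- function(ps) {
  assert_that(all(ps$start < ps$end), "peak set: start must be < end")
  assert_that(all(ps$start <= ps$summit & ps$summit < ps$end),
              "peak set: summit must lie within [start, end)")
  assert_that(!anyDuplicated(ps$name), "peak set: peak names must be unique")
  invisible(ps)
}

peaks_granges <- function(ps) {
  GenomicRanges::GRanges(ps$chrom,
                         IRanges::IRanges(start = ps$start + 1L, end = ps$end),
                         name = ps$name)
}

#' Read a MACS2 narrowPeak file
#'
#' Ten-column narrowPeak dialect; column 9 is the -log10 q-value and column 10
#' the summit offset from `start`. The summit is stored as an absolute
#' position.
#'
#' @param path Path, optionally gzipped.
#' @return A [peak_set()].
#' @export
read_narrowpeak <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  tab <- read.table(con, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character",
                                   "numeric", "numeric", "numeric", "integer"),
                    stringsAsFactors = FALSE)
  if (ncol(tab) != 10L) {
    stop("narrowPeak file ", path, ": expected 10 columns, got ", ncol(tab),
         call. = FALSE)
  }
  offset <- tab[[10L]]
  width <- tab[[3L]] - tab[[2L]]
  bad <- which(offset < 0L | offset >= width)
  if (length(bad)) {
    stop("narrowPeak file ", path, ": line ", bad[1L],
         " summit offset ", offset[bad[1L]],
         " outside [0, peak width)", call. = FALSE)
  }
  if (anyDuplicated(tab[[4L]])) {
    stop("narrowPeak file ", path, ": peak names must be unique (duplicate: ",
         tab[[4L]][duplicated(tab[[4L]])][1L], ")", call. = FALSE)
  }
  peak_set(chrom = tab[[1L]], start = tab[[2L]], end = tab[[3L]],
           summit = tab[[2L]] + offset, score = tab[[9L]], name = tab[[4L]])
}

#' Write a peak set as narrowPeak
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  tab <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    0L, ".", 0, 0, peaks$score, peaks$summit - peaks$start)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file (e.g. an exclusion list)
#'
#' @param path Path to a 3+ column BED file, optionally gzipped.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  tab <- read.table(con, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 3L, "BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]), stringsAsFactors = FALSE)
  assert_that(all(out$start < out$end), "BED file: start must be < end")
  out
}

#' Read an index-sort table
#'
#' Index sorting records, for every sorted cell, its destination plate well
#' together with one fluorescence intensity per channel. Exports from
#' different sorters are normalised through `channel_map` (logical name ->
#' column name in the CSV) rather than guessed.
#'
#' @param path CSV with a header, optionally gzipped.
#' @param channel_map Named character vector mapping logical channel names to
#'   CSV column names, e.g. `c(HIF1A = "PE")`.
#' @param id_column Optional explicit cell id column; if `NULL` the cell id is
#'   composed as `plate:well` from columns `plate` and `well`.
#' @return A `data.frame` of class `index_sort_table` with columns `cell_id`,
#'   `plate`, `well`, then one column per logical channel.
#' @export
read_index_table <- function(path, channel_map, id_column = NULL) {
  con <- open_text(path)
  on.exit(close(con))
  tab <- read.table(con, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing_ch <- setdiff(unname(channel_map), colnames(tab))
  if (length(missing_ch)) {
    stop("index-sort table ", path, ": mapped channel column(s) ",
         paste(missing_ch, collapse = ", "), " not found; available columns: ",
         paste(colnames(tab), collapse = ", "), call. = FALSE)
  }
  if (is.null(id_column)) {
    assert_that(all(c("plate", "well") %in% colnames(tab)),
                "index-sort table needs 'plate' and 'well' columns (or id_column)")
    cell_id <- paste0(tab$plate, ":", tab$well)
    plate <- as.character(tab$plate)
    well <- as.character(tab$well)
  } else {
    assert_that(id_column %in% colnames(tab),
                paste0("id column '", id_column, "' not in table"))
    cell_id <- as.character(tab[[id_column]])
    plate <- if ("plate" %in% colnames(tab)) as.character(tab$plate) else NA_character_
    well <- if ("well" %in% colnames(tab)) as.character(tab$well) else NA_character_
  }
  if (anyDuplicated(cell_id)) {
    stop("index-sort table ", path, ": duplicate cell id ",
         cell_id[duplicated(cell_id)][1L], call. = FALSE)
  }
  out <- data.frame(cell_id = cell_id, plate = plate, well = well,
                    stringsAsFactors = FALSE)
  for (logical_name in names(channel_map)) {
    v <- as.numeric(tab[[channel_map[[logical_name]]]])
    assert_that(all(is.finite(v)),
                paste0("channel ", logical_name, " contains non-finite values"))
    out[[logical_name]] <- v
  }
  class(out) <- c("index_sort_table", "data.frame")
  out
}

#' Write an index-sort table as CSV
#'
#' @param table An `index_sort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write a sparse peak-by-cell count matrix
#'
#' MatrixMarket coordinate format plus one id per line in the two sidecar
#' files (peaks = rows, cells = columns). `write_count_matrix` followed by
#' `read_count_matrix` is the identity on values and ids.
#'
#' @param path_matrix MTX file.
#' @param path_peaks,path_cells Sidecar files with one id per line.
#' @return A `dgCMatrix` with peak row names and cell column names.
#' @export
read_count_matrix <- function(path_matrix, path_peaks, path_cells) {
  m <- Matrix::readMM(path_matrix)
  if (methods::is(m, "nMatrix")) m <- m * 1  # pattern MTX -> numeric
  m <- methods::as(m, "CsparseMatrix")
  peaks <- open_text_close(path_peaks)
  cells <- open_text_close(path_cells)
  if (nrow(m) != length(peaks) || ncol(m) != length(cells)) {
    stop("count matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecar lengths (", length(peaks), " peaks, ",
         length(cells), " cells)", call. = FALSE)
  }
  if (any(m@x < 0)) stop("count matrix contains negative entries", call. = FALSE)
  assert_that(!anyDuplicated(cells), "cell ids must be unique")
  dimnames(m) <- list(peaks, cells)
  m
}

open_text_close <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  # realize the whole connection so it can be closed before returning
  txt <- readLines(con)
  txt
}

#' @rdname read_count_matrix
#' @param counts A sparse (or dense) non-negative matrix with dimnames.
#' @export
write_count_matrix <- function(counts, path_matrix, path_peaks, path_cells) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, path_matrix)
  writeLines(rownames(counts) %||% as.character(seq_len(nrow(counts))), path_peaks)
  writeLines(colnames(counts) %||% as.character(seq_len(ncol(counts))), path_cells)
  invisible(path_matrix)
}

#' Compute per-peak GC fraction from a genome
#'
#' GC is (#G + #C) / (#A + #C + #G + #T) over the peak interval; ambiguous
#' bases count toward neither numerator nor denominator. Peaks whose interval
#' contains only ambiguous bases get `NA` GC and are flagged; they are
#' excluded from background matching downstream.
#'
#' @param peaks A [peak_set()].
#' @param genome FASTA path or a [Biostrings::DNAStringSet].
#' @return The peak set with `gc` filled in.
#' @export
compute_gc <- function(peaks, genome) {
  seqs <- peak_sequences(peaks, genome)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt, NA_real_)
  peaks$gc <- as.numeric(gc)
  peaks
}

#' Extract peak sequences from a genome
#'
#' @inheritParams compute_gc
#' @return A [Biostrings::DNAStringSet], one sequence per peak.
#' @export
peak_sequences <- function(peaks, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  # FASTA headers may carry descriptions after the id
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  lens <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  bad <- which(peaks$end > lens)
  if (length(bad)) {
    stop("peak ", peaks$name[bad[1L]], " extends beyond chromosome ",
         peaks$chrom[bad[1L]], " (length ", lens[bad[1L]], ")", call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(peaks)), function(i) {
    Biostrings::subseq(genome[[peaks$chrom[i]]],
                       start = peaks$start[i] + 1L, end = peaks$end[i])
  }))
  names(seqs) <- peaks$name
  seqs
}

#' Attach per-peak mean accessibility from a count matrix
#'
#' @param peaks A [peak_set()].
#' @param counts Peak-by-cell count matrix with row names matching peak names.
#' @return The peak set with `mean_access` filled.
#' @export
compute_mean_access <- function(peaks, counts) {
  idx <- match(peaks$name, rownames(counts))
  assert_that(!anyNA(idx), "count matrix row names must cover all peak names")
  peaks$mean_access <- Matrix::rowMeans(counts)[idx]
  peaks
}
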