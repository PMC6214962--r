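#' Cluster motif modules and cell subgroups
#'
#' Average-linkage hierarchical clustering with distance `1 - Pearson
#' correlation`, applied independently to the rows (features -> modules) and
#' columns (cells -> subgroups) of a deviation z-score matrix, each tree cut
#' to the configured number of clusters. Constant rows/columns (undefined
#' correlation) are dropped with a warning. Deterministic given input order.
#'
#' @param z Feature-by-cell z-score matrix (typically restricted to
#'   significantly variable features).
#' @param k_modules,k_subgroups Cluster counts for features and cells.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return List of class `module_clustering`: `modules` (named feature ->
#'   module id), `subgroups` (named cell -> subgroup id), `feature_tree`,
#'   `cell_tree`, `dropped_features`, `dropped_cells`, plus a
#'   silhouette-style suggestion printed by its print method but never
#'   auto-applied.
#' @export
cluster_modules_subgroups <- function(z, k_modules, k_subgroups,
                                      linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  assert_that(nrow(z) >= 2L && ncol(z) >= 2L,
              "need at least 2 features and 2 cells")
  assert_that(k_modules >= 1L && k_subgroups >= 1L, "cluster counts must be >= 1")
  z0 <- z
  z0[is.na(z0)] <- 0
  const_row <- apply(z0, 1, sd) == 0
  const_col <- apply(z0, 2, sd) == 0
  if (any(const_row)) warning(sum(const_row), " constant feature row(s) dropped")
  if (any(const_col)) warning(sum(const_col), " constant cell column(s) dropped")
  zr <- z0[!const_row, !const_col, drop = FALSE]
  assert_that(nrow(zr) >= 2L && ncol(zr) >= 2L,
              "too few non-constant rows/columns to cluster")
  dr <- stats::as.dist(1 - cor(t(zr)))
  dc <- stats::as.dist(1 - cor(zr))
  ft <- hclust(dr, method = linkage)
  ct <- hclust(dc, method = linkage)
  structure(list(
    modules = cutree(ft, k = min(k_modules, nrow(zr))),
    subgroups = cutree(ct, k = min(k_subgroups, ncol(zr))),
    feature_tree = ft, cell_tree = ct,
    dropped_features = rownames(z)[const_row],
    dropped_cells = colnames(z)[const_col],
    linkage = linkage), class = "module_clustering")
}

#' @export
print.module_clustering <- function(x, ...) {
  cat("module_clustering: ", length(unique(x$modules)), " motif modules over ",
      length(x$modules), " features; ", length(unique(x$subgroups)),
      " cell subgroups over ", length(x$subgroups), " cells (",
      x$linkage, " linkage, 1 - Pearson distance)\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects all thresholds, seeds and analysis choices of an end-to-end run.
#' Either `simulation` (a [sim_config()], the synthetic route) or explicit
#' input paths must be supplied.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed for every stochastic stage.
#' @param simulation Optional [sim_config()] generating the experiment.
#' @param paths Optional named list of input files: `fragments`, `peaks`
#'   (narrowPeak), `genome` (FASTA), `index_table` (CSV), `exclude` (vector
#'   of BED paths).
#' @param channel_map Channel renaming for [read_index_table()].
#' @param peak_width,top_n Peak selection parameters.
#' @param min_fragments,frip_factor Cell filter parameters.
#' @param feature_kind `"annotation"` (use the simulation's planted
#'   membership), `"kmer"` or `"motif"`.
#' @param kmer_k K-mer length when `feature_kind = "kmer"`.
#' @param pwms PWM list when `feature_kind = "motif"`.
#' @param background_iterations,k_nn Background sampling parameters.
#' @param alpha Significance level for variable features.
#' @param stain_channel,stain_cutpoints Optional protein stain grouping.
#' @param k_modules,k_subgroups Cluster counts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulation = NULL,
                            paths = NULL, channel_map = NULL,
                            peak_width = 500L, top_n = 50000L,
                            min_fragments = 500L, frip_factor = 0.5,
                            feature_kind = c("annotation", "kmer", "motif"),
                            kmer_k = 6L, pwms = NULL,
                            background_iterations = 50L, k_nn = 250L,
                            alpha = 0.05, stain_channel = NULL,
                            stain_cutpoints = NULL,
                            k_modules = 3L, k_subgroups = 7L) {
  feature_kind <- match.arg(feature_kind)
  assert_that(!is.null(simulation) || !is.null(paths),
              "either a simulation config or input paths are required")
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              simulation = simulation, paths = paths,
              channel_map = channel_map, peak_width = as.integer(peak_width),
              top_n = as.integer(top_n),
              min_fragments = as.integer(min_fragments),
              frip_factor = frip_factor, feature_kind = feature_kind,
              kmer_k = as.integer(kmer_k), pwms = pwms,
              background_iterations = as.integer(background_iterations),
              k_nn = as.integer(k_nn), alpha = alpha,
              stain_channel = stain_channel,
              stain_cutpoints = stain_cutpoints,
              k_modules = as.integer(k_modules),
              k_subgroups = as.integer(k_subgroups))
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(log, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  elapsed <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  log(sprintf("stage=%s elapsed_s=%.2f", name, elapsed))
  res
}

#' Run the full analysis pipeline
#'
#' Executes QC, annotation, deviation, variability, optional protein-link and
#' clustering stages as configured, writing every result table plus a JSON
#' manifest (resolved configuration, seed, input checksums) to
#' `config$outdir`. Rerunning with the same configuration reproduces
#' byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "pipeline.log")
  log_con <- file(log_path, "wt")
  on.exit(close(log_con))
  log <- function(msg) writeLines(paste0("[piatac] ", msg), log_con)
  log(sprintf("seed=%d", config$seed))

  checksums <- list()
  if (!is.null(config$simulation)) {
    sim <- stage(log, "simulate",
                 generate_accessibility_experiment(config$simulation))
    counts <- sim$counts
    peaks <- sim$peaks
    index_table <- sim$index_table
    genome <- NULL
    totals <- setNames(as.numeric(Matrix::colSums(counts)), colnames(counts))
    annotation <- sim$annotation
  } else {
    p <- config$paths
    for (f in unlist(p)) {
      if (!file.exists(f)) {
        stop("pipeline stage 'inputs' failed: missing input file ", f,
             call. = FALSE)
      }
      checksums[[basename(f)]] <- unname(tools::md5sum(f))
    }
    peaks <- stage(log, "read_peaks", read_narrowpeak(p$peaks))
    if (!is.null(p$exclude)) {
      beds <- lapply(p$exclude, read_bed)
      peaks <- stage(log, "filter_regions", filter_regions(peaks, beds))
    }
    peaks <- stage(log, "select_peaks",
                   select_summit_peaks(peaks, config$peak_width, config$top_n))
    fragments <- stage(log, "read_fragments", read_fragments(p$fragments))
    cfp <- stage(log, "count_in_peaks",
                 count_fragments_in_peaks(fragments, peaks))
    counts <- cfp$counts
    totals <- cfp$totals
    genome <- p$genome
    index_table <- if (!is.null(p$index_table)) {
      stage(log, "read_index_table",
            read_index_table(p$index_table, config$channel_map))
    } else NULL
    if (config$feature_kind == "annotation") {
      stop("pipeline stage 'annotate' failed: feature_kind 'annotation' ",
           "requires a simulation config", call. = FALSE)
    }
    annotation <- NULL
  }

  qc <- stage(log, "qc", filter_cells(counts, totals, config$min_fragments,
                                      config$frip_factor))
  write_qc_table(qc, file.path(config$outdir, "qc_report.tsv"))
  keep_cells <- qc$cell_id[qc$pass]
  counts <- counts[, keep_cells, drop = FALSE]

  if (config$feature_kind != "annotation") {
    if (is.null(genome)) {
      stop("pipeline stage 'annotate' failed: a genome FASTA is required for ",
           config$feature_kind, " annotation", call. = FALSE)
    }
    annotation <- stage(log, "annotate", {
      if (config$feature_kind == "kmer") {
        match_kmers(peaks, genome, config$kmer_k)
      } else {
        assert_that(!is.null(config$pwms), "feature_kind 'motif' needs pwms")
        match_motifs(config$pwms, peaks, genome)
      }
    })
  }
  # keep only features with members among retained peaks
  annotation <- annotation[rownames(counts), , drop = FALSE]
  annotation <- annotation[, Matrix::colSums(annotation) > 0, drop = FALSE]

  peaks <- peaks[match(rownames(counts), peaks$name), , drop = FALSE]
  peaks <- compute_mean_access(peaks, counts)
  bg <- stage(log, "background",
              sample_background_peaks(peaks, B = config$background_iterations,
                                      k_nn = min(config$k_nn, nrow(peaks)),
                                      seed = config$seed))
  dev <- stage(log, "deviations", corrected_deviations(counts, annotation, bg))
  vt <- stage(log, "variability", motif_variability(dev))
  write_tsv_table(vt, file.path(config$outdir, "variability.tsv"))
  write_tsv_table(round_num(as.data.frame(dev$z), 6),
                  file.path(config$outdir, "deviation_z.tsv"), rownames = TRUE)
  sig <- significant_features(vt, config$alpha)
  write_tsv_table(sig, file.path(config$outdir, "significant_features.tsv"))

  results <- list(qc = qc, deviations = dev, variability = vt,
                  significant = sig)

  if (!is.null(index_table) && !is.null(config$stain_channel)) {
    groups <- stage(log, "stain_groups",
                    assign_stain_groups(index_table, config$stain_channel,
                                        cutpoints = config$stain_cutpoints))
    groups <- groups[groups$cell_id %in% colnames(counts), , drop = FALSE]
    intens <- setNames(groups$intensity, groups$cell_id)
    ct <- stage(log, "protein_correlation",
                correlate_protein_deviation(dev$z[, groups$cell_id,
                                                  drop = FALSE],
                                            intens, config$alpha))
    write_tsv_table(ct, file.path(config$outdir, "protein_correlation.tsv"))
    results$stain_groups <- groups
    results$protein_correlation <- ct
  }

  cl_features <- if (nrow(sig) >= 2L) sig$feature else rownames(dev$z)
  clust <- stage(log, "cluster", cluster_modules_subgroups(
    dev$z[cl_features, , drop = FALSE],
    config$k_modules, config$k_subgroups))
  write_tsv_table(data.frame(feature = names(clust$modules),
                             module = unname(clust$modules)),
                  file.path(config$outdir, "modules.tsv"))
  write_tsv_table(data.frame(cell_id = names(clust$subgroups),
                             subgroup = unname(clust$subgroups)),
                  file.path(config$outdir, "subgroups.tsv"))
  results$clustering <- clust

  manifest <- list(package_version = as.character(utils::packageVersion("piatac")),
                   seed = config$seed,
                   resolved_config = serializable_config(config),
                   input_checksums = checksums)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done")
  invisible(list(results = results, manifest = manifest))
}

round_num <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_tsv_table <- function(df, path, rownames = FALSE) {
  df <- as.data.frame(df)
  if (rownames) df <- cbind(id = base::rownames(df), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL  # environment-specific; keeps manifests rerun-stable
  cfg$pwms <- if (!is.null(cfg$pwms)) names(cfg$pwms) else NULL
  if (!is.null(cfg$simulation)) {
    sim <- unclass(cfg$simulation)
    sim$programs <- lapply(sim$programs, function(p) {
      p$cells <- if (!is.null(p$cells)) length(p$cells) else NULL
      p$weights <- if (!is.null(p$weights)) "continuous" else NULL
      p
    })
    cfg$simulation <- sim
  }
  cfg
}
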