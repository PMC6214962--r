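#' Configuration for a synthetic Pi-ATAC experiment
#'
#' Defines the ground-truth structure the downstream stages assume: sparse
#' Poisson peak-by-cell counts with per-peak baseline accessibility and
#' per-cell depth, planted motif programs, a GC/accessibility confound, and
#' index-FACS protein channels coupled to motif activity.
#'
#' Counts are drawn as
#' `X_ij ~ Poisson(d_j * p_ij)` with
#' `p_ij proportional to r_i * exp(sum_k M_ik beta_k a_kj + g_j * gcz_i)`,
#' normalised within each cell so that the expected column total is the
#' cell's depth `d_j`. Here `r_i` is the per-peak baseline rate, `a_kj` the
#' per-cell activity of feature k, and `g_j ~ N(0, gc_bias_sd)` a per-cell
#' GC bias slope acting on the standardised peak GC `gcz_i` — the technical
#' confound the matched-background correction must remove. Peak GC is drawn
#' correlated with `log r_i` at `gc_confound_r`, and feature member peaks can
#' be skewed toward a feature-specific GC direction via `feature_gc_skew`,
#' so that uncorrected deviations inherit the confound.
#'
#' @param n_peaks,n_cells,n_features,peaks_per_feature Dimensions.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-peak baseline rate (relative scale; normalised per cell).
#' @param depth_log_mean,depth_log_sd Log-normal parameters of per-cell depth.
#' @param programs List of planted programs, each a list with `feature`
#'   (index), `beta` (effect size > 0), and either `cells` (indices of member
#'   cells, activity 1) or `weights` (length `n_cells` continuous activity).
#' @param channels List of protein channels, each a list with `name`,
#'   `feature` (coupled feature index or `NA`), `slope`, `noise_sd`,
#'   `background`, optional `model` (`"gaussian"` truncated at 0, default, or
#'   `"lognormal"`).
#' @param gc_confound_r Target Pearson correlation between peak GC and
#'   `log r_i`. Default 0.5.
#' @param gc_bias_sd SD of the per-cell GC bias slope. Default 0.
#' @param feature_gc_skew Strength of the per-feature GC skew when sampling
#'   member peaks. Default 0.
#' @param doublet_rate,species Barnyard parameters (see
#'   [generate_barnyard_mixture()]): `species` is a list with `n_a`, `n_b`,
#'   `contamination`.
#' @param binarize Emit 0/1 instead of counts. Default FALSE.
#' @param seed Integer master seed; all draws derive sub-streams from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_peaks = 1000L, n_cells = 200L, n_features = 20L,
                       peaks_per_feature = 100L,
                       baseline_log_mean = 0, baseline_log_sd = 0.5,
                       depth_log_mean = log(5000), depth_log_sd = 0.3,
                       programs = list(), channels = list(),
                       gc_confound_r = 0.5, gc_bias_sd = 0,
                       feature_gc_skew = 0,
                       doublet_rate = 0, species = NULL,
                       binarize = FALSE, seed = 1L) {
  cfg <- list(n_peaks = as.integer(n_peaks), n_cells = as.integer(n_cells),
              n_features = as.integer(n_features),
              peaks_per_feature = as.integer(peaks_per_feature),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              programs = programs, channels = channels,
              gc_confound_r = gc_confound_r, gc_bias_sd = gc_bias_sd,
              feature_gc_skew = feature_gc_skew,
              doublet_rate = doublet_rate, species = species,
              binarize = isTRUE(binarize), seed = as.integer(seed))
  assert_that(cfg$n_peaks > 0 && cfg$n_cells > 0, "dimensions must be > 0")
  assert_that(cfg$peaks_per_feature <= cfg$n_peaks,
              "peaks_per_feature cannot exceed n_peaks")
  assert_that(cfg$doublet_rate >= 0 && cfg$doublet_rate < 1,
              "doublet_rate must be in [0, 1)")
  for (p in programs) {
    assert_that(!is.null(p$feature) && p$feature >= 1 &&
                  p$feature <= cfg$n_features, "program feature out of range")
    assert_that(!is.null(p$beta) && p$beta > 0, "program beta must be > 0")
  }
  if (!is.null(species)) {
    assert_that(species$contamination >= 0 && species$contamination < 0.5,
                "contamination fraction must be in [0, 0.5)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic protein-indexed accessibility experiment
#'
#' Draws the full object bundle every downstream stage consumes: a sparse
#' count matrix, a peak set with GC and mean accessibility, a peak-by-feature
#' membership matrix, an index-sort protein table, and the ground truth.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (dgCMatrix peaks x cells), `peaks`
#'   ([peak_set()]), `annotation` (sparse peak-by-feature 0/1),
#'   `index_table` ([read_index_table()] layout), and `truth` (list:
#'   `activity` features x cells, `depths`, `baseline`, `gc`, `gc_bias`,
#'   `membership`, `channel_coupling`).
#' @export
generate_accessibility_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_pk <- config$n_peaks; n_cl <- config$n_cells; n_ft <- config$n_features

  # peaks: baseline rates and a GC covariate correlated with log baseline
  base <- with_substream(config$seed, 1L, {
    log_r <- rnorm(n_pk, config$baseline_log_mean, config$baseline_log_sd)
    rho <- config$gc_confound_r
    eps <- rnorm(n_pk)
    gcz <- rho * scale_or_zero(log_r) + sqrt(max(0, 1 - rho^2)) * eps
    list(log_r = log_r, gcz = as.numeric(scale_or_zero(gcz)))
  })
  r <- exp(base$log_r)
  gc <- pmin(0.95, pmax(0.05, 0.41 + 0.08 * base$gcz))

  # membership: per-feature GC-skewed sampling without replacement
  membership <- with_substream(config$seed, 2L, {
    sk <- config$feature_gc_skew
    dirs <- if (n_ft > 0) rnorm(n_ft) else numeric()
    idx <- lapply(seq_len(n_ft), function(k) {
      w <- exp(sk * dirs[k] * base$gcz)
      sample.int(n_pk, config$peaks_per_feature, prob = w / sum(w))
    })
    list(idx = idx, dirs = dirs)
  })
  M <- Matrix::sparseMatrix(
    i = unlist(membership$idx),
    j = rep(seq_len(n_ft), each = config$peaks_per_feature),
    x = 1, dims = c(n_pk, n_ft),
    dimnames = list(sprintf("peak_%05d", seq_len(n_pk)),
                    sprintf("feature_%03d", seq_len(n_ft))))

  # per-cell depths, activities, GC bias slopes
  depths <- with_substream(config$seed, 3L,
                           rlnorm(n_cl, config$depth_log_mean,
                                  config$depth_log_sd))
  activity <- matrix(0, n_ft, n_cl)
  beta <- numeric(n_ft)
  with_substream(config$seed, 4L, {
    for (p in config$programs) {
      a <- if (!is.null(p$weights)) {
        assert_that(length(p$weights) == n_cl, "program weights length mismatch")
        p$weights
      } else {
        v <- numeric(n_cl); v[p$cells] <- 1; v
      }
      activity[p$feature, ] <- a
      beta[p$feature] <- p$beta
    }
  })
  gc_bias <- with_substream(config$seed, 5L, rnorm(n_cl, 0, config$gc_bias_sd))

  # Poisson counts with per-cell renormalisation so E[colsum] = depth
  log_rate <- matrix(base$log_r, n_pk, n_cl) +
    as.matrix(M %*% (activity * beta)) +
    outer(base$gcz, gc_bias)
  w <- exp(log_rate)
  p_ij <- sweep(w, 2, colSums(w), "/")
  lambda <- sweep(p_ij, 2, depths, "*")
  X <- with_substream(config$seed, 6L,
                      matrix(rpois(n_pk * n_cl, lambda), n_pk, n_cl))
  if (config$binarize) X <- (X > 0) * 1L
  dimnames(X) <- list(rownames(M), sprintf("cell_%04d", seq_len(n_cl)))
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")

  # synthetic peak coordinates: non-overlapping 500 bp windows on one chrom
  peaks <- peak_set(chrom = "chrS1",
                    start = (seq_len(n_pk) - 1L) * 1000L,
                    end = (seq_len(n_pk) - 1L) * 1000L + 500L,
                    summit = (seq_len(n_pk) - 1L) * 1000L + 250L,
                    score = rev(seq_len(n_pk)) / n_pk * 100,
                    name = rownames(M), gc = gc)
  peaks <- compute_mean_access(peaks, Xs)

  # protein channels coupled to feature activity
  channel_truth <- list()
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12)
  n_plates <- ceiling(n_cl / 96L)
  plate <- sprintf("P%d", rep(seq_len(n_plates), each = 96L))[seq_len(n_cl)]
  well <- rep(wells, n_plates)[seq_len(n_cl)]
  index_table <- data.frame(cell_id = colnames(X), plate = plate, well = well,
                            stringsAsFactors = FALSE)
  with_substream(config$seed, 7L, {
    for (ch in config$channels) {
      a <- if (!is.null(ch$feature) && !is.na(ch$feature)) {
        activity[ch$feature, ]
      } else rep(0, n_cl)
      noise <- rnorm(n_cl, 0, ch$noise_sd)
      intens <- if (identical(ch$model, "lognormal")) {
        ch$background * exp(ch$slope * a + noise)
      } else {
        pmax(0, ch$background + ch$slope * a + noise)
      }
      index_table[[ch$name]] <- intens
      channel_truth[[ch$name]] <- list(feature = ch$feature %||% NA,
                                       slope = ch$slope)
    }
  })
  class(index_table) <- c("index_sort_table", "data.frame")

  list(counts = Xs, peaks = peaks, annotation = structure(M, kind = "motif"),
       index_table = index_table,
       truth = list(activity = activity, beta = beta, depths = depths,
                    baseline = r, gc = gc, gc_bias = gc_bias,
                    membership = membership$idx,
                    feature_gc_dirs = membership$dirs,
                    channel_coupling = channel_truth))
}

#' Generate a barnyard species-mixture table
#'
#' Singlet cells draw a total fragment count from the depth distribution and
#' allocate a fraction `1 - contamination` to their own species (binomially);
#' doublets are one cell of each species and split roughly 50/50.
#'
#' @param config A [sim_config()] whose `species` field holds `n_a`, `n_b`
#'   and `contamination`, plus `doublet_rate` and the depth parameters.
#' @return List with `counts` (data.frame `cell_id`, `species_a`,
#'   `species_b`) and `truth` (per-cell true species and doublet flag).
#' @export
generate_barnyard_mixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species
  assert_that(!is.null(sp), "config$species must be set")
  n_a <- sp$n_a; n_b <- sp$n_b; cont <- sp$contamination
  n_single <- n_a + n_b
  n_doublet <- with_substream(config$seed, 11L,
                              rbinom(1L, n_single, config$doublet_rate))
  with_substream(config$seed, 12L, {
    tot_s <- pmax(1L, round(rlnorm(n_single, config$depth_log_mean,
                                   config$depth_log_sd)))
    own <- rbinom(n_single, tot_s, 1 - cont)
    species <- rep(c("species_a", "species_b"), c(n_a, n_b))
    a_cnt <- ifelse(species == "species_a", own, tot_s - own)
    b_cnt <- tot_s - a_cnt
    if (n_doublet > 0) {
      tot_d <- pmax(2L, round(rlnorm(n_doublet, config$depth_log_mean +
                                       log(2), config$depth_log_sd)))
      a_d <- rbinom(n_doublet, tot_d, 0.5)
      a_cnt <- c(a_cnt, a_d)
      b_cnt <- c(b_cnt, tot_d - a_d)
      species <- c(species, rep("doublet", n_doublet))
    }
    n <- length(a_cnt)
    counts <- data.frame(cell_id = sprintf("bc_%04d", seq_len(n)),
                         species_a = a_cnt, species_b = b_cnt,
                         stringsAsFactors = FALSE)
    truth <- data.frame(cell_id = counts$cell_id, species = species,
                        doublet = species == "doublet",
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
  })
}

#' Generate bulk replicate count vectors
#'
#' Each replicate is an independent Poisson draw around `depth` total
#' fragments spread over peaks proportional to the same baseline rates used
#' by [generate_accessibility_experiment()]; serves as the bulk reference for
#' the aggregation analyses.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates. Default 4.
#' @param depth Expected total fragments per replicate. Default 1e6.
#' @return List of per-peak count vectors, length `n_reps`.
#' @export
generate_bulk_replicates <- function(config, n_reps = 4L, depth = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(n_reps >= 1L, "n_reps must be >= 1")
  base <- with_substream(config$seed, 1L, {
    log_r <- rnorm(config$n_peaks, config$baseline_log_mean,
                   config$baseline_log_sd)
    log_r
  })
  pr <- exp(base); pr <- pr / sum(pr)
  with_substream(config$seed, 21L, {
    lapply(seq_len(n_reps), function(i) {
      setNames(rpois(config$n_peaks, depth * pr),
               sprintf("peak_%05d", seq_len(config$n_peaks)))
    })
  })
}

#' Synthesise a genome carrying the peak set
#'
#' Builds one random sequence per chromosome, long enough to contain every
#' peak, honouring each peak's GC fraction, optionally planting exact motif
#' strings inside member peaks so that annotation recovery is checkable.
#' Labelled synthetic throughout: coordinates and composition have no
#' relation to any real genome.
#'
#' @param peaks A [peak_set()]; `gc` values are used where defined
#'   (0.41 otherwise).
#' @param planted Optional named list: motif string -> integer vector of peak
#'   row indices into which one exact copy is planted (at a random position,
#'   forward or reverse-complement at random).
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
synthesize_genome <- function(peaks, planted = NULL, seed = 1L) {
  chroms <- unique(peaks$chrom)
  with_substream(seed, 31L, {
    seqs <- lapply(chroms, function(ch) {
      len <- max(peaks$end[peaks$chrom == ch]) + 100L
      base_gc <- 0.41
      p <- c((1 - base_gc) / 2, base_gc / 2, base_gc / 2, (1 - base_gc) / 2)
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p)
      # rewrite each peak interval at its own GC
      rows <- which(peaks$chrom == ch)
      for (i in rows) {
        g <- peaks$gc[i]
        if (is.na(g)) g <- base_gc
        w <- peaks$end[i] - peaks$start[i]
        pp <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
        chars[(peaks$start[i] + 1L):peaks$end[i]] <-
          sample(c("A", "C", "G", "T"), w, replace = TRUE, prob = pp)
      }
      paste(chars, collapse = "")
    })
    names(seqs) <- chroms
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    if (!is.null(planted)) {
      for (motif in names(planted)) {
        for (i in planted[[motif]]) {
          w <- peaks$end[i] - peaks$start[i]
          L <- nchar(motif)
          assert_that(L <= w, "planted motif longer than peak")
          pos <- peaks$start[i] + sample.int(w - L + 1L, 1L)
          ins <- if (runif(1) < 0.5) motif else {
            as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
          }
          Biostrings::subseq(genome[[peaks$chrom[i]]], pos, pos + L - 1L) <-
            Biostrings::DNAString(ins)
        }
      }
    }
    genome
  })
}
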