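#' @useDynLib piatac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cor cutree dist hclust kmeans median p.adjust pchisq
#'   pnorm pt quantile rbinom rlnorm rmultinom rnorm rpois runif sd setNames
#'   wilcox.test chisq.test cor.test complete.cases
#' @importFrom utils read.table write.table head tail
NULL

# One global seed governs all randomness; each component draws from its own
# deterministically derived sub-stream so that adding draws to one stage never
# shifts another stage's stream.
substream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + offset * 7919 + 12345) %% 2147483587)
}

with_substream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, offset))
  force(code)
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Benjamini-Hochberg adjusted p-values (wrapper kept for a single audit point)
bh_adjust <- function(p) p.adjust(p, method = "BH")
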