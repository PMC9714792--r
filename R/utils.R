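#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix Matrix Diagonal colSums rowSums rowMeans colMeans readMM writeMM t
#' @importFrom stats rnbinom rpois rnorm runif median mad p.adjust pnorm pwilcox
#'   t.test fisher.test wilcox.test ks.test quantile setNames aggregate sd
#' @importFrom utils write.table read.table head
#' @importFrom graphics matplot legend
#' @importFrom grDevices pdf dev.off
#' @importFrom methods as is
NULL

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package route
# through this so that user-level RNG state is never clobbered.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible integer sub-seed for a named stage from a master seed.
# Keeps values well inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single value in [0, 1]", name)
  as.numeric(x)
}
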