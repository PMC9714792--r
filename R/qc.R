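#' Quality-control thresholds
#'
#' Cells are removed when their mitochondrial count fraction exceeds
#' \code{max_mito_fraction} (default 5\%), when they have fewer than
#' \code{min_genes} detected genes (default 200), or when their detected-gene
#' count exceeds the median plus \code{mad_multiplier} times the raw median
#' absolute deviation of detected-gene counts (default 3).
#'
#' @param max_mito_fraction maximum mitochondrial count fraction, in [0, 1].
#' @param min_genes minimum detected genes per cell.
#' @param mad_multiplier multiplier of the raw MAD for the upper gene bound.
#' @return an object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.05, min_genes = 200L,
                          mad_multiplier = 3) {
  if (mad_multiplier <= 0) stopf("'mad_multiplier' must be positive")
  structure(list(
    max_mito_fraction = check_fraction(max_mito_fraction, "max_mito_fraction"),
    min_genes = check_count(min_genes, "min_genes", 0L),
    mad_multiplier = mad_multiplier
  ), class = "qc_thresholds")
}

#' Filter cells on mitochondrial fraction and detected-gene bounds
#'
#' Removes cells with a mitochondrial count fraction above
#' \code{max_mito_fraction}, fewer than \code{min_genes} detected genes, or
#' more detected genes than \code{median + mad_multiplier * MAD} of the
#' detected-gene counts. The MAD is the raw median absolute deviation (no
#' normal-consistency scaling), and the upper cutoff is computed within each
#' sample when \code{sample} is supplied, mirroring per-sample processing
#' before integration.
#'
#' Mitochondrial genes are identified by \code{mito_genes} or, by default, the
#' \code{"MT-"} prefix of the gene identifier. When none are found the mito
#' rule is skipped with a warning and the skip is recorded in the report.
#'
#' @param counts genes x cells count matrix (dense or \code{Matrix} sparse)
#'   with gene and cell identifiers as dimnames.
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @param sample optional per-cell sample identifiers (length \code{ncol}).
#' @param mito_genes optional explicit mitochondrial gene identifiers.
#' @param upper_cutoff optional named per-sample vector of detected-gene
#'   upper cutoffs, overriding the median + MAD estimate. The report records
#'   the cutoffs used, so a second pass over the kept cells with the recorded
#'   cutoffs reproduces the filter (the cutoff is an estimated parameter of
#'   the dataset, not re-estimated on its own output).
#' @return list with \code{keep} (kept cell ids), \code{report} (per-cell
#'   data.frame: \code{cell}, \code{sample}, \code{n_detected},
#'   \code{mito_fraction}, \code{upper_cutoff}, \code{keep}, \code{rule}) and
#'   \code{mito_rule_applied}.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(), sample = NULL,
                      mito_genes = NULL, upper_cutoff = NULL) {
  if (ncol(counts) < 1L) stopf("at least one cell required")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (is.null(mito_genes))
    mito_genes <- grep("^MT-", rownames(counts), ignore.case = TRUE, value = TRUE)
  totals <- Matrix::colSums(counts)
  n_detected <- Matrix::colSums(counts > 0)
  mito_rule <- length(mito_genes) > 0
  if (mito_rule) {
    mito_fraction <- Matrix::colSums(counts[mito_genes, , drop = FALSE]) /
      pmax(totals, 1)
  } else {
    warnf("no mitochondrial genes found; mito rule skipped")
    mito_fraction <- rep(NA_real_, ncol(counts))
  }
  if (is.null(sample)) sample <- rep("all", ncol(counts))
  if (length(sample) != ncol(counts))
    stopf("'sample' must have one entry per cell")

  if (is.null(upper_cutoff)) {
    upper_cutoff <- vapply(split(n_detected, sample), function(x)
      median(x) + thresholds$mad_multiplier * mad(x, constant = 1), numeric(1))
  }
  upper_cutoff <- upper_cutoff[as.character(sample)]

  fail_mito <- mito_rule & !is.na(mito_fraction) &
    mito_fraction > thresholds$max_mito_fraction
  fail_low <- n_detected < thresholds$min_genes
  fail_high <- n_detected > upper_cutoff

  rule <- mapply(function(m, l, h) {
    r <- c(if (isTRUE(m)) "mito", if (l) "low_genes", if (h) "high_genes")
    if (length(r)) paste(r, collapse = ";") else ""
  }, fail_mito, fail_low, fail_high)

  keep <- !(fail_mito | fail_low | fail_high)
  report <- data.frame(
    cell = colnames(counts), sample = as.character(sample),
    n_detected = as.integer(n_detected), mito_fraction = mito_fraction,
    upper_cutoff = unname(upper_cutoff), keep = keep, rule = unname(rule),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(keep = colnames(counts)[keep], report = report,
       mito_rule_applied = mito_rule, thresholds = thresholds)
}

#' Library-size normalize and log-transform a count matrix
#'
#' Each cell's counts are scaled to a common total (\code{scale}, default
#' 1e4) and transformed as \code{log(1 + scale * count / cell_total)}.
#' Cells with zero total counts are dropped with a warning.
#'
#' @param counts genes x cells count matrix.
#' @param scale per-cell target total.
#' @return a sparse genes x cells matrix of normalized values with attributes
#'   \code{scale_factor} and \code{pseudocount} (1, inside \code{log1p}).
#' @export
lognormalize <- function(counts, scale = 1e4) {
  if (length(counts) == 0L || ncol(counts) == 0L) stopf("empty count matrix")
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warnf("dropping %d cell(s) with zero total counts", sum(totals == 0))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
    if (ncol(counts) == 0L) stopf("no cells with positive totals")
  }
  norm <- counts %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "scale_factor") <- scale
  attr(norm, "pseudocount") <- 1
  norm
}
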