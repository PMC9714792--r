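#' Log2 fold change between two groups of normalized values
#'
#' Fold change on the de-logged mean scale with a pseudocount guarding zeros:
#' \code{log2((mean(expm1(a)) + pseudocount) / (mean(expm1(b)) + pseudocount))}.
#' Input values are assumed log1p-normalized (see \code{\link{lognormalize}}).
#'
#' @param a,b numeric vectors of normalized expression in the two groups.
#' @param pseudocount positive offset on the de-logged mean scale (default 1).
#' @return a single log2 fold change; antisymmetric in \code{a}, \code{b}.
#' @export
log2fc <- function(a, b, pseudocount = 1) {
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  if (pseudocount <= 0) stopf("'pseudocount' must be positive")
  log2((mean(expm1(a)) + pseudocount) / (mean(expm1(b)) + pseudocount))
}

# Two-sided Wilcoxon rank-sum p-value for one numeric vector split by a
# logical group. Exact enumeration (via the null rank-sum distribution) when
# both groups have <= `exact_limit` observations and there are no ties;
# otherwise the normal approximation with tie correction and continuity
# correction. With every observation tied the statistic is degenerate and
# p = 1.
rank_sum_p <- function(values, in_group, exact_limit = 25L) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  r <- rank(values)
  w <- sum(r[in_group]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(values))
  if (!ties && n1 <= exact_limit && n2 <= exact_limit) {
    p <- if (w > n1 * n2 / 2) 2 * (1 - pwilcox(w - 1, n1, n2))
         else 2 * pwilcox(w, n1, n2)
    return(min(p, 1))
  }
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(2 * pnorm(-abs(z)), 1)
}

# Vectorized rank-sum scan: `mat` is genes x cells (dense), `in_group` a
# logical over cells. Returns a p-value per row, delegating each row to
# rank_sum_p.
rank_sum_scan <- function(mat, in_group, exact_limit = 25L) {
  apply(mat, 1, rank_sum_p, in_group = in_group, exact_limit = exact_limit)
}

#' Cluster marker genes by Wilcoxon rank-sum test
#'
#' Compares each gene between the target population and all other cells.
#' Genes are pre-filtered on detection fraction (\code{max(pct_in, pct_out) >=
#' min_pct}) and fold-change magnitude (\code{|log2fc| >= lfc_min}); the
#' surviving genes receive a two-sided Wilcoxon rank-sum p-value and
#' Bonferroni correction over the number of genes tested. Results are sorted
#' by adjusted p, then by decreasing \code{|log2fc|}.
#'
#' @param norm normalized genes x cells matrix from \code{\link{lognormalize}}.
#' @param labels per-cell population labels (vector aligned to columns), or a
#'   data.frame with \code{cell} and \code{population} columns.
#' @param target population id to contrast against the rest.
#' @param min_pct minimum detection fraction in either group (default 0.25).
#' @param lfc_min minimum absolute log2 fold change (default 0.25).
#' @param alpha significance level recorded for downstream filtering.
#' @param pseudocount passed to \code{\link{log2fc}}.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{pct_in},
#'   \code{pct_out}, \code{p}, \code{p_adj} and attributes \code{alpha},
#'   \code{n_tested}.
#' @export
find_markers <- function(norm, labels, target, min_pct = 0.25,
                         lfc_min = 0.25, alpha = 0.05, pseudocount = 1) {
  labels <- resolve_labels(labels, norm)
  in_group <- labels == target
  if (sum(in_group) < 3L || sum(!in_group) < 3L)
    stopf("both the target population and its complement need >= 3 cells")
  pct_in <- Matrix::rowMeans(norm[, in_group, drop = FALSE] > 0)
  pct_out <- Matrix::rowMeans(norm[, !in_group, drop = FALSE] > 0)
  mean_in <- Matrix::rowMeans(expm1(norm[, in_group, drop = FALSE]))
  mean_out <- Matrix::rowMeans(expm1(norm[, !in_group, drop = FALSE]))
  lfc <- log2((mean_in + pseudocount) / (mean_out + pseudocount))
  test <- pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= lfc_min
  n_tested <- sum(test)
  if (n_tested == 0L) {
    out <- data.frame(gene = character(0), log2fc = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      p = numeric(0), p_adj = numeric(0))
  } else {
    sub <- as.matrix(norm[test, , drop = FALSE])
    p <- rank_sum_scan(sub, in_group)
    out <- data.frame(gene = rownames(norm)[test], log2fc = lfc[test],
                      pct_in = pct_in[test], pct_out = pct_out[test],
                      p = p, p_adj = pmin(p * n_tested, 1),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$p_adj, -abs(out$log2fc)), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- n_tested
  out
}

# Accept either a vector of labels aligned to columns or a data.frame with
# cell/population columns; always return a character vector over columns.
resolve_labels <- function(labels, mat) {
  if (is.data.frame(labels)) {
    if (!all(c("cell", "population") %in% names(labels)))
      stopf("label data.frame needs 'cell' and 'population' columns")
    idx <- match(colnames(mat), labels$cell)
    if (anyNA(idx)) stopf("%d cells missing from label table", sum(is.na(idx)))
    return(as.character(labels$population[idx]))
  }
  if (length(labels) != ncol(mat))
    stopf("labels must have one entry per cell")
  as.character(labels)
}
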