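#' Per-cell gene-signature (module) score with bin-matched control genes
#'
#' Computes, for every cell, the mean normalized expression of the signature
#' genes minus the mean expression of a pooled control set. Genes are binned
#' by their dataset-mean expression into \code{n_bins} equal-size bins and,
#' for each signature gene, \code{ctrl_per_gene} control genes are drawn
#' uniformly from that gene's bin (excluding the signature genes themselves),
#' so the control set matches the signature's expression-level profile.
#' Deterministic given \code{seed}.
#'
#' @param norm normalized genes x cells matrix.
#' @param signature character vector of signature gene ids; genes absent from
#'   the matrix are dropped with a warning (an empty intersection is an
#'   error listing the missing genes).
#' @param n_bins number of expression bins (default 24).
#' @param ctrl_per_gene control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return numeric per-cell score vector (named by cell) with attributes
#'   \code{signature}, \code{n_controls}, \code{n_bins}, \code{seed}.
#' @export
signature_score <- function(norm, signature, n_bins = 24L,
                            ctrl_per_gene = 100L, seed = 1L) {
  present <- intersect(signature, rownames(norm))
  missing <- setdiff(signature, rownames(norm))
  if (!length(present))
    stopf("no signature gene found in the matrix; missing: %s",
          paste(missing, collapse = ", "))
  if (length(missing))
    warnf("%d signature gene(s) absent from the matrix: %s",
          length(missing), paste(head(missing, 10), collapse = ", "))
  means <- Matrix::rowMeans(norm)
  n_bins <- min(check_count(n_bins, "n_bins"), length(means))
  bin <- as.integer(cut(rank(means, ties.method = "first"),
                        breaks = n_bins, labels = FALSE))
  names(bin) <- rownames(norm)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      ## controls come from the gene's expression bin, excluding the
      ## signature itself so planted signal cannot contaminate the baseline
      pool <- setdiff(names(bin)[bin == bin[[g]]], present)
      if (!length(pool)) pool <- names(bin)[bin == bin[[g]]]
      sample(pool, min(ctrl_per_gene, length(pool)), replace = FALSE)
    }))
  })
  ## controls are pooled with multiplicity: every signature gene contributes
  ## an equal-weight control draw from its own bin
  ctrl_idx <- match(ctrl, rownames(norm))
  score <- Matrix::colMeans(norm[present, , drop = FALSE]) -
    Matrix::colMeans(norm[ctrl_idx, , drop = FALSE])
  attr(score, "signature") <- present
  attr(score, "n_controls") <- length(unique(ctrl))
  attr(score, "n_bins") <- n_bins
  attr(score, "seed") <- seed
  score
}

#' Cell-cycle phase assignment from S and G2M signature scores
#'
#' Scores each cell for the S and G2M gene programs with
#' \code{\link{signature_score}} and assigns: G1 when both scores are
#' non-positive, otherwise the phase with the larger score.
#'
#' @param norm normalized genes x cells matrix.
#' @param s_genes,g2m_genes gene lists for the S and G2M programs.
#' @param seed integer seed (distinct sub-seeds are derived per program).
#' @param ... passed to \code{\link{signature_score}}.
#' @return data.frame with columns \code{cell}, \code{s_score},
#'   \code{g2m_score}, \code{phase} (factor with levels G1, S, G2M).
#' @export
cell_cycle_phase <- function(norm, s_genes, g2m_genes, seed = 1L, ...) {
  s <- signature_score(norm, s_genes, seed = derive_seed(seed, "s_phase"), ...)
  g2m <- signature_score(norm, g2m_genes, seed = derive_seed(seed, "g2m_phase"), ...)
  phase <- ifelse(s <= 0 & g2m <= 0, "G1", ifelse(s > g2m, "S", "G2M"))
  data.frame(cell = colnames(norm), s_score = as.numeric(s),
             g2m_score = as.numeric(g2m),
             phase = factor(phase, levels = c("G1", "S", "G2M")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell-type proportion test with arcsine square-root transform
#'
#' For one population, computes its per-sample cell proportion, applies the
#' variance-stabilizing transform \code{asin(sqrt(p))}, and compares the two
#' conditions by a two-tailed two-sample t test (pooled variance by default;
#' small per-condition sample counts make Welch degrees of freedom unstable).
#'
#' @param meta per-cell data.frame with \code{sample}, \code{condition},
#'   \code{population} columns.
#' @param population population id to test.
#' @param var_equal use the pooled-variance t test (default TRUE).
#' @return list of class \code{proportion_test} with \code{population},
#'   \code{conditions} (alphabetical; \code{t} is condition 1 minus
#'   condition 2), \code{proportions} (per-sample data.frame), \code{t},
#'   \code{df}, \code{p}.
#' @export
proportion_test <- function(meta, population, var_equal = TRUE) {
  need <- c("sample", "condition", "population")
  if (!all(need %in% names(meta)))
    stopf("meta needs columns: %s", paste(need, collapse = ", "))
  tab <- table(meta$sample, meta$population)
  props <- as.numeric(tab[, population]) / rowSums(tab)
  samp <- rownames(tab)
  cond <- meta$condition[match(samp, meta$sample)]
  conds <- sort(unique(as.character(cond)))   # deterministic group order
  if (length(conds) != 2L) stopf("exactly two conditions required")
  if (any(table(cond) < 2L)) stopf("each condition needs >= 2 samples")
  z <- asin(sqrt(props))
  a <- z[cond == conds[1]]; b <- z[cond == conds[2]]
  df <- length(a) + length(b) - 2L
  if (sd(a) == 0 && sd(b) == 0) {
    tt <- list(statistic = if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf,
               p.value = if (mean(a) == mean(b)) 1 else 0,
               parameter = df)
  } else {
    fit <- t.test(a, b, var.equal = var_equal)
    tt <- list(statistic = unname(fit$statistic), p.value = fit$p.value,
               parameter = unname(fit$parameter))
  }
  structure(list(
    population = population,
    conditions = conds,
    proportions = data.frame(sample = samp, condition = as.character(cond),
                             proportion = props, transformed = z,
                             stringsAsFactors = FALSE, row.names = NULL),
    t = tt$statistic, df = tt$parameter, p = tt$p.value
  ), class = "proportion_test")
}

#' Gene-set enrichment by one-sided Fisher exact test
#'
#' For each set, builds the 2x2 overlap table of the query against the
#' universe and computes the one-sided (enrichment) Fisher exact p-value,
#' followed by Benjamini-Hochberg correction across sets.
#'
#' @param query character vector of gene ids; must be a subset of
#'   \code{universe}.
#' @param sets named list of gene-id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe background gene ids.
#' @param alpha significance level recorded on the result.
#' @return data.frame with \code{set}, \code{overlap}, \code{set_size},
#'   \code{odds_ratio}, \code{p}, \code{p_adj}, sorted by \code{p_adj}.
#' @export
fisher_enrichment <- function(query, sets, universe, alpha = 0.05) {
  if (!length(query) || !length(universe)) stopf("empty query or universe")
  if (!all(query %in% universe)) stopf("query must be a subset of the universe")
  universe <- unique(universe)
  query <- unique(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(query, s))
    tab <- matrix(c(k, length(s) - k,
                    length(query) - k,
                    length(universe) - length(s) - length(query) + k), 2, 2)
    ft <- fisher.test(tab, alternative = "greater")
    data.frame(set = nm, overlap = k, set_size = length(s),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p_adj, out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}
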