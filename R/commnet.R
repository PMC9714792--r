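#' @section Communication scoring model:
#' A directed edge from population A to population B through a
#' ligand-receptor pair (L, R) exists when L is significantly enriched in A
#' and R is significantly enriched in B (log2 fold change of the population
#' against all other cells at least \code{lfc_min}, Bonferroni-adjusted
#' Wilcoxon p below \code{alpha}). The edge weight is the additive sum
#' \code{w_ligand + w_db + w_receptor}: the ligand's enrichment log2FC in the
#' source, the database interaction weight of the pair, and the receptor's
#' enrichment log2FC in the target. Autocrine (A = A) edges are included.
#' @name commnet
#' @keywords internal
NULL

# Precompute the per-gene quantities that are invariant under label
# permutation: de-logged expression, per-gene ranks across all cells, and the
# tie-correction term of the rank-sum variance.
lr_precompute <- function(norm, genes) {
  genes <- intersect(genes, rownames(norm))
  X <- as.matrix(norm[genes, , drop = FALSE])
  E <- expm1(X)
  R <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  tie_term <- numeric(nrow(X))
  has_ties <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    R[i, ] <- rank(X[i, ])
    tt <- table(X[i, ])
    tie_term[i] <- sum(tt^3 - tt)
    has_ties[i] <- any(tt > 1)
  }
  list(genes = genes, E = E, R = R, row_sums_E = rowSums(E),
       tie_term = tie_term, has_ties = has_ties, n = ncol(X))
}

# Enrichment weight matrix (genes x populations) for one label assignment.
# weight = log2FC(population vs rest) where the gene passes lfc_min and the
# Bonferroni-adjusted two-sided Wilcoxon p (exact when both groups are small
# and the gene has no ties, matching rank_sum_p); NA where not admitted.
# Populations with fewer than 3 cells are skipped (all NA).
lr_weight_matrix <- function(pre, labels, pops, lfc_min = 0.25, alpha = 0.05,
                             pseudocount = 1, exact_limit = 25L) {
  M <- vapply(pops, function(p) as.numeric(labels == p), numeric(length(labels)))
  n1 <- colSums(M)
  n <- pre$n
  n_genes <- length(pre$genes)
  RS <- pre$R %*% M
  W <- sweep(RS, 2, n1 * (n1 + 1) / 2)
  S <- pre$E %*% M
  mean_in <- sweep(S, 2, pmax(n1, 1), "/")
  mean_out <- sweep(-S + pre$row_sums_E, 2, pmax(n - n1, 1), "/")
  lfc <- log2((mean_in + pseudocount) / (mean_out + pseudocount))

  p <- matrix(NA_real_, n_genes, length(pops), dimnames = list(pre$genes, pops))
  for (j in seq_along(pops)) {
    if (n1[j] < 3L || (n - n1[j]) < 3L) next
    n2 <- n - n1[j]
    exact <- !pre$has_ties & n1[j] <= exact_limit & n2 <= exact_limit
    if (any(exact)) {
      w <- W[exact, j]
      hi <- w > n1[j] * n2 / 2
      pe <- ifelse(hi, 2 * (1 - pwilcox(w - 1, n1[j], n2)),
                   2 * pwilcox(w, n1[j], n2))
      p[exact, j] <- pmin(pe, 1)
    }
    if (any(!exact)) {
      sigma2 <- n1[j] * n2 / 12 *
        ((n + 1) - pre$tie_term[!exact] / (n * (n - 1)))
      z <- W[!exact, j] - n1[j] * n2 / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      pa <- pmin(2 * pnorm(-abs(z)), 1)
      pa[sigma2 <= 0] <- 1
      p[!exact, j] <- pa
    }
  }
  p_adj <- pmin(p * n_genes, 1)
  wmat <- ifelse(!is.na(p_adj) & lfc >= lfc_min & p_adj < alpha, lfc, NA_real_)
  dimnames(wmat) <- list(pre$genes, pops)
  wmat
}

#' Per-population enrichment weights for a gene panel
#'
#' For each population and each gene of the panel, computes the gene's log2
#' fold change of that population against all other cells; the weight is kept
#' when the gene qualifies as enriched (log2FC at least \code{lfc_min} and
#' Bonferroni-adjusted two-sided Wilcoxon p below \code{alpha}, corrected over
#' the panel size) and is absent otherwise. Populations with fewer than 3
#' cells are skipped with a warning.
#'
#' @param norm normalized genes x cells matrix.
#' @param labels per-cell population labels (vector or data.frame with
#'   \code{cell}/\code{population}).
#' @param genes gene panel (typically all ligands and receptors of a
#'   database); genes absent from the matrix are dropped.
#' @param lfc_min minimum log2 fold change (default 0.25).
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @param pseudocount passed to the fold-change computation.
#' @return data.frame with columns \code{population}, \code{gene},
#'   \code{weight}; attribute \code{genes} records the panel actually tested.
#' @export
expression_weights <- function(norm, labels, genes, lfc_min = 0.25,
                               alpha = 0.05, pseudocount = 1) {
  labels <- resolve_labels(labels, norm)
  pre <- lr_precompute(norm, genes)
  if (!length(pre$genes)) stopf("none of the genes are present in the matrix")
  pops <- sort(unique(labels))
  small <- pops[table(labels)[pops] < 3L]
  if (length(small))
    warnf("population(s) with < 3 cells skipped: %s", paste(small, collapse = ", "))
  wmat <- lr_weight_matrix(pre, labels, pops, lfc_min, alpha, pseudocount)
  idx <- which(!is.na(wmat), arr.ind = TRUE)
  out <- data.frame(population = colnames(wmat)[idx[, 2]],
                    gene = rownames(wmat)[idx[, 1]],
                    weight = wmat[idx], stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$population, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genes") <- pre$genes
  attr(out, "weight_matrix") <- wmat
  out
}

#' Score ligand-receptor interactions between populations
#'
#' Emits one directed edge for every (source population, target population,
#' pair) where the pair's ligand has an enrichment weight in the source and
#' its receptor has one in the target. The edge weight is the additive sum of
#' the ligand weight, the database pair weight, and the receptor weight.
#' Autocrine edges (source = target) are included. Pairs whose ligand or
#' receptor is absent from the tested gene panel are dropped and counted in
#' the \code{dropped_pairs} attribute.
#'
#' @param weights output of \code{\link{expression_weights}}.
#' @param db data.frame with \code{ligand}, \code{receptor}, \code{weight}
#'   columns (see \code{\link{read_lr_pairs}}).
#' @return data.frame of edges: \code{source}, \code{target}, \code{ligand},
#'   \code{receptor}, \code{w_ligand}, \code{w_db}, \code{w_receptor},
#'   \code{weight}.
#' @export
score_interactions <- function(weights, db) {
  if (!nrow(db)) stopf("empty ligand-receptor database")
  genes <- attr(weights, "genes")
  present <- db$ligand %in% genes & db$receptor %in% genes
  dropped <- sum(!present)
  db <- db[present, , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(db))) {
    lw <- weights[weights$gene == db$ligand[i], , drop = FALSE]
    rw <- weights[weights$gene == db$receptor[i], , drop = FALSE]
    if (!nrow(lw) || !nrow(rw)) next
    grid <- expand.grid(si = seq_len(nrow(lw)), ti = seq_len(nrow(rw)))
    edges[[length(edges) + 1L]] <- data.frame(
      source = lw$population[grid$si], target = rw$population[grid$ti],
      ligand = db$ligand[i], receptor = db$receptor[i],
      w_ligand = lw$weight[grid$si], w_db = db$weight[i],
      w_receptor = rw$weight[grid$ti],
      stringsAsFactors = FALSE)
  }
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(source = character(0), target = character(0),
                         ligand = character(0), receptor = character(0),
                         w_ligand = numeric(0), w_db = numeric(0),
                         w_receptor = numeric(0))
  out$weight <- out$w_ligand + out$w_db + out$w_receptor
  out <- out[order(-out$weight), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_pairs") <- dropped
  out
}

#' Permutation significance of ligand-receptor edges
#'
#' Re-scores the observed edges under permutations of the population labels
#' (shuffled across cells within each sample, preserving per-sample
#' population sizes) and reports, per edge, the add-one permutation p-value
#' \code{(1 + #\{permuted weight >= observed weight\}) / (1 + n_perm)}. In a
#' permutation where the edge's ligand or receptor is not admitted the
#' permuted weight is treated as -Inf. Only the rank-sum statistics and group
#' means are recomputed per permutation; the gene ranks are label-invariant
#' and precomputed once, which is exactly equivalent to naive recomputation.
#'
#' @param norm normalized genes x cells matrix.
#' @param labels per-cell population labels.
#' @param db ligand-receptor database data.frame.
#' @param n_perm number of permutations (default 1000; values below 100
#'   trigger a resolution warning). The study-scale setting is 100000.
#' @param seed integer seed.
#' @param sample optional per-cell sample ids defining the permutation
#'   stratum; \code{NULL} shuffles across all cells.
#' @param lfc_min,alpha,pseudocount edge-admission parameters, as in
#'   \code{\link{expression_weights}}.
#' @return the observed edge data.frame with an added \code{p_perm} column.
#' @export
permutation_test <- function(norm, labels, db, n_perm = 1000L, seed = 1L,
                             sample = NULL, lfc_min = 0.25, alpha = 0.05,
                             pseudocount = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100L) warnf("n_perm < 100 gives coarse p-value resolution")
  labels <- resolve_labels(labels, norm)
  if (is.null(sample)) sample <- rep("all", ncol(norm))
  genes <- unique(c(db$ligand, db$receptor))
  pre <- lr_precompute(norm, genes)
  if (!length(pre$genes)) stopf("no database gene present in the matrix")
  pops <- sort(unique(labels))

  wmat <- lr_weight_matrix(pre, labels, pops, lfc_min, alpha, pseudocount)
  weights <- weights_from_matrix(wmat)
  attr(weights, "genes") <- pre$genes
  edges <- score_interactions(weights, db)
  if (!nrow(edges)) {
    edges$p_perm <- numeric(0)
    return(edges)
  }
  li <- match(edges$ligand, pre$genes); si <- match(edges$source, pops)
  ri <- match(edges$receptor, pre$genes); ti <- match(edges$target, pops)
  exceed <- integer(nrow(edges))
  strata <- split(seq_along(labels), sample)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- labels
      for (s in strata) perm[s] <- perm[s][sample.int(length(s))]
      wp <- lr_weight_matrix(pre, perm, pops, lfc_min, alpha, pseudocount)
      wl <- wp[cbind(li, si)]
      wr <- wp[cbind(ri, ti)]
      pw <- wl + edges$w_db + wr
      exceed <- exceed + (!is.na(pw) & pw >= edges$weight)
    }
  })
  edges$p_perm <- (1 + exceed) / (1 + n_perm)
  edges
}

#' Export a scored edge list as GraphML
#'
#' Writes the population-to-population communication network (edge attributes:
#' ligand, receptor, weight, p_perm) to GraphML for plotting in graph tools.
#'
#' @param edges edge data.frame from \code{\link{score_interactions}} or
#'   \code{\link{permutation_test}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(edges, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stopf("igraph is required for GraphML export")
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target",
              intersect(c("ligand", "receptor", "weight", "p_perm"),
                        names(edges)))],
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# long weight data.frame from a genes x populations weight matrix
weights_from_matrix <- function(wmat) {
  idx <- which(!is.na(wmat), arr.ind = TRUE)
  out <- data.frame(population = colnames(wmat)[idx[, 2]],
                    gene = rownames(wmat)[idx[, 1]],
                    weight = wmat[idx], stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$population, out$gene), , drop = FALSE]
}

#' Aggregate a scored network into per-population ligand/receptor scores
#'
#' Restricted to edges significant at \code{p_perm < alpha}: a population's
#' ligand score is the sum of the ligand weights of its outgoing significant
#' edges, and its receptor score the sum of the receptor weights of its
#' incoming significant edges. Pairwise population-to-population edge counts
#' are tallied both over all edges and over significant edges.
#'
#' @param edges edge data.frame with \code{p_perm} (from
#'   \code{\link{permutation_test}}).
#' @param alpha significance level on \code{p_perm} (default 0.05).
#' @return list of class \code{network_summary}: \code{population_scores}
#'   (data.frame: \code{population}, \code{ligand_score},
#'   \code{receptor_score}), \code{edge_counts} and
#'   \code{edge_counts_significant} (source x target matrices),
#'   \code{edge_weights_significant} (source x target total-weight matrix).
#' @export
summarize_network <- function(edges, alpha = 0.05) {
  pops <- sort(unique(c(edges$source, edges$target)))
  sig <- edges[!is.na(edges$p_perm) & edges$p_perm < alpha, , drop = FALSE]
  lig <- setNames(numeric(length(pops)), pops)
  rec <- setNames(numeric(length(pops)), pops)
  if (nrow(sig)) {
    ls <- tapply(sig$w_ligand, sig$source, sum)
    rs <- tapply(sig$w_receptor, sig$target, sum)
    lig[names(ls)] <- ls
    rec[names(rs)] <- rs
  }
  count_mat <- function(e) {
    m <- matrix(0L, length(pops), length(pops), dimnames = list(pops, pops))
    if (nrow(e)) {
      tab <- table(factor(e$source, pops), factor(e$target, pops))
      m[] <- as.integer(tab)
    }
    m
  }
  wmat <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (nrow(sig))
    for (i in seq_len(nrow(sig)))
      wmat[sig$source[i], sig$target[i]] <- wmat[sig$source[i], sig$target[i]] +
        sig$weight[i]
  structure(list(
    population_scores = data.frame(population = pops,
                                   ligand_score = unname(lig),
                                   receptor_score = unname(rec),
                                   stringsAsFactors = FALSE),
    edge_counts = count_mat(edges),
    edge_counts_significant = count_mat(sig),
    edge_weights_significant = wmat,
    alpha = alpha
  ), class = "network_summary")
}
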