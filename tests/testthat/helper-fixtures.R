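# Shared fixtures, built in code at test time.

# small simulated expression dataset with planted markers and one LR channel
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- sim_expr_params(
        n_populations = 4, n_samples_per_condition = 3, cells_per_sample = 120,
        n_genes = 600, baseline_mean = 0.4, dispersion = 2,
        marker_genes_per_population = 6, marker_log2fc = 2,
        condition_de_genes = 20, condition_log2fc = 1,
        active_lr_channels = list(
          list(source = "P1", target = "P2", ligand = "LIGA", receptor = "RECA")),
        seed = 42)
      cache <<- simulate_counts(p)
    }
    cache
  }
})

# normalized matrix + metadata from the small dataset after QC
small_norm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      qc <- qc_filter(sim$counts, qc_thresholds(min_genes = 50),
                      sample = sim$meta$sample)
      norm <- lognormalize(sim$counts[, qc$keep, drop = FALSE])
      meta <- sim$meta[sim$meta$cell %in% colnames(norm), , drop = FALSE]
      cache <<- list(norm = norm, meta = meta, truth = sim$truth)
    }
    cache
  }
})

# Build one cell's count column with an exact detected-gene count and exact
# mitochondrial count fraction. Gene 1 is "MT-1".
make_cell <- function(n_genes, detected, mito_fraction = 0) {
  col <- numeric(n_genes)
  if (mito_fraction > 0) {
    # total chosen so the mito count is integral: total = 1000
    mito <- round(1000 * mito_fraction)
    rest <- 1000 - mito
    k <- detected - 1L
    base <- rest %/% k
    col[1 + seq_len(k)] <- base
    col[1 + seq_len(rest - base * k)] <- col[1 + seq_len(rest - base * k)] + 1
    col[1] <- mito
  } else {
    col[1 + seq_len(detected)] <- 1
  }
  col
}

# Exact two-sided Wilcoxon rank-sum p by brute-force enumeration of all
# group assignments (independent oracle; no ties assumed).
brute_wilcox_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(w_all <= w_obs); hi <- mean(w_all >= w_obs)
  min(2 * min(lo, hi), 1)
}

# Yen threshold by exhaustive search: same 256-bin histogram, criterion
# evaluated with explicit sums at every candidate split level.
brute_yen <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  best <- -Inf; best_t <- 1L
  for (t in seq_len(n_bins - 1L)) {
    p1 <- sum(p[1:t]); g1 <- sum(p[1:t]^2); g2 <- sum(p[(t + 1):n_bins]^2)
    if (p1 <= 0 || p1 >= 1 || g1 <= 0 || g2 <= 0) next
    crit <- -log(g1 * g2) + 2 * log(p1 * (1 - p1))
    if (crit > best) { best <- crit; best_t <- t }
  }
  centers[best_t]
}
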