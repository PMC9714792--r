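#' Parameters for the synthetic single-cell expression generator
#'
#' Bundles and validates every knob of the negative-binomial count simulator.
#' The defaults emulate the design the downstream statistics assume: a
#' pulmonary-artery-like dataset of 14 cell populations observed in two
#' conditions (donor and disease) with 3 biological samples each,
#' cluster-specific marker genes, condition-specific fold changes, a
#' mitochondrial gene block (named with the \code{"MT-"} prefix so QC mito
#' detection is exercised end-to-end), and optional planted ligand-receptor
#' channels.
#'
#' @param n_populations number of cell populations.
#' @param n_samples_per_condition biological samples per condition.
#' @param cells_per_sample cells drawn for each sample.
#' @param n_genes total number of genes (including mito/marker/DE blocks).
#' @param baseline_mean expected counts per gene per cell before planting.
#' @param dispersion negative-binomial size parameter; variance is
#'   \code{mu + mu^2 / dispersion}. \code{Inf} (or \code{poisson = TRUE})
#'   switches to the Poisson limit.
#' @param poisson draw Poisson counts instead of negative binomial.
#' @param marker_genes_per_population planted marker genes per population.
#' @param marker_log2fc log2 elevation of marker genes in their population.
#' @param condition_de_genes number of genes elevated in the disease condition.
#' @param condition_log2fc log2 elevation of those genes in disease cells.
#' @param n_mito_genes size of the mitochondrial gene block.
#' @param mito_fraction_range per-cell expected mitochondrial count fraction is
#'   drawn uniformly from this interval.
#' @param proportions optional \code{n_populations x 2} matrix (columns
#'   \code{donor}, \code{disease}) of population proportions per condition;
#'   each column must sum to 1. \code{NULL} means uniform in both conditions.
#' @param active_lr_channels list of planted communication channels, each a
#'   list/vector with elements \code{source}, \code{target}, \code{ligand},
#'   \code{receptor} (population ids and gene names).
#' @param lr_log2fc log2 elevation of ligand genes in the source population and
#'   receptor genes in the target population.
#' @param conditions labels for the two conditions.
#' @param seed integer seed; mandatory for reproducibility.
#' @return an object of class \code{sim_expr_params}.
#' @export
sim_expr_params <- function(n_populations = 14L,
                            n_samples_per_condition = 3L,
                            cells_per_sample = 400L,
                            n_genes = 2000L,
                            baseline_mean = 0.3,
                            dispersion = 2,
                            poisson = FALSE,
                            marker_genes_per_population = 10L,
                            marker_log2fc = 2,
                            condition_de_genes = 50L,
                            condition_log2fc = 1,
                            n_mito_genes = 10L,
                            mito_fraction_range = c(0.01, 0.04),
                            proportions = NULL,
                            active_lr_channels = list(),
                            lr_log2fc = 2,
                            conditions = c("donor", "disease"),
                            seed = 1L) {
  p <- list(
    n_populations = check_count(n_populations, "n_populations"),
    n_samples_per_condition = check_count(n_samples_per_condition, "n_samples_per_condition"),
    cells_per_sample = check_count(cells_per_sample, "cells_per_sample"),
    n_genes = check_count(n_genes, "n_genes"),
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    poisson = isTRUE(poisson) || is.infinite(dispersion),
    marker_genes_per_population = check_count(marker_genes_per_population, "marker_genes_per_population", 0L),
    marker_log2fc = marker_log2fc,
    condition_de_genes = check_count(condition_de_genes, "condition_de_genes", 0L),
    condition_log2fc = condition_log2fc,
    n_mito_genes = check_count(n_mito_genes, "n_mito_genes", 0L),
    mito_fraction_range = mito_fraction_range,
    proportions = proportions,
    active_lr_channels = active_lr_channels,
    lr_log2fc = lr_log2fc,
    conditions = conditions,
    seed = check_count(seed, "seed", 0L)
  )
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    stopf("'baseline_mean' must be positive")
  if (!p$poisson && (!is.numeric(dispersion) || dispersion <= 0))
    stopf("'dispersion' must be positive (or Inf for the Poisson limit)")
  if (length(mito_fraction_range) != 2L || any(mito_fraction_range < 0) ||
      any(mito_fraction_range > 1) || mito_fraction_range[1] > mito_fraction_range[2])
    stopf("'mito_fraction_range' must be an increasing interval within [0, 1]")
  if (length(conditions) != 2L) stopf("exactly two condition labels required")
  if (!is.null(proportions)) {
    proportions <- as.matrix(proportions)
    if (nrow(proportions) != p$n_populations || ncol(proportions) != 2L)
      stopf("'proportions' must be n_populations x 2")
    if (any(proportions < 0) || any(abs(colSums(proportions) - 1) > 1e-8))
      stopf("each condition's proportions must be non-negative and sum to 1")
    p$proportions <- proportions
  }
  lr_genes <- unique(unlist(lapply(active_lr_channels, function(ch)
    c(ch[["ligand"]], ch[["receptor"]]))))
  n_reserved <- p$n_mito_genes +
    p$n_populations * p$marker_genes_per_population +
    p$condition_de_genes + length(lr_genes)
  if (n_reserved > p$n_genes)
    stopf("planted gene demands (%d) exceed n_genes (%d)", n_reserved, p$n_genes)
  structure(p, class = "sim_expr_params")
}

#' Simulate a single-cell count matrix with known ground truth
#'
#' Draws gene-by-cell counts from a negative-binomial (or Poisson) model around
#' \code{baseline_mean}, then plants structure on the mean scale: each
#' population's marker genes are multiplied by \code{2^marker_log2fc} in that
#' population, condition DE genes by \code{2^condition_log2fc} in disease
#' cells, and ligand (receptor) genes of each active channel are elevated by
#' \code{2^lr_log2fc} in the source (target) population. A designated
#' \code{"MT-"} gene block receives per-cell expected mitochondrial fractions
#' drawn from \code{mito_fraction_range}. Fully reproducible given the seed.
#'
#' @param params a \code{\link{sim_expr_params}} object.
#' @return a list of class \code{sim_expr} with elements \code{counts}
#'   (sparse genes x cells \code{dgCMatrix}), \code{meta} (data.frame with
#'   \code{cell}, \code{sample}, \code{condition}, \code{population}), and
#'   \code{truth} (all planted parameters and realized labels).
#' @export
simulate_counts <- function(params) {
  if (!inherits(params, "sim_expr_params")) params <- do.call(sim_expr_params, params)
  p <- params
  with_seed(p$seed, {
    pops <- paste0("P", seq_len(p$n_populations))
    props <- p$proportions
    if (is.null(props))
      props <- matrix(1 / p$n_populations, p$n_populations, 2)
    rownames(props) <- pops
    colnames(props) <- p$conditions

    ## gene layout: mito block, per-population marker blocks, condition DE
    ## block, ligand/receptor genes, filler
    lr_genes <- unique(unlist(lapply(p$active_lr_channels, function(ch)
      c(ch[["ligand"]], ch[["receptor"]]))))
    n_mark <- p$n_populations * p$marker_genes_per_population
    gene_ids <- character(p$n_genes)
    idx <- 0L
    mito_idx <- seq_len(p$n_mito_genes)
    gene_ids[mito_idx] <- paste0("MT-", seq_len(p$n_mito_genes))
    idx <- p$n_mito_genes
    marker_idx <- if (n_mark > 0) idx + seq_len(n_mark) else integer(0)
    gene_ids[marker_idx] <- paste0("MRK", seq_len(max(n_mark, 0)))
    idx <- idx + n_mark
    de_idx <- if (p$condition_de_genes > 0) idx + seq_len(p$condition_de_genes) else integer(0)
    gene_ids[de_idx] <- paste0("DE", seq_len(max(p$condition_de_genes, 0)))
    idx <- idx + p$condition_de_genes
    lr_idx <- if (length(lr_genes)) idx + seq_along(lr_genes) else integer(0)
    gene_ids[lr_idx] <- lr_genes
    idx <- idx + length(lr_genes)
    filler <- seq_len(p$n_genes) > idx
    gene_ids[filler] <- sprintf("G%05d", which(filler))

    markers_by_pop <- if (n_mark > 0)
      setNames(split(gene_ids[marker_idx],
                     rep(pops, each = p$marker_genes_per_population)), NULL)
    else list()
    names(markers_by_pop) <- if (n_mark > 0) pops else character(0)

    ## cell sheet
    samples <- as.vector(outer(seq_len(p$n_samples_per_condition), p$conditions,
                               function(i, cond) paste0(cond, "_", i)))
    sample_cond <- rep(p$conditions, each = p$n_samples_per_condition)
    meta <- do.call(rbind, lapply(seq_along(samples), function(s) {
      pop <- sample(pops, p$cells_per_sample, replace = TRUE,
                    prob = props[, sample_cond[s]])
      data.frame(sample = samples[s], condition = sample_cond[s],
                 population = pop, stringsAsFactors = FALSE)
    }))
    meta$cell <- sprintf("cell%05d", seq_len(nrow(meta)))
    meta <- meta[, c("cell", "sample", "condition", "population")]
    n_cells <- nrow(meta)

    ## per-cell expected mito fraction
    mito_frac <- runif(n_cells, p$mito_fraction_range[1], p$mito_fraction_range[2])

    ## mean matrix (genes x cells), built per cell group to limit peak memory
    mu_gene <- rep(p$baseline_mean, p$n_genes)
    counts <- matrix(0L, p$n_genes, n_cells)
    for (pop in pops) {
      for (cond in p$conditions) {
        cells <- which(meta$population == pop & meta$condition == cond)
        if (!length(cells)) next
        mu <- mu_gene
        if (length(markers_by_pop))
          mu[match(markers_by_pop[[pop]], gene_ids)] <-
            mu[match(markers_by_pop[[pop]], gene_ids)] * 2^p$marker_log2fc
        if (cond == p$conditions[2] && length(de_idx))
          mu[de_idx] <- mu[de_idx] * 2^p$condition_log2fc
        for (ch in p$active_lr_channels) {
          if (identical(ch[["source"]], pop))
            mu[match(ch[["ligand"]], gene_ids)] <-
              mu[match(ch[["ligand"]], gene_ids)] * 2^p$lr_log2fc
          if (identical(ch[["target"]], pop))
            mu[match(ch[["receptor"]], gene_ids)] <-
              mu[match(ch[["receptor"]], gene_ids)] * 2^p$lr_log2fc
        }
        ## mito means rescaled per cell so the expected mito count share
        ## equals the cell's drawn fraction f: mito_total = f/(1-f) * rest
        non_mito_total <- sum(mu[-mito_idx])
        mu_block <- matrix(mu, p$n_genes, length(cells))
        if (p$n_mito_genes > 0) {
          f <- mito_frac[cells]
          mito_total <- f / (1 - f) * non_mito_total
          mu_block[mito_idx, ] <- matrix(mito_total / p$n_mito_genes,
                                         p$n_mito_genes, length(cells),
                                         byrow = TRUE)
        }
        n <- length(mu_block)
        counts[, cells] <- if (p$poisson) rpois(n, mu_block)
                           else rnbinom(n, mu = mu_block, size = p$dispersion)
      }
    }
    dimnames(counts) <- list(gene_ids, meta$cell)
    counts <- Matrix::Matrix(counts * 1.0, sparse = TRUE)

    truth <- list(
      params = unclass(p)[setdiff(names(p), "proportions")],
      proportions = props,
      populations = pops,
      samples = samples,
      markers_by_population = markers_by_pop,
      condition_de_genes = gene_ids[de_idx],
      mito_genes = gene_ids[mito_idx],
      active_lr_channels = p$active_lr_channels,
      cell_population = setNames(meta$population, meta$cell),
      cell_condition = setNames(meta$condition, meta$cell),
      mito_fraction = setNames(mito_frac, meta$cell)
    )
    structure(list(counts = counts, meta = meta, truth = truth),
              class = "sim_expr")
  })
}

#' Parameters for the synthetic vessel-image generator
#'
#' Geometry and noise parameters for a transverse vessel section rendered as
#' concentric rings: lumen, a thin VWF-lined intima between
#' \code{lumen_radius} and \code{media_inner_radius}, an ACTA2-positive media,
#' and an adventitia. Nuclei are placed in the media without overlap and a
#' planted fraction of them carries signal in the proliferation-marker channel.
#'
#' @param image_size side length in pixels (square image).
#' @param lumen_radius,media_inner_radius,media_outer_radius,adventitia_outer_radius
#'   ring radii in pixels, strictly increasing.
#' @param n_medial_nuclei number of nuclei placed in the media.
#' @param nucleus_radius nucleus disk radius in pixels.
#' @param positive_nucleus_fraction fraction of medial nuclei positive for the
#'   marker channel.
#' @param channel_snr ratio of foreground amplitude (1.0) to Gaussian noise
#'   standard deviation; \code{Inf} means noise-free (pure ring/disk
#'   indicators, no background baseline).
#' @param background camera background baseline added to every channel when
#'   noise is on (fraction of the intensity range, default 0.1).
#' @param max_place_retries placement attempts per nucleus before failing.
#' @param seed integer seed.
#' @return an object of class \code{sim_image_params}.
#' @export
sim_image_params <- function(image_size = 256L,
                             lumen_radius = 40,
                             media_inner_radius = 46,
                             media_outer_radius = 80,
                             adventitia_outer_radius = 105,
                             n_medial_nuclei = 20L,
                             nucleus_radius = 5,
                             positive_nucleus_fraction = 0.25,
                             channel_snr = 20,
                             background = 0.1,
                             max_place_retries = 1000L,
                             seed = 1L) {
  radii <- c(lumen_radius, media_inner_radius, media_outer_radius,
             adventitia_outer_radius)
  if (any(diff(radii) <= 0)) stopf("ring radii must be strictly increasing")
  if (2 * adventitia_outer_radius >= image_size)
    stopf("image_size must exceed the vessel diameter")
  p <- list(
    image_size = check_count(image_size, "image_size", 16L),
    lumen_radius = lumen_radius,
    media_inner_radius = media_inner_radius,
    media_outer_radius = media_outer_radius,
    adventitia_outer_radius = adventitia_outer_radius,
    n_medial_nuclei = check_count(n_medial_nuclei, "n_medial_nuclei", 0L),
    nucleus_radius = nucleus_radius,
    positive_nucleus_fraction = check_fraction(positive_nucleus_fraction,
                                               "positive_nucleus_fraction"),
    channel_snr = channel_snr,
    background = check_fraction(background, "background"),
    max_place_retries = check_count(max_place_retries, "max_place_retries"),
    seed = check_count(seed, "seed", 0L)
  )
  if (!is.numeric(channel_snr) || channel_snr <= 0)
    stopf("'channel_snr' must be positive (Inf for noise-free)")
  structure(p, class = "sim_image_params")
}

# squared-distance field from a center, on the pixel-center grid
# (row/col, 0-based, pixel centers at integer coordinates)
dist_field <- function(size, center) {
  rows <- matrix(0:(size - 1), size, size)
  cols <- matrix(0:(size - 1), size, size, byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2)
}

#' Simulate a multichannel transverse vessel image with known ground truth
#'
#' Emits five channels as matrices in [0, 1]: \code{dapi} (nucleus disks),
#' \code{vwf} (intimal annulus at the lumen boundary), \code{acta2} (media
#' annulus), \code{adventitia} (outer annulus), and \code{marker}
#' (signal inside exactly the planted positive nuclei). Gaussian noise with
#' standard deviation \code{1/channel_snr} is added to every channel and the
#' result is clipped to [0, 1]. Nuclei are placed in the media by rejection
#' sampling with a retry cap; failure to place raises an error.
#'
#' @param params a \code{\link{sim_image_params}} object.
#' @return a list of class \code{sim_vessel} with elements \code{image}
#'   (class \code{vessel_image}: named list of numeric matrices with a
#'   \code{roles} attribute) and \code{truth} (nucleus centers, positivity,
#'   medial flags, ring radii, center).
#' @export
simulate_vessel_image <- function(params) {
  if (!inherits(params, "sim_image_params")) params <- do.call(sim_image_params, params)
  p <- params
  with_seed(p$seed, {
    size <- p$image_size
    center <- c((size - 1) / 2, (size - 1) / 2)
    d <- dist_field(size, center)

    vwf <- (d >= p$lumen_radius & d < p$media_inner_radius) * 1
    acta2 <- (d >= p$media_inner_radius & d < p$media_outer_radius) * 1
    adventitia <- (d >= p$media_outer_radius & d < p$adventitia_outer_radius) * 1

    ## place non-overlapping nuclei with centers inside the media annulus
    r_lo <- p$media_inner_radius + p$nucleus_radius
    r_hi <- p$media_outer_radius - p$nucleus_radius
    if (r_hi <= r_lo) stopf("media annulus too thin for the nucleus radius")
    centers <- matrix(NA_real_, p$n_medial_nuclei, 2)
    for (i in seq_len(p$n_medial_nuclei)) {
      placed <- FALSE
      for (try in seq_len(p$max_place_retries)) {
        r <- sqrt(runif(1, r_lo^2, r_hi^2))
        a <- runif(1, 0, 2 * pi)
        cand <- center + r * c(sin(a), cos(a))
        if (i == 1L || all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                              2, cand)^2)) > 2 * p$nucleus_radius + 1)) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("could not place nucleus %d without overlap after %d retries",
              i, p$max_place_retries)
    }

    n_pos <- round(p$positive_nucleus_fraction * p$n_medial_nuclei)
    positive <- rep(FALSE, p$n_medial_nuclei)
    if (n_pos > 0) positive[sample(p$n_medial_nuclei, n_pos)] <- TRUE

    dapi <- matrix(0, size, size)
    marker <- matrix(0, size, size)
    for (i in seq_len(p$n_medial_nuclei)) {
      disk <- dist_field(size, centers[i, ]) <= p$nucleus_radius
      dapi[disk] <- 1
      if (positive[i]) marker[disk] <- 1
    }

    chans <- list(dapi = dapi, vwf = vwf, acta2 = acta2,
                  adventitia = adventitia, marker = marker)
    if (is.finite(p$channel_snr)) {
      ## realistic acquisition: non-zero camera background baseline plus
      ## Gaussian read noise, clipped to the sensor range
      sdn <- 1 / p$channel_snr
      bg <- p$background
      chans <- lapply(chans, function(ch)
        pmin(pmax(bg + ch * (1 - bg) +
                    matrix(rnorm(length(ch), 0, sdn), nrow(ch)), 0), 1))
    }
    img <- structure(chans, class = "vessel_image",
                     roles = setNames(names(chans), names(chans)))

    truth <- list(
      params = unclass(p),
      center = center,
      nucleus_centers = centers,
      nucleus_radius = p$nucleus_radius,
      positive = positive,
      medial = rep(TRUE, p$n_medial_nuclei),
      ring_radii = c(lumen = p$lumen_radius, media_inner = p$media_inner_radius,
                     media_outer = p$media_outer_radius,
                     adventitia_outer = p$adventitia_outer_radius)
    )
    structure(list(image = img, truth = truth), class = "sim_vessel")
  })
}
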