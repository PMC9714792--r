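# short stable hash of a config list, for provenance headers
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                                     digits = NA))
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# write a data.frame with a provenance header (config hash, seed, stage)
write_stage_table <- function(df, path, hash, seed, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vascell stage=%s config=%s seed=%s", stage, hash,
                     as.character(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage table written by the pipeline, skipping provenance headers
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_stage_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Run the expression analysis pipeline end-to-end
#'
#' Sequences QC filtering, log-normalization, per-population marker
#' detection, optional signature and cell-cycle scoring, per-population
#' proportion tests, and (when a ligand-receptor database is supplied)
#' communication scoring with the permutation null and network summary.
#' Every stage writes its table to \code{out_dir} with a provenance header
#' and appends a record to the run log. All randomness derives from
#' stage-specific sub-seeds of \code{config$seed}.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{input}{directory of a 10x-style dataset (see
#'       \code{\link{read_tenx}}), or \code{NULL} when \code{sim} is given.}
#'     \item{sim}{list of \code{\link{sim_expr_params}} arguments; the
#'       dataset is simulated when \code{input} is absent.}
#'     \item{out_dir}{output directory.}
#'     \item{qc}{list of \code{\link{qc_thresholds}} arguments.}
#'     \item{markers}{list: \code{min_pct}, \code{lfc_min}, \code{alpha}.}
#'     \item{signatures}{optional named list of gene sets, or a GMT path.}
#'     \item{cell_cycle}{optional list with \code{s_genes}, \code{g2m_genes}.}
#'     \item{lr}{optional list: \code{db} (data.frame or TSV path),
#'       \code{n_perm}, \code{lfc_min}, \code{alpha}.}
#'     \item{seed}{master seed (mandatory).}
#'   }
#' @return list of class \code{expression_report} with all stage results,
#'   the run log, and \code{out_dir}.
#' @export
run_expression_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$seed)) stopf("config$seed is mandatory")
  ## hash only the analysis-relevant part: output location does not alter results
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(stage = stage, ..., time = format(Sys.time()))
  }
  emit <- function(df, name, stage) {
    if (!is.null(out_dir))
      write_stage_table(df, file.path(out_dir, name), hash, config$seed, stage)
  }

  ## input
  if (!is.null(config$input)) {
    ds <- read_tenx(config$input)
    counts <- ds$counts; meta <- ds$meta; truth <- ds$truth
  } else {
    sim_args <- config$sim
    if (is.null(sim_args)) sim_args <- list()
    sim_args$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_counts(do.call(sim_expr_params, sim_args))
    counts <- sim$counts; meta <- sim$meta; truth <- sim$truth
  }
  note("input", n_genes = nrow(counts), n_cells = ncol(counts))

  ## qc
  qc_args <- config$qc; if (is.null(qc_args)) qc_args <- list()
  thr <- do.call(qc_thresholds, qc_args)
  samp <- if (!is.null(meta)) meta$sample[match(colnames(counts), meta$cell)] else NULL
  qc <- qc_filter(counts, thr, sample = samp)
  counts <- counts[, qc$keep, drop = FALSE]
  if (!is.null(meta)) meta <- meta[meta$cell %in% qc$keep, , drop = FALSE]
  emit(qc$report, "qc_report.tsv", "qc")
  note("qc", n_removed = sum(!qc$report$keep), n_kept = length(qc$keep))

  ## normalization
  norm <- lognormalize(counts)
  note("normalize", scale = attr(norm, "scale_factor"))

  ## markers per population
  mk <- config$markers; if (is.null(mk)) mk <- list()
  mk_args <- list(min_pct = mk$min_pct %||% 0.25, lfc_min = mk$lfc_min %||% 0.25,
                  alpha = mk$alpha %||% 0.05)
  pops <- sort(unique(meta$population))
  markers <- lapply(pops, function(p)
    cbind(population = p,
          do.call(find_markers, c(list(norm, meta, p), mk_args))))
  markers <- do.call(rbind, markers)
  emit(markers, "markers.tsv", "markers")
  note("markers", n_populations = length(pops), n_rows = nrow(markers))

  ## signatures
  scores <- NULL
  if (!is.null(config$signatures)) {
    sets <- config$signatures
    if (is.character(sets) && length(sets) == 1L) sets <- read_gmt(sets)
    scores <- data.frame(cell = colnames(norm), stringsAsFactors = FALSE)
    for (nm in names(sets))
      scores[[nm]] <- as.numeric(signature_score(
        norm, sets[[nm]], seed = derive_seed(config$seed, paste0("sig_", nm))))
    emit(scores, "signature_scores.tsv", "signatures")
    note("signatures", n_sets = length(sets))
  }

  ## cell cycle
  phases <- NULL
  if (!is.null(config$cell_cycle)) {
    phases <- cell_cycle_phase(norm, config$cell_cycle$s_genes,
                               config$cell_cycle$g2m_genes,
                               seed = derive_seed(config$seed, "cell_cycle"))
    emit(phases, "cell_cycle.tsv", "cell_cycle")
    note("cell_cycle", table = as.list(table(phases$phase)))
  }

  ## proportions
  prop <- lapply(pops, function(p) {
    r <- proportion_test(meta, p)
    data.frame(population = p, t = r$t, df = r$df, p = r$p,
               stringsAsFactors = FALSE)
  })
  prop <- do.call(rbind, prop)
  emit(prop, "proportion_tests.tsv", "proportions")
  note("proportions", n_populations = nrow(prop))

  ## communication
  edges <- NULL; network <- NULL
  if (!is.null(config$lr)) {
    db <- config$lr$db
    if (is.character(db)) db <- read_lr_pairs(db)
    edges <- permutation_test(
      norm, meta, db,
      n_perm = config$lr$n_perm %||% 1000L,
      seed = derive_seed(config$seed, "permutation"),
      sample = meta$sample[match(colnames(norm), meta$cell)],
      lfc_min = config$lr$lfc_min %||% 0.25,
      alpha = config$lr$alpha %||% 0.05)
    network <- summarize_network(edges, alpha = config$lr$alpha %||% 0.05)
    emit(edges, "lr_edges.tsv", "commnet")
    emit(network$population_scores, "lr_population_scores.tsv", "commnet")
    note("commnet", n_edges = nrow(edges),
         n_significant = sum(edges$p_perm < (config$lr$alpha %||% 0.05)))
  }

  report <- structure(list(
    qc = qc, norm = norm, meta = meta, markers = markers, scores = scores,
    phases = phases, proportions = prop, edges = edges, network = network,
    truth = if (exists("truth", inherits = FALSE)) truth else NULL,
    log = log, config_hash = hash, out_dir = out_dir
  ), class = "expression_report")
  if (!is.null(out_dir))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, force = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the vessel-image analysis pipeline over a set of images
#'
#' Per image: vessel segmentation, radial profiling, nucleus segmentation,
#' medial assignment, and marker quantification. Across images: two-group
#' Wilcoxon comparison of the per-vessel positive percentages when group
#' labels allow it. Per-image failures are logged and skipped; the run fails
#' only when every image fails.
#'
#' @param config list (or JSON path) with elements:
#'   \describe{
#'     \item{images}{character vector of TIFF paths (with channel sidecars),
#'       or a list of in-memory \code{vessel_image} objects.}
#'     \item{groups}{optional group label per image.}
#'     \item{shape_channels}{channels combined for vessel segmentation
#'       (default \code{c("vwf", "acta2", "adventitia")}).}
#'     \item{nuclear_channel, acta2_channel, vwf_channel, marker_channel}{
#'       channel-role names (defaults \code{"dapi"}, \code{"acta2"},
#'       \code{"vwf"}, \code{"marker"}).}
#'     \item{n_probes, samples_per_probe}{profiling resolution (32, 100).}
#'     \item{dilation_radius, positivity_cutoff, min_area}{quantification
#'       parameters (2, 0.1, default nucleus floor).}
#'     \item{out_dir}{optional output directory for TSVs and profile plots.}
#'     \item{seed}{master seed recorded in provenance headers.}
#'   }
#' @return list of class \code{image_report}: per-image results, a summary
#'   data.frame, the group comparison (or NULL), failures, and the run log.
#' @export
run_image_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config) &&
      grepl("\\.json$", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  images <- config$images
  if (is.null(images) || length(images) == 0L) stopf("no images supplied")
  hash <- config_hash(config[setdiff(names(config), c("images", "out_dir"))])
  seed <- config$seed %||% 0L
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  shape_ch <- config$shape_channels %||% c("vwf", "acta2", "adventitia")
  nuc_ch <- config$nuclear_channel %||% "dapi"
  acta_ch <- config$acta2_channel %||% "acta2"
  vwf_ch <- config$vwf_channel %||% "vwf"
  mark_ch <- config$marker_channel %||% "marker"
  min_area <- config$min_area %||% (pi * (5 / 2)^2)

  ids <- names(images) %||% paste0("image", seq_along(images))
  if (is.null(names(images)) && is.character(images))
    ids <- basename(unlist(images))
  results <- list(); failures <- list()
  for (i in seq_along(images)) {
    id <- ids[i]
    res <- tryCatch({
      img <- images[[i]]
      if (is.character(img)) img <- read_vessel_tiff(img)
      img <- max_project(img)
      rois <- segment_vessel(img, shape_ch)
      prof <- radial_profile(img, rois,
                             n_probes = config$n_probes %||% 32L,
                             samples_per_probe = config$samples_per_probe %||% 100L)
      nuc <- segment_nuclei(img[[nuc_ch]], min_area = min_area)
      medial <- assign_medial(nuc, img[[acta_ch]], img[[vwf_ch]],
                              dilation_radius = config$dilation_radius %||% 2)
      quant <- quantify_marker(nuc, medial, img[[mark_ch]],
                               positivity_cutoff = config$positivity_cutoff %||% 0.1)
      if (!is.null(out_dir)) {
        write_stage_table(quant$records,
                          file.path(out_dir, paste0(id, "_nuclei.tsv")),
                          hash, seed, "nuclei")
        ptab <- data.frame(position = prof$positions, prof$profiles)
        write_stage_table(ptab, file.path(out_dir, paste0(id, "_profile.tsv")),
                          hash, seed, "profile")
        grDevices::pdf(file.path(out_dir, paste0(id, "_profile.pdf")), 6, 4)
        plot_radial_profile(prof, main = id)
        grDevices::dev.off()
      }
      list(id = id, rois = rois, profile = prof, nuclei = nuc,
           quant = quant, positive_pct = quant$positive_pct,
           n_medial = quant$n_medial)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
    else results[[id]] <- res
  }
  if (!length(results))
    stopf("all %d image(s) failed; first error: %s", length(images),
          failures[[1]])

  summary <- data.frame(
    image = names(results),
    group = if (!is.null(config$groups))
      as.character(config$groups)[match(names(results), ids)] else NA_character_,
    n_medial = vapply(results, function(r) r$n_medial, numeric(1)),
    positive_pct = vapply(results, function(r) r$positive_pct, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  comparison <- NULL
  grp <- summary$group[!is.na(summary$positive_pct)]
  if (!all(is.na(summary$group)) && length(unique(grp)) == 2L &&
      all(table(grp) >= 2L)) {
    gs <- split(summary$positive_pct[!is.na(summary$positive_pct)], grp)
    comparison <- c(compare_groups(gs[[1]], gs[[2]]),
                    list(groups = names(gs)))
  } else if (length(images) >= 1L) {
    warnf("group comparison skipped (need two groups with >= 2 vessels each)")
  }
  if (!is.null(out_dir))
    write_stage_table(summary, file.path(out_dir, "vessel_summary.tsv"),
                      hash, seed, "summary")
  structure(list(results = results, summary = summary,
                 comparison = comparison, failures = failures,
                 config_hash = hash, out_dir = out_dir),
            class = "image_report")
}
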