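#' Write a simulated single-cell dataset in 10x-style layout
#'
#' Emits \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv},
#' \code{meta.tsv} (cell annotations) and \code{truth.json} (planted ground
#' truth) into a directory.
#'
#' @param sim a \code{sim_expr} object from \code{\link{simulate_counts}}.
#' @param dir output directory, created if absent.
#' @return \code{dir}, invisibly.
#' @export
write_tenx <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_expr"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(sim$counts, file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = rownames(sim$counts), name = rownames(sim$counts),
                         type = "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(sim$counts), file.path(dir, "barcodes.tsv"))
  write.table(sim$meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$proportions <- as.data.frame(truth$proportions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a 10x-style directory written by \code{\link{write_tenx}}
#'
#' Also accepts plain 10x output (no \code{meta.tsv}/\code{truth.json}).
#'
#' @param dir directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @return list with \code{counts} (sparse genes x cells), \code{meta}
#'   (data.frame or NULL), \code{truth} (list or NULL).
#' @export
read_tenx <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  feats <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                      stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(feats[[1]], barcodes)
  meta <- NULL
  if (file.exists(file.path(dir, "meta.tsv")))
    meta <- read.table(file.path(dir, "meta.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json")))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(counts = counts, meta = meta, truth = truth)
}

#' Write a multichannel vessel image as TIFF plus a channel-role sidecar
#'
#' Channels are written as successive TIFF frames (32-bit float) and the frame
#' to role mapping goes to \code{<path>.channels.json}.
#'
#' @param image a \code{vessel_image} (named list of matrices in [0, 1]).
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_vessel_tiff <- function(image, path) {
  stopifnot(inherits(image, "vessel_image") || (is.list(image) && !is.null(names(image))))
  tiff::writeTIFF(lapply(image, function(m) pmin(pmax(m, 0), 1)), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(channels = names(image)),
                       paste0(path, ".channels.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multichannel vessel TIFF written with a channel-role sidecar
#'
#' @param path TIFF path; \code{<path>.channels.json} must exist, or channel
#'   names can be supplied explicitly.
#' @param channels optional channel-name vector overriding the sidecar.
#' @return a \code{vessel_image}: named list of numeric matrices.
#' @export
read_vessel_tiff <- function(path, channels = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.null(channels)) {
    sidecar <- paste0(path, ".channels.json")
    if (!file.exists(sidecar))
      stopf("no channel sidecar at %s; pass 'channels'", sidecar)
    channels <- unlist(jsonlite::read_json(sidecar)$channels)
  }
  if (length(frames) != length(channels))
    stopf("TIFF has %d frames but %d channel names given",
          length(frames), length(channels))
  structure(setNames(frames, channels), class = "vessel_image",
            roles = setNames(channels, channels))
}

#' Read a ligand-receptor pair database from TSV
#'
#' Expects columns \code{ligand}, \code{receptor}, \code{weight} (header
#' required); the weight is the database interaction weight in [0, 1].
#'
#' @param path TSV path.
#' @return data.frame with columns \code{ligand}, \code{receptor},
#'   \code{weight}.
#' @export
read_lr_pairs <- function(path) {
  db <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "weight")
  if (!all(need %in% names(db)))
    stopf("LR database must have columns: %s", paste(need, collapse = ", "))
  if (any(db$weight < 0 | db$weight > 1))
    stopf("LR pair weights must lie in [0, 1]")
  db[need]
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
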