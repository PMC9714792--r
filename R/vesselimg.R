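#' Construct a multichannel vessel image
#'
#' @param channels named list of numeric matrices (one per channel role) or
#'   3D arrays (rows x cols x z) for z-stacks.
#' @return object of class \code{vessel_image}.
#' @export
vessel_image <- function(channels) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stopf("'channels' must be a named list")
  structure(channels, class = "vessel_image",
            roles = setNames(names(channels), names(channels)))
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum across z-planes, applied per channel. 2D channels pass
#' through unchanged.
#'
#' @param stack a \code{vessel_image} (channels may be 3D arrays), a single
#'   3D array, or a list of z-plane matrices.
#' @return the projected image (same type, channels all 2D).
#' @export
max_project <- function(stack) {
  project_one <- function(x) {
    if (is.list(x)) return(do.call(pmax, x))
    if (length(dim(x)) == 3L)
      return(do.call(pmax, lapply(seq_len(dim(x)[3]), function(k) x[, , k])))
    x
  }
  if (inherits(stack, "vessel_image"))
    return(vessel_image(lapply(unclass(stack), project_one)))
  project_one(stack)
}

# largest connected component of a binary mask (8-connectivity)
largest_cc <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Segment the vessel lumen and outer boundary
#'
#' Combines the listed channels by per-pixel maximum, thresholds the combined
#' image (Otsu by default), takes the largest connected component as the
#' vessel wall, fills it to obtain the outer-boundary mask, and takes the
#' largest interior hole as the lumen. The lumen center of mass is computed on
#' the binary lumen mask.
#'
#' @param image a \code{vessel_image} (z-stacks are max-projected first).
#' @param channels names of the channels to combine for the vessel shape.
#' @param threshold optional fixed threshold replacing Otsu.
#' @return list of class \code{vessel_rois}: \code{lumen} and \code{outer}
#'   logical masks, \code{center} (row, col; 0-based pixel-center
#'   coordinates), \code{threshold}.
#' @export
segment_vessel <- function(image, channels, threshold = NULL) {
  image <- max_project(image)
  miss <- setdiff(channels, names(image))
  if (length(miss)) stopf("channel(s) not present: %s", paste(miss, collapse = ", "))
  combined <- do.call(pmax, unclass(image)[channels])
  rng <- range(combined)
  if (diff(rng) == 0) stopf("combined channel is constant; cannot segment")
  if (is.null(threshold)) {
    scaled <- (combined - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * diff(rng)
  }
  wall <- largest_cc(combined > threshold)
  outer <- EBImage::fillHull(wall) > 0
  holes <- outer & !wall
  if (!any(holes)) stopf("no interior hole found; vessel section not transverse")
  lumen <- largest_cc(holes)
  px <- which(lumen, arr.ind = TRUE)
  center <- c(mean(px[, 1]) - 1, mean(px[, 2]) - 1)
  structure(list(lumen = lumen, outer = outer, center = center,
                 threshold = threshold), class = "vessel_rois")
}

# bilinear interpolation at 0-based (row, col) real coordinates
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 0), nr - 1); c <- pmin(pmax(c, 0), nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    img[cbind(r1 + 1, c0 + 1)] * fr * (1 - fc) +
    img[cbind(r0 + 1, c1 + 1)] * (1 - fr) * fc +
    img[cbind(r1 + 1, c1 + 1)] * fr * fc
}

#' Radial intensity profile of the vessel wall
#'
#' Casts \code{n_probes} evenly spaced rays from the lumen center of mass.
#' Along each ray, intensities are sampled by bilinear interpolation from the
#' ray's lumen-boundary crossing to its outer-boundary crossing and the trace
#' is resampled onto \code{samples_per_probe} fixed positions of the
#' normalized radial axis [0, 1] (0 = lumen boundary, 1 = outer boundary).
#' Each channel's profile is the pointwise mean over probes. Probes failing
#' to cross both boundaries are dropped and reported; more than half dropped
#' is a geometry error.
#'
#' @param image a \code{vessel_image}.
#' @param rois \code{vessel_rois} from \code{\link{segment_vessel}}.
#' @param n_probes number of rays (default 32).
#' @param samples_per_probe resampled positions per trace (default 100).
#' @param channels channels to profile (default all).
#' @return list of class \code{radial_profile}: \code{profiles}
#'   (samples x channels matrix), \code{positions} (normalized radial axis),
#'   \code{traces} (per-channel samples x probes matrices),
#'   \code{probes_used}, \code{angles}, \code{boundaries} (per-probe lumen
#'   and outer crossing radii).
#' @export
radial_profile <- function(image, rois, n_probes = 32L,
                           samples_per_probe = 100L, channels = NULL) {
  image <- max_project(image)
  if (is.null(channels)) channels <- names(image)
  n_probes <- check_count(n_probes, "n_probes", 1L)
  samples_per_probe <- check_count(samples_per_probe, "samples_per_probe", 2L)
  center <- rois$center
  angles <- 2 * pi * (seq_len(n_probes) - 1) / n_probes
  r_max <- sqrt(nrow(rois$lumen)^2 + ncol(rois$lumen)^2)
  step <- 0.25
  rs <- seq(0, r_max, by = step)

  in_mask <- function(mask, rr, cc) {
    ri <- round(rr); ci <- round(cc)
    ok <- ri >= 0 & ri < nrow(mask) & ci >= 0 & ci < ncol(mask)
    out <- rep(FALSE, length(rr))
    out[ok] <- mask[cbind(ri[ok] + 1, ci[ok] + 1)]
    out
  }

  bounds <- matrix(NA_real_, n_probes, 2,
                   dimnames = list(NULL, c("lumen", "outer")))
  for (k in seq_len(n_probes)) {
    dr <- sin(angles[k]); dc <- cos(angles[k])
    rr <- center[1] + rs * dr; cc <- center[2] + rs * dc
    lum <- in_mask(rois$lumen, rr, cc)
    out <- in_mask(rois$outer, rr, cc)
    if (!lum[1]) next                       # center not inside lumen: fail
    exit_lumen <- which(!lum)[1]
    if (is.na(exit_lumen)) next
    beyond <- which(!out & seq_along(rs) >= exit_lumen)[1]
    if (is.na(beyond) || beyond <= exit_lumen) next
    bounds[k, ] <- c(rs[exit_lumen], rs[beyond])
  }
  used <- which(!is.na(bounds[, 1]))
  if (length(used) < n_probes / 2)
    stopf("%d of %d probes failed to cross both boundaries",
          n_probes - length(used), n_probes)

  tpos <- seq(0, 1, length.out = samples_per_probe)
  traces <- lapply(channels, function(ch) {
    m <- matrix(NA_real_, samples_per_probe, n_probes)
    for (k in used) {
      r <- bounds[k, 1] + tpos * (bounds[k, 2] - bounds[k, 1])
      m[, k] <- bilinear(image[[ch]], center[1] + r * sin(angles[k]),
                         center[2] + r * cos(angles[k]))
    }
    m
  })
  names(traces) <- channels
  profiles <- vapply(traces, function(m)
    rowMeans(m[, used, drop = FALSE]), numeric(samples_per_probe))
  structure(list(profiles = profiles, positions = tpos, traces = traces,
                 probes_used = used, angles = angles, boundaries = bounds),
            class = "radial_profile")
}

#' Yen's automatic histogram threshold
#'
#' Computes the intensity level maximizing Yen's maximum-correlation
#' criterion over an \code{n_bins}-bin histogram of the image. Pixels
#' strictly above the returned threshold are foreground.
#'
#' @param channel numeric matrix (2D image).
#' @param n_bins histogram bins (default 256).
#' @return the threshold intensity (a bin-center value).
#' @export
yen_threshold <- function(channel, n_bins = 256L) {
  v <- as.numeric(channel)
  rng <- range(v)
  if (diff(rng) == 0) stopf("constant image has no threshold")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- rev(cumsum(rev(p^2)))
  t <- seq_len(n_bins - 1L)
  crit <- suppressWarnings(
    -log(P1sq[t] * P2sq[t + 1L]) + 2 * log(P1[t] * (1 - P1[t]))
  )
  crit[!is.finite(crit)] <- -Inf
  centers[which.max(crit)]
}

# Binary mask from a channel: Yen threshold unless the channel is constant
# (no signal -> empty mask) or a fixed threshold is supplied. Yen adapts the
# cut to the background mode, so scattered noisy background pixels always
# clear it (even a few percent of them when the true foreground is small or
# absent); a morphological opening with a small disc removes this speckle,
# as the despeckle step of imaging macros does, while structures at least as
# wide as the brush (nuclei, wall rings) pass through intact.
binarize <- function(channel, threshold = NULL, despeckle = TRUE,
                     despeckle_brush = 5L) {
  if (is.null(threshold)) {
    if (diff(range(channel)) == 0) return(channel > Inf)
    threshold <- yen_threshold(channel)
    ## stained structures occupy a minority of a transverse section; a cut
    ## labelling most pixels foreground means Yen landed below the
    ## background mode (possible when no real foreground class exists).
    ## Fall back to the robust background ceiling.
    if (mean(channel > threshold) > 0.5)
      threshold <- median(channel) + 5 * mad(channel)
  }
  mask <- channel > threshold
  if (despeckle && any(mask))
    mask <- EBImage::opening(mask,
                             EBImage::makeBrush(despeckle_brush, "disc")) > 0
  mask
}

#' Segment nuclei in the nuclear channel
#'
#' Thresholds the nuclear channel (Yen), fills holes, splits touching nuclei
#' by watershed on the distance transform, and discards objects below a
#' minimum area floor.
#'
#' @param dapi nuclear-channel matrix.
#' @param min_area minimum object area in pixels (default
#'   \code{pi * (5/2)^2}, half the default synthetic nucleus diameter).
#' @param threshold optional fixed threshold replacing Yen.
#' @return list of class \code{nucleus_set}: \code{labels} (integer label
#'   matrix) and \code{records} (data.frame: \code{id}, \code{area},
#'   \code{centroid_row}, \code{centroid_col}).
#' @export
segment_nuclei <- function(dapi, min_area = pi * (5 / 2)^2, threshold = NULL) {
  mask <- binarize(dapi, threshold)
  empty <- function() {
    warnf("no nuclei detected")
    structure(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                   records = data.frame(id = integer(0), area = numeric(0),
                                        centroid_row = numeric(0),
                                        centroid_col = numeric(0))),
              class = "nucleus_set")
  }
  if (!any(mask)) return(empty())
  mask <- EBImage::fillHull(mask) > 0
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty())
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  px <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  records <- data.frame(
    id = seq_along(keep),
    area = as.numeric(tabulate(ids, nbins = length(keep))),
    centroid_row = tapply(px[, 1] - 1, ids, mean),
    centroid_col = tapply(px[, 2] - 1, ids, mean),
    row.names = NULL
  )
  structure(list(labels = lab, records = records), class = "nucleus_set")
}

#' Assign nuclei to the medial layer
#'
#' A nucleus is medial when the dilated ACTA2 mask overlaps it and no VWF
#' signal lies within the nuclear region.
#'
#' @param nuclei a \code{nucleus_set} from \code{\link{segment_nuclei}}.
#' @param acta2,vwf channel matrices (thresholded by Yen internally) or
#'   logical masks.
#' @param dilation_radius disk radius in pixels for the ACTA2 dilation
#'   (default 2; 0 means no dilation).
#' @return logical vector of medial flags, one per nucleus record.
#' @export
assign_medial <- function(nuclei, acta2, vwf, dilation_radius = 2) {
  acta2_mask <- if (is.logical(acta2)) acta2 else binarize(acta2)
  vwf_mask <- if (is.logical(vwf)) vwf else binarize(vwf)
  if (dilation_radius > 0) {
    brush <- EBImage::makeBrush(2 * round(dilation_radius) + 1, shape = "disc")
    acta2_mask <- EBImage::dilate(acta2_mask, brush) > 0
  }
  lab <- nuclei$labels
  n <- nrow(nuclei$records)
  if (n == 0L) return(logical(0))
  ids <- lab[lab > 0]
  acta_hit <- tapply(acta2_mask[lab > 0], ids, any)
  vwf_hit <- tapply(vwf_mask[lab > 0], ids, any)
  out <- acta_hit & !vwf_hit
  unname(as.logical(out[as.character(nuclei$records$id)]))
}

#' Quantify marker positivity over medial nuclei
#'
#' The marker channel is thresholded (Yen) and each nucleus receives the
#' fraction of its area covered by the marker mask. The vessel summary is the
#' percentage of medial nuclei whose fraction reaches
#' \code{positivity_cutoff}.
#'
#' @param nuclei a \code{nucleus_set}.
#' @param medial logical medial flags (see \code{\link{assign_medial}}).
#' @param marker marker channel matrix or logical mask.
#' @param positivity_cutoff minimum positive-area fraction calling a nucleus
#'   positive (default 0.1).
#' @return list: \code{records} (per-nucleus data.frame with \code{medial}
#'   and \code{marker_positive_area_fraction}), \code{positive_pct}
#'   (percentage of positive medial nuclei; \code{NA} with a warning when no
#'   nucleus is medial), \code{n_medial}.
#' @export
quantify_marker <- function(nuclei, medial, marker, positivity_cutoff = 0.1) {
  marker_mask <- if (is.logical(marker)) marker else binarize(marker)
  rec <- nuclei$records
  lab <- nuclei$labels
  frac <- numeric(nrow(rec))
  if (nrow(rec)) {
    ids <- lab[lab > 0]
    hit <- tapply(marker_mask[lab > 0], ids, sum)
    frac <- as.numeric(hit[as.character(rec$id)]) / rec$area
  }
  rec$medial <- medial
  rec$marker_positive_area_fraction <- frac
  n_medial <- sum(medial)
  if (n_medial == 0L) {
    warnf("no medial nuclei; vessel summary undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * mean(frac[medial] >= positivity_cutoff)
  }
  list(records = rec, positive_pct = pct, n_medial = n_medial)
}

#' Compare per-vessel summaries between groups
#'
#' Two-sided Wilcoxon rank-sum test on per-vessel summary values (e.g.
#' positive-nucleus percentages) between two groups.
#'
#' @param a,b numeric vectors of per-vessel values for the two groups
#'   (each needs >= 2 values).
#' @return list with \code{p}, \code{n} (group sizes), and \code{medians}.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs >= 2 vessels")
  p <- rank_sum_p(c(a, b), c(rep(TRUE, length(a)), rep(FALSE, length(b))))
  list(p = p, n = c(length(a), length(b)),
       medians = c(median(a), median(b)))
}

#' Plot a radial profile
#'
#' Mean intensity over probes against the normalized radial position, one
#' line per channel.
#'
#' @param profile a \code{radial_profile}.
#' @param ... passed to \code{matplot}.
#' @return invisibly, the profile.
#' @export
plot_radial_profile <- function(profile, ...) {
  graphics::matplot(profile$positions, profile$profiles, type = "l", lty = 1,
                    xlab = "normalized radial position (lumen to outside)",
                    ylab = "mean intensity", ...)
  graphics::legend("topright", legend = colnames(profile$profiles),
                   col = seq_len(ncol(profile$profiles)), lty = 1, bty = "n")
  invisible(profile)
}
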