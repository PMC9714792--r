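noise_free_vessel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_vessel_image(sim_image_params(seed = 5, channel_snr = Inf,
                                                       positive_nucleus_fraction = 0.25))
    cache
  }
})

test_that("max projection equals the per-pixel maximum loop", {
  set.seed(2)
  stack <- array(runif(20 * 20 * 4), c(20, 20, 4))
  proj <- max_project(stack)
  oracle <- matrix(NA_real_, 20, 20)
  for (i in 1:20) for (j in 1:20) oracle[i, j] <- max(stack[i, j, ])
  expect_equal(proj, oracle)
  ## single plane passes through; two-plane pixelwise max
  expect_identical(max_project(stack[, , 1]), stack[, , 1])
  expect_equal(max_project(list(matrix(3, 2, 2), matrix(7, 2, 2))),
               matrix(7, 2, 2))
})

test_that("vessel segmentation recovers the analytic lumen and outer masks", {
  sv <- noise_free_vessel()
  p <- sv$truth$params
  rois <- segment_vessel(sv$image, c("vwf", "acta2", "adventitia"))
  d <- vascell:::dist_field(p$image_size, sv$truth$center)
  expect_identical(rois$lumen, d < p$lumen_radius)
  expect_identical(rois$outer, d < p$adventitia_outer_radius)
  ## centrally symmetric annulus: center of mass at the geometric center
  expect_equal(rois$center, sv$truth$center, tolerance = 0.01)
  ## uniform sub-threshold offset leaves the masks unchanged
  shifted <- vessel_image(lapply(unclass(sv$image), function(m) m + 0.05))
  rois2 <- segment_vessel(shifted, c("vwf", "acta2", "adventitia"))
  expect_identical(rois2$lumen, rois$lumen)
  expect_identical(rois2$outer, rois$outer)
  ## a solid disk (no hole) is a segmentation error
  solid <- vessel_image(list(a = (d < 50) * 1))
  expect_error(segment_vessel(solid, "a"), "hole")
})

test_that("radial profiles match the analytic ring geometry", {
  sv <- noise_free_vessel()
  p <- sv$truth$params
  rois <- segment_vessel(sv$image, c("vwf", "acta2", "adventitia"))
  prof <- radial_profile(sv$image, rois, n_probes = 32, samples_per_probe = 100)
  expect_length(prof$probes_used, 32)
  ## constant channel gives a constant profile
  const <- vessel_image(c(unclass(sv$image), list(flat = matrix(0.6, p$image_size, p$image_size))))
  pf <- radial_profile(const, rois, channels = "flat")
  expect_equal(unname(pf$profiles[, "flat"]), rep(0.6, 100), tolerance = 1e-6)
  ## media channel: indicator of the normalized media span within 2 positions
  span <- (c(p$media_inner_radius, p$media_outer_radius) - p$lumen_radius) /
    (p$adventitia_outer_radius - p$lumen_radius)
  acta <- prof$profiles[, "acta2"]
  hi <- which(acta > 0.5)
  expect_lt(abs(min(hi - 1) / 99 - span[1]), 2 / 99 + 1e-9)
  expect_lt(abs(max(hi - 1) / 99 - span[2]), 2 / 99 + 1e-9)
  ## probe-count refinement: 32 vs 64 probes agree on symmetric input
  ## (pointwise everywhere; the steep ring edges allow a wider band there)
  prof64 <- radial_profile(sv$image, rois, n_probes = 64)
  expect_lt(max(abs(prof64$profiles[, "acta2"] - acta)), 0.12)
  expect_lt(mean(abs(prof64$profiles[, "acta2"] - acta)), 0.01)
})

test_that("radial profile commutes with image rotation on symmetric input", {
  sv <- noise_free_vessel()
  rois <- segment_vessel(sv$image, c("vwf", "acta2", "adventitia"))
  prof <- radial_profile(sv$image, rois, channels = c("vwf", "acta2", "adventitia"))
  rot <- vessel_image(lapply(unclass(sv$image), function(m) t(m[nrow(m):1, ])))
  rois_r <- segment_vessel(rot, c("vwf", "acta2", "adventitia"))
  prof_r <- radial_profile(rot, rois_r, channels = c("vwf", "acta2", "adventitia"))
  expect_lt(max(abs(prof$profiles - prof_r$profiles)), 0.02)
})

test_that("yen threshold separates a two-valued image and shifts with intensity", {
  img <- matrix(c(rep(10, 40), rep(200, 60)), 10, 10)
  thr <- yen_threshold(img)
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_identical(as.integer(table(img > thr)), c(40L, 60L))
  thr2 <- yen_threshold(img + 17)
  expect_lt(abs(thr2 - (thr + 17)), (190 / 256) + 1e-9)  # one bin width
  expect_error(yen_threshold(matrix(5, 4, 4)), "constant")
})

test_that("yen threshold equals the exhaustive-search oracle on random 8-bit images", {
  set.seed(123)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 900, replace = TRUE,
                         prob = runif(256)^2), 30, 30)
    expect_equal(yen_threshold(img), brute_yen(img),
                 info = paste("image", i))
  }
})

test_that("nucleus segmentation counts planted disks and splits touching pairs", {
  sv <- noise_free_vessel()
  nuc <- segment_nuclei(sv$image$dapi)
  expect_equal(nrow(nuc$records), nrow(sv$truth$nucleus_centers))
  ## centroids match the planted centers (nearest-match within 1 px)
  dmat <- as.matrix(dist(rbind(
    as.matrix(nuc$records[, c("centroid_row", "centroid_col")]),
    sv$truth$nucleus_centers)))
  n <- nrow(nuc$records)
  nearest <- apply(dmat[seq_len(n), n + seq_len(n), drop = FALSE], 1, min)
  expect_lt(max(nearest), 1)
  ## two overlapping disks with distinct centers give two labels
  img <- matrix(0, 60, 60)
  d1 <- vascell:::dist_field(60, c(25, 25)) <= 8
  d2 <- vascell:::dist_field(60, c(25, 38)) <= 8
  img[d1 | d2] <- 1
  img[1, 1] <- 0.001  # break constancy of the background
  two <- segment_nuclei(img, threshold = 0.5)
  expect_identical(nrow(two$records), 2L)
  ## blank channel: zero nuclei with a warning
  expect_warning(none <- segment_nuclei(matrix(0, 30, 30), threshold = 0.5),
                 "no nuclei")
  expect_identical(nrow(none$records), 0L)
})

test_that("medial assignment follows the ACTA2/VWF rule and is monotone in dilation", {
  ## geometry: nucleus A inside ACTA2 band, nucleus B overlapping VWF band,
  ## nucleus C adjacent to (but not touching) the ACTA2 band
  img <- matrix(0, 80, 80)
  acta2 <- matrix(FALSE, 80, 80); acta2[, 30:50] <- TRUE
  vwf <- matrix(FALSE, 80, 80); vwf[, 10:14] <- TRUE
  dapi <- matrix(0, 80, 80)
  nucA <- vascell:::dist_field(80, c(40, 40)) <= 5
  nucB <- vascell:::dist_field(80, c(40, 12)) <= 5
  nucC <- vascell:::dist_field(80, c(40, 58)) <= 5   # cols 53..63, gap of 2
  dapi[nucA | nucB | nucC] <- 1
  nuc <- segment_nuclei(dapi, threshold = 0.5)
  expect_identical(nrow(nuc$records), 3L)
  ord <- order(nuc$records$centroid_col)   # B (12), A (40), C (58)
  med0 <- assign_medial(nuc, acta2, vwf, dilation_radius = 0)
  medB <- med0[ord[1]]; medA <- med0[ord[2]]; medC <- med0[ord[3]]
  expect_true(medA)
  expect_false(medB)   # VWF inside the nuclear region
  expect_false(medC)   # not touching ACTA2 at radius 0
  med6 <- assign_medial(nuc, acta2, vwf, dilation_radius = 6)
  expect_true(med6[ord[3]])  # large enough dilation reaches nucleus C
  ## monotone: the medial set never shrinks as the radius grows
  sets <- lapply(0:6, function(r) which(assign_medial(nuc, acta2, vwf, r)))
  for (i in seq_len(6))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("marker quantification returns exact per-nucleus fractions", {
  dapi <- matrix(0, 60, 60)
  inside <- vascell:::dist_field(60, c(20, 20)) <= 5
  outside <- vascell:::dist_field(60, c(45, 45)) <= 5
  dapi[inside | outside] <- 1
  nuc <- segment_nuclei(dapi, threshold = 0.5)
  marker <- matrix(FALSE, 60, 60); marker[1:32, ] <- TRUE  # covers nucleus 1 only
  q <- quantify_marker(nuc, medial = c(TRUE, TRUE), marker,
                       positivity_cutoff = 0.1)
  fr <- q$records$marker_positive_area_fraction[order(q$records$centroid_row)]
  expect_equal(fr, c(1, 0))
  expect_equal(q$positive_pct, 50)
  ## no medial nuclei: undefined summary with a warning
  expect_warning(q0 <- quantify_marker(nuc, medial = c(FALSE, FALSE), marker),
                 "no medial")
  expect_true(is.na(q0$positive_pct))
})

test_that("group comparison is an exact rank test invariant to monotone transforms", {
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(compare_groups(c(2, 2, 2), c(2, 2, 2))$p, 1)
  a <- c(3, 9, 14, 20); b <- c(5, 11, 28, 31)
  expect_equal(compare_groups(a, b)$p, compare_groups(exp(a / 10), exp(b / 10))$p)
  expect_error(compare_groups(1, c(2, 3)), ">= 2")
})

test_that("a background-only channel yields an empty mask, not a noise mask", {
  set.seed(6)
  noise_only <- matrix(0.1 + rnorm(256^2, 0, 0.02), 256)
  expect_false(any(vascell:::binarize(noise_only)))
  with_signal <- noise_only
  with_signal[100:120, 100:120] <- 1
  m <- vascell:::binarize(with_signal)
  expect_gt(sum(m), 300)
  expect_lt(mean(m[-(100:120), ]), 0.001)
})

test_that("planted positive fractions are recovered end to end at the default SNR", {
  errs <- vapply(1:6, function(s) {
    fr <- c(0, 0.25, 0.5)[(s %% 3) + 1]
    sv <- simulate_vessel_image(sim_image_params(seed = 100 + s,
                                                 positive_nucleus_fraction = fr))
    nuc <- segment_nuclei(sv$image$dapi)
    med <- assign_medial(nuc, sv$image$acta2, sv$image$vwf)
    q <- quantify_marker(nuc, med, sv$image$marker)
    abs(q$positive_pct - 100 * mean(sv$truth$positive))
  }, numeric(1))
  expect_lt(mean(errs), 5)
})
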