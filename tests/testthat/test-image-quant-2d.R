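test_that("nuclei segmentation recovers well-separated and touching blobs", {
  # zero-contrast image: no objects
  flat <- channel_image(matrix(1000, 128, 128), "hoechst")
  expect_equal(n_objects(segment_nuclei(flat)), 0)

  # two bright blobs far apart: 2 objects, centroids near the truth.
  # oracle: connected components of a global-threshold mask
  sim <- generate_monolayer_images(2, image_size = 128, seed = 31,
    min_spacing = 60)
  seg <- segment_nuclei(sim$hoechst)
  x <- unclass(sim$hoechst)
  attributes(x) <- list(dim = dim(x))
  cc <- EBImage::bwlabel(x > 500 + 0.5 * (max(x) - 500))
  expect_equal(n_objects(seg), max(cc))
  cen <- label_centroids(seg)
  truth <- sim$ground_truth$nucleus_centers
  for (i in 1:2) {
    d <- sqrt((cen[, 1] - truth[i, 1])^2 + (cen[, 2] - truth[i, 2])^2)
    expect_lt(min(d), 2)
  }

  # two overlapping blobs with two intensity peaks: the watershed must
  # split them into 2 objects, where plain thresholding sees only 1.
  # built directly so the center distance is exactly 17 px for radius 8: distinct summits, merged mask
  blob <- function(img, cx, cy, r, peak) {
    hm <- sqrt(2 * log(2))
    for (i in seq_len(nrow(img))) {
      img[i, ] <- img[i, ] + peak *
        exp(-0.5 * ((i - cx)^2 + (seq_len(ncol(img)) - cy)^2) * (hm / r)^2)
    }
    img
  }
  xo <- blob(blob(matrix(500, 96, 96), 40, 40, 8, 30000), 40, 57, 8, 30000)
  merged <- EBImage::bwlabel(xo > 500 + 0.25 * (max(xo) - 500))
  expect_equal(max(merged), 1) # confirms the blobs really touch
  expect_equal(n_objects(segment_nuclei(channel_image(xo, "hoechst"))), 2)
})

test_that("segmentation meets recall/precision bounds on dense monolayers", {
  scores <- sapply(1:3, function(s) {
    sim <- generate_monolayer_images(120, image_size = 400, seed = 40 + s)
    segmentation_score(sim$ground_truth, segment_nuclei(sim$hoechst))
  })
  expect_true(all(scores["matched", ] >= 0.95))
  expect_true(all(scores["spurious", ] <= 0.05))
})

test_that("cytoplasm rings have the right geometry and conserve labels", {
  # single disk nucleus of radius 10: ring from radius 10 to 16 (+-1 px)
  n <- 64
  lab <- matrix(0L, n, n)
  cx <- 32
  for (i in 1:n) for (j in 1:n) {
    if ((i - cx)^2 + (j - cx)^2 <= 100) lab[i, j] <- 1L
  }
  nuc <- label_map(lab, "nuclei")
  cyt <- segment_cytoplasm(nuc, expansion = 6)
  idx <- which(unclass(cyt) > 0L, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cx)^2)
  expect_gte(min(d), 10)
  expect_lte(max(d), 17)
  expect_gte(max(d), 15)
  # no ring pixel sits on the nucleus
  expect_equal(sum(unclass(cyt) > 0L & lab > 0L), 0)

  # label conservation on a generated field
  sim <- generate_monolayer_images(30, image_size = 256, seed = 55)
  masks <- sim$ground_truth$nucleus_masks
  rings <- segment_cytoplasm(masks, 6)
  expect_identical(map_labels(rings), map_labels(masks))

  expect_error(segment_cytoplasm(nuc, 0), "expansion")
})

test_that("contested ring pixels go to the nearest nucleus, ties to lower label", {
  lab <- matrix(0L, 40, 60)
  lab[18:22, 18:22] <- 1L
  lab[18:22, 31:35] <- 2L # 8 px gap between nucleus edges
  nuc <- label_map(lab, "nuclei")
  got <- segment_cytoplasm(nuc, 6)
  oracle <- brute_force_expand(nuc, 6)
  expect_identical(as_mat(got), oracle)

  empty <- label_map(matrix(0L, 16, 16), "nuclei")
  expect_equal(n_objects(segment_cytoplasm(empty)), 0)
})

test_that("PI overlap rule is inclusive at exactly 10%", {
  # hand-built fixture: one 10x10 nucleus (100 px), controlled PI pixels
  lab <- matrix(0L, 40, 40)
  lab[11:20, 11:20] <- 1L
  nuc <- label_map(lab, "nuclei")
  cyt <- segment_cytoplasm(nuc, 6)
  gfp <- channel_image(matrix(100, 40, 40), "gfp")
  for (case in list(list(npx = 9, pos = FALSE), list(npx = 10, pos = TRUE))) {
    mask <- matrix(FALSE, 40, 40)
    mask[11:20, 11][seq_len(min(case$npx, 10))] <- TRUE
    if (case$npx > 10) mask[11:20, 12][seq_len(case$npx - 10)] <- TRUE
    rec <- measure_cells(nuc, cyt, gfp, mask)
    expect_equal(rec$pi_overlap_fraction, case$npx / 100)
    expect_identical(rec$pi_positive, case$pos)
  }

  # empty mask: everyone negative
  rec <- measure_cells(nuc, cyt, gfp, matrix(FALSE, 40, 40))
  expect_false(any(rec$pi_positive))
})

test_that("partial-overlap generator fixtures classify exactly as expected", {
  fracs <- c(0.05, 0.09, 0.10, 0.50, 1.0)
  expected <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  for (k in seq_along(fracs)) {
    # large nuclei (area > 200 px) so the ceiling-rounded painted count
    # stays strictly on the requested side of the 10% boundary
    sim <- generate_monolayer_images(6, image_size = 256, seed = 60 + k,
      pi_fraction = 1, pi_paint_fraction = fracs[k], radius_range = c(8, 9))
    masks <- sim$ground_truth$nucleus_masks
    mask <- pi_mask_from_image(sim$pi, threshold = 20000)
    rec <- measure_cells(masks, segment_cytoplasm(masks), sim$gfp, mask)
    expect_identical(rec$pi_positive, rep(expected[k], 6),
      label = sprintf("paint fraction %.2f", fracs[k]))
  }
})

test_that("PI thresholding recovers the painted mask and handles edge cases", {
  sim <- generate_monolayer_images(12, image_size = 256, seed = 70,
    pi_fraction = 0.5)
  truth_ids <- sim$ground_truth$pi_positive_ids
  masks <- unclass(sim$ground_truth$nucleus_masks)
  # threshold at half the painted level: mask == ground-truth PI nuclei
  got <- pi_mask_from_image(sim$pi, threshold = 20000)
  want <- masks > 0 & masks %in% truth_ids
  expect_identical(got, want)
  # Otsu default finds the same mask on this bimodal image
  expect_identical(pi_mask_from_image(sim$pi), want)

  zero <- channel_image(matrix(0, 32, 32), "pi")
  expect_equal(sum(pi_mask_from_image(zero, threshold = 1)), 0)
  hi <- channel_image(matrix(100, 32, 32), "pi")
  expect_equal(sum(pi_mask_from_image(hi, threshold = 200)), 0)
})

test_that("cell measurements are exact on constant fields and scale linearly", {
  sim <- generate_monolayer_images(15, image_size = 256, seed = 80)
  masks <- sim$ground_truth$nucleus_masks
  rings <- segment_cytoplasm(masks)
  v <- 1234
  gfp <- channel_image(matrix(v, 256, 256), "gfp")
  rec <- measure_cells(masks, rings, gfp, matrix(FALSE, 256, 256))
  expect_equal(rec$nuclear_mean_gfp, rep(v, 15))
  expect_equal(rec$cytoplasmic_mean_gfp, rep(v, 15))

  # linearity: scaling the GFP image scales every mean
  g1 <- sim$gfp
  g3 <- channel_image(unclass(g1) * 3, "gfp")
  r1 <- measure_cells(masks, rings, g1, matrix(FALSE, 256, 256))
  r3 <- measure_cells(masks, rings, g3, matrix(FALSE, 256, 256))
  expect_equal(r3$nuclear_mean_gfp, 3 * r1$nuclear_mean_gfp)
  expect_equal(r3$cytoplasmic_mean_gfp, 3 * r1$cytoplasmic_mean_gfp)

  expect_error(
    measure_cells(masks, rings, channel_image(matrix(1, 10, 10), "gfp"),
      matrix(FALSE, 256, 256)),
    "shape"
  )
})

test_that("image summaries aggregate records and flag empty images", {
  rec <- data.frame(
    label = 1:10, nucleus_area = 100,
    nuclear_mean_gfp = 1:10 * 10, cytoplasm_area = 50,
    cytoplasmic_mean_gfp = 1:10 * 20,
    pi_overlap_fraction = c(rep(1, 3), rep(0, 7)),
    pi_positive = c(rep(TRUE, 3), rep(FALSE, 7))
  )
  s <- summarize_image(rec)
  expect_equal(s$pi_positive_fraction, 0.3)
  expect_equal(s$mean_nuclear_gfp, 55)
  expect_equal(s$mean_cytoplasmic_gfp, 110)
  expect_equal(s$n_cells, 10)
  expect_false(s$flagged)

  one <- summarize_image(rec[1, ])
  expect_equal(one$mean_nuclear_gfp, rec$nuclear_mean_gfp[1])
  expect_equal(one$pi_positive_fraction, 1)

  none <- summarize_image(rec[0, ])
  expect_true(none$flagged)
  expect_true(is.na(none$mean_nuclear_gfp))
  expect_equal(none$n_cells, 0)
})

test_that("the monolayer wrapper picks the reporter compartment", {
  sim <- generate_monolayer_images(20, image_size = 256, seed = 90)
  q_nuc <- quantify_monolayer(sim$hoechst, sim$gfp, sim$pi, reporter = "p21")
  q_cyt <- quantify_monolayer(sim$hoechst, sim$gfp, sim$pi, reporter = "BTG2")
  expect_equal(q_nuc$summary$reporter_gfp, q_nuc$summary$mean_nuclear_gfp)
  expect_equal(q_cyt$summary$reporter_gfp, q_cyt$summary$mean_cytoplasmic_gfp)
  expect_gt(q_nuc$summary$n_cells, 15)
})
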