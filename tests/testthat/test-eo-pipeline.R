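test_that("bin assignment follows floor(log2(area/170)) with the printed anchors", {
  expect_equal(assign_bin(170), 0L)
  expect_equal(assign_bin(10880), 6L)
  expect_equal(assign_bin(680), 2L)
  expect_equal(assign_bin(339), 0L)
  expect_equal(assign_bin(341), 1L)
  # boundaries are exactly 170 * 2^k and binning is monotone
  areas <- sort(runif(200, 170, 170 * 2^10))
  bins <- assign_bin(areas)
  expect_true(all(diff(bins) >= 0))
  for (k in 0:9) {
    expect_equal(assign_bin(170 * 2^k), k)
    if (k > 0) expect_equal(assign_bin(170 * 2^k - 0.01), k - 1L)
  }
  expect_error(assign_bin(150), "minimum")
  expect_warning(b <- assign_bin(170 * 2^10 + 1), "clamped")
  expect_equal(b, 9L)
})

test_that("size classes map bins 0-3/4-6/7-9 to small/medium/large", {
  expect_equal(as.character(eo_size_class(c(0, 3, 4, 6, 7, 9))),
               c("small", "small", "medium", "medium", "large", "large"))
})

test_that("detection finds rendered objects and drops sub-170 um^2 blobs", {
  mpp <- 0.5
  sp <- section_spec(260, 260, mpp, 1,
                     list(eo_spec(c(70, 70), 680, 1, 0, 0),
                          eo_spec(c(190, 190), 150, 1, 0, 0)),  # to be filtered
                     rng_seed = 13)
  sec <- render_section(sp)
  masks <- assign_pixels(to_optical_density(sec$image), stain_model(), mpp)
  det <- detect_eos(masks)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$area_um2 - 680) / 680, 0.02)
  expect_false(det$on_border)
  # empty masks are a valid input
  expect_equal(nrow(detect_eos(make_masks(matrix(FALSE, 5, 5),
                                          matrix(FALSE, 5, 5)))), 0L)
})

test_that("detection respects 8-connectivity for diagonally touching blobs", {
  ins <- matrix(FALSE, 40, 40)
  ins[5:20, 5:20] <- TRUE     # 256 px
  ins[21:36, 21:36] <- TRUE   # shares one corner diagonally
  det <- detect_eos(make_masks(ins, matrix(FALSE, 40, 40), mpp = 1),
                    connectivity = 8, compute_morphology = FALSE)
  expect_equal(nrow(det), 1L)
  expect_equal(det$area_um2, 512)
  det4 <- detect_eos(make_masks(ins, matrix(FALSE, 40, 40), mpp = 1),
                     connectivity = 4, compute_morphology = FALSE)
  expect_equal(nrow(det4), 2L)
})

test_that("positivity filter retains iff either hormone area exceeds 40 um^2", {
  tab <- rbind(eo_row(500, 50, 0, "a"),    # retained, Ins-positive only
               eo_row(500, 39, 39, "b"),   # excluded
               eo_row(500, 41, 41, "c"),   # retained, dual positive
               eo_row(500, 40, 40, "d"))   # boundary: excluded (strictly >)
  out <- filter_by_positivity(tab)
  expect_equal(out$object_id, c("a", "c"))
  expect_equal(attr(out, "n_excluded"), 2L)
  expect_true(out$ins_pos[1] && !out$gluc_pos[1])
  expect_true(out$ins_pos[2] && out$gluc_pos[2])
  # raising the threshold never increases the retained count
  prev <- Inf
  for (thr in c(10, 40, 60, 100)) {
    n <- nrow(filter_by_positivity(tab, thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("content classes partition the retained objects", {
  tab <- rbind(eo_row(600, 500, 20, "a"),
               eo_row(600, 45, 45, "b"),
               eo_row(600, 0, 300, "c"))
  out <- process_eo_table(tab)
  expect_equal(as.character(out$content_class),
               c("InsOnly", "InsGluc", "GlucOnly"))
  expect_equal(sum(table(out$content_class)), nrow(out))
  expect_error(classify_content(c(FALSE), c(FALSE)), "neither")
})

test_that("the full pipeline recovers ground truth exactly on disjoint interior blobs", {
  mpp <- 0.5
  specs <- list(eo_spec(c(60, 60), 400, 1, 0, 0.1),
                eo_spec(c(200, 70), 900, 0.5, 0.5, 0.2),
                eo_spec(c(80, 210), 2500, 0, 1, 0.2))
  sp <- section_spec(300, 300, mpp, 1, specs, rng_seed = 99)
  sec <- render_section(sp)
  masks <- assign_pixels(to_optical_density(sec$image), stain_model(), mpp)
  det <- detect_eos(masks, compute_morphology = FALSE)
  gt <- sec$ground_truth
  expect_equal(nrow(det), nrow(gt))
  # match by centroid proximity
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((det$centroid_x_um / mpp - gt$centroid_x_px[i])^2 +
              (det$centroid_y_um / mpp - gt$centroid_y_px[i])^2)
    j <- which.min(d)
    expect_equal(det$area_um2[j], gt$area_um2[i])
    expect_equal(det$ins_area_um2[j], gt$ins_area_um2[i])
    expect_equal(det$gluc_area_um2[j], gt$gluc_area_um2[i])
  }
})
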