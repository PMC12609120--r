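test_that("optical density transform follows Beer-Lambert closed forms", {
  # background pixel -> OD ~ 0 (within the eps stabilizer)
  img <- array(255, dim = c(2, 2, 3))
  od <- to_optical_density(img)
  expect_true(all(od >= 0))
  expect_lt(max(od), 0.003)
  # pixel at I0/10 -> OD ~ 1 per channel
  img[1, 1, ] <- 25.5
  od <- to_optical_density(img)
  expect_equal(unname(od[1, 1, ]), rep(1, 3), tolerance = 0.02)
  expect_error(to_optical_density(img, background_intensity = c(0, 255, 255)),
               "nonzero")
})

test_that("rendered pure-DAB pixels have OD collinear with the DAB vector", {
  m <- stain_model()
  sp <- section_spec(60, 60, 0.5, 1,
                     list(eo_spec(c(30, 30), 300, 1, 0, 0)), rng_seed = 3)
  sec <- render_section(sp, m, hematoxylin_conc = c(0, 0))
  od <- to_optical_density(sec$image)
  # take the darkest pixel (deep inside the blob)
  mag <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2)
  i <- which.max(mag)
  v <- c(od[, , 1][i], od[, , 2][i], od[, , 3][i])
  cosine <- sum(v * m$vectors["ins", ]) / sqrt(sum(v^2))
  expect_gt(cosine, 0.999)
})

test_that("pixel assignment is winner-take-all with hematoxylin ties and empty background", {
  m <- stain_model()
  img <- array(255L, dim = c(4, 4, 3))
  masks <- assign_pixels(to_optical_density(img), m, 1)
  expect_false(any(masks$ins | masks$gluc | masks$hematoxylin))
  # one pure-DAB pixel at unit concentration
  od <- array(0, dim = c(4, 4, 3))
  od[2, 2, ] <- m$vectors["ins", ]
  masks <- assign_pixels(od, m, 1)
  expect_true(masks$ins[2, 2])
  expect_equal(sum(masks$ins), 1)
  expect_false(any(masks$gluc))
  # masks are mutually exclusive by construction
  expect_false(any(masks$ins & masks$gluc))
})

test_that("chromogen positivity requires the OD threshold and under-counts dual stains", {
  m <- stain_model(od_threshold = 0.5)
  od <- array(0, dim = c(2, 2, 3))
  od[1, 1, ] <- 0.4 * m$vectors["ins", ]     # assigned to DAB but below cutoff
  od[1, 2, ] <- 0.8 * m$vectors["ins", ]
  # saturated dual-stain pixel: both chromogens strong, insulin stronger
  od[2, 1, ] <- 1.2 * m$vectors["ins", ] + 1.1 * m$vectors["gluc", ]
  masks <- assign_pixels(od, m, 1)
  expect_false(masks$ins[1, 1])
  expect_true(masks$ins[1, 2])
  expect_true(masks$ins[2, 1])      # assigned to the stronger projection only
  expect_false(masks$gluc[2, 1])    # the dual-positive pixel is under-counted
})

test_that("raising the OD threshold never increases positive area", {
  sp <- section_spec(80, 80, 0.5, 1,
                     list(eo_spec(c(40, 40), 500, 0.6, 0.4, 0.2)), rng_seed = 5)
  sec <- render_section(sp)
  od <- to_optical_density(sec$image)
  prev_ins <- Inf; prev_gluc <- Inf
  for (thr in c(0.05, 0.2, 0.5, 0.9, 1.2)) {
    masks <- assign_pixels(od, stain_model(od_threshold = thr), 0.5)
    expect_lte(sum(masks$ins), prev_ins)
    expect_lte(sum(masks$gluc), prev_gluc)
    prev_ins <- sum(masks$ins); prev_gluc <- sum(masks$gluc)
  }
})

test_that("quantify_areas matches ground truth and is additive over disjoint annotations", {
  mpp <- 0.5
  sp <- section_spec(160, 160, mpp, 1,
                     list(eo_spec(c(80, 80), 680, 1, 0, 0)), rng_seed = 9)
  sec <- render_section(sp)
  masks <- assign_pixels(to_optical_density(sec$image), stain_model(), mpp)
  gt <- sec$ground_truth
  # annotation covering the whole section
  side <- 160 * mpp
  whole <- cbind(c(0, side, side, 0), c(0, 0, side, side))
  res <- quantify_areas(masks, list(whole = whole))
  expect_equal(res$ins_area_um2, gt$ins_area_um2)
  expect_equal(res$total_area_um2, side^2)
  # two halves partition the section: areas add up
  left <- cbind(c(0, side / 2, side / 2, 0), c(0, 0, side, side))
  right <- cbind(c(side / 2, side, side, side / 2), c(0, 0, side, side))
  res2 <- quantify_areas(masks, list(l = left, r = right))
  expect_equal(sum(res2$ins_area_um2), res$ins_area_um2)
  expect_equal(sum(res2$gluc_area_um2), res$gluc_area_um2)
  # annotation covering no positive pixels -> zeros with its polygon area
  corner <- cbind(c(0, 5, 5, 0), c(0, 0, 5, 5))
  res3 <- quantify_areas(masks, list(c = corner))
  expect_equal(res3$ins_area_um2, 0)
  expect_equal(res3$gluc_area_um2, 0)
  expect_equal(res3$total_area_um2, 25)
})

test_that("areas scale with the square of microns per pixel", {
  ins <- rect_mask(20, 20, 5, 10, 5, 10)
  gluc <- matrix(FALSE, 20, 20)
  poly <- cbind(c(0, 20, 20, 0), c(0, 0, 20, 20))
  a1 <- quantify_areas(make_masks(ins, gluc, mpp = 1), list(poly))
  a2 <- quantify_areas(make_masks(ins, gluc, mpp = 2),
                       list(poly * 2))
  expect_equal(a2$ins_area_um2, 4 * a1$ins_area_um2)
  expect_equal(a2$total_area_um2, 4 * a1$total_area_um2)
})
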