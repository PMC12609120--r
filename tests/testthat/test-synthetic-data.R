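test_that("a single circular EO renders to its target area with correct hormone split", {
  sp <- section_spec(200, 200, 0.5, 1,
                     list(eo_spec(c(100, 100), 680, 1, 0, 0)), rng_seed = 7)
  sec <- render_section(sp)
  gt <- sec$ground_truth
  expect_equal(nrow(gt), 1L)
  # within one boundary-pixel ring of the target: ring ~ perimeter * mpp^2
  expect_lt(abs(gt$area_um2 - 680), 2 * pi * sqrt(680 / pi) * 0.5)
  expect_equal(gt$ins_area_um2, gt$area_um2)
  expect_equal(gt$gluc_area_um2, 0)
})

test_that("zero eo_specs give an empty ground truth and pure background", {
  sp <- section_spec(50, 50, 0.5, 1, list(), rng_seed = 1)
  sec <- render_section(sp, hematoxylin_conc = c(0, 0))
  expect_equal(nrow(sec$ground_truth), 0L)
  expect_true(all(sec$image == 255L))
})

test_that("touching EO specs merge into one ground-truth object", {
  # two blobs with centers 1 px apart must fuse
  sp <- section_spec(120, 120, 0.5, 1,
                     list(eo_spec(c(60, 60), 400, 1, 0, 0),
                          eo_spec(c(61, 60), 400, 0, 1, 0)),
                     rng_seed = 2)
  expect_warning(sec <- render_section(sp), "merged")
  gt <- sec$ground_truth
  expect_equal(nrow(gt), 1L)
  # merged area within 2% of the sum (overlap is re-counted once)
  expect_lt(abs(gt$area_um2 - 800) / 800, 0.5)  # heavy overlap shrinks it
  expect_equal(gt$ins_area_um2 + gt$gluc_area_um2, gt$area_um2)
})

test_that("rendering is byte-identical under the same seed", {
  sp <- section_spec(100, 100, 0.5, 0.9,
                     list(eo_spec(c(50, 50), 900, 0.6, 0.4, 0.3)), rng_seed = 42)
  s1 <- render_section(sp)
  s2 <- render_section(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("degenerate and oversized specs are rejected", {
  expect_error(eo_spec(c(10, 10), 0), "degenerate")
  expect_error(eo_spec(c(10, 10), 100, 0.7, 0.7), "ins_fraction")
  expect_error(section_spec(10, 10, 0.5, 1,
                            list(eo_spec(c(5, 5), 1e6))), "too small")
})

test_that("cohort sampling is deterministic and respects zero-density cells", {
  profs <- list(nd_profile(), t1d_profile())
  c1 <- sample_cohort(profs, 2, 2, rng_seed = 33)
  c2 <- sample_cohort(profs, 2, 2, rng_seed = 33)
  expect_identical(c1$donors, c2$donors)
  expect_identical(lapply(c1$sections, spec_eo_table),
                   lapply(c2$sections, spec_eo_table))
  # T1D profile has zero small InsOnly density: no InsOnly object in bins 0-3
  t1d_secs <- c1$sections[vapply(c1$sections, function(s)
    grepl("^T1D", attr(s, "donor_id")), TRUE)]
  for (s in t1d_secs) {
    tab <- process_eo_table(spec_eo_table(s))
    small_insonly <- tab$content_class == "InsOnly" & tab$eo_bin <= 3
    expect_equal(sum(small_insonly), 0L)
  }
})

test_that("sampled class proportions match the profile within 3 binomial SEs", {
  prof <- nd_profile()
  co <- sample_cohort(list(prof), n_donors_per_group = 6,
                      sections_per_donor = 2, rng_seed = 8, donor_sdlog = 0)
  tabs <- lapply(co$sections, function(s) process_eo_table(spec_eo_table(s)))
  all_cls <- unlist(lapply(tabs, function(t) as.character(t$content_class)))
  n <- length(all_cls)
  for (j in seq_along(eo_content_levels())) {
    p_hat <- mean(all_cls == eo_content_levels()[j])
    p <- prof$class_mix[j]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(p_hat - p), 3 * se + 1e-12)
  }
})

test_that("infeasible densities are rejected naming the bin", {
  dens <- matrix(0, 10, 3)
  dens[10, 2] <- 50   # 50 huge EOs per mm^2 cannot fit
  prof <- cohort_profile("ND", 30, dens)
  expect_error(sample_cohort(list(prof), 1, 1, rng_seed = 1), "bin 9")
})
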