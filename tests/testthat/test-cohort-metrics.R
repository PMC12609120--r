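test_that("donor aggregation uses the two-stage region-then-donor mean", {
  mk <- function(dens, region, sid) {
    # dens objects of 500 um^2 per mm^2 over 1 mm^2 of tissue
    n <- dens
    tab <- data.frame(object_id = sprintf("%s_%d", sid, seq_len(n)),
                      area_um2 = rep(500, n), ins_area_um2 = rep(500, n),
                      gluc_area_um2 = rep(0, n))
    section_profile(tab, tissue_area_mm2 = 1, section_id = sid,
                    donor_id = "d1", region = region)
  }
  profs <- list(mk(4, "PH", "s1"), mk(6, "PH", "s2"), mk(10, "PT", "s3"))
  donor <- aggregate_donor(profs)
  # PH mean = 5, PT = 10, donor = mean(5, 10) = 7.5, not mean(4, 6, 10)
  expect_equal(donor$density_total, 7.5)
  # single section: donor metrics equal section metrics
  single <- aggregate_donor(list(mk(4, "PH", "s1")))
  expect_equal(single$density_total, 4)
  # idempotence: aggregating a single-region donor twice changes nothing
  expect_equal(aggregate_donor(profs[1])$density_total,
               aggregate_donor(profs[1])$density_total)
})

test_that("count and area shares sum to 100% per section", {
  co <- sample_cohort(list(nd_profile()), 1, 1, rng_seed = 12)
  prof <- cohort_section_profiles(co)[[1]]
  m <- section_metrics(prof)
  cs <- unlist(m[grep("^countshare_.*_bin", names(m))])
  as_ <- unlist(m[grep("^areashare_.*_bin", names(m))])
  expect_equal(sum(cs), 100)
  expect_equal(sum(as_), 100)
  expect_error(section_profile(eo_row(500, 500, 0), 0), "positive")
})

test_that("endotype assignment splits at diagnosis age 13", {
  e <- assign_endotype(c("T1D", "T1D", "T1D", "ND"), c(6, 12.99, 13, NA))
  expect_equal(as.character(e), c("T1DE1", "T1DE1", "T1DE2", NA))
})

test_that("AAb risk requires at least three of four criteria", {
  r <- assign_aab_risk(
    group = c("AAb_multi", "AAb_multi", "AAb_multi", "ND"),
    grs_ge_50th = c(TRUE, TRUE, TRUE, TRUE),
    insulitis_reported = c(TRUE, TRUE, TRUE, TRUE),
    hlaI_hyperexpression = c(FALSE, FALSE, TRUE, TRUE),
    aab_flags = c("GADA;IA2A", "GADA", "GADA;mIAA;IA2A;ZnT8A", "IA2A"))
  expect_equal(as.character(r), c("high", "low", "high", NA))
  # missing flags are treated as FALSE with a message
  expect_message(
    r2 <- assign_aab_risk("AAb_multi", NA, TRUE, TRUE, "GADA"),
    "missing")
  expect_equal(as.character(r2), "low")
})

test_that("pancreas-weight fold changes follow medians with gap flagging", {
  br <- factor(c("b1", "b1", "b2", "b2", "b4"),
               levels = c("b1", "b2", "b3", "b4"))
  fc <- pancreas_weight_foldchange(c(10, 10, 20, 20, 30), br)
  expect_equal(fc$median_g, c(10, 20, NA, 30))
  expect_equal(fc$fold_change, c(NA, 2, NA, 1.5))
  expect_equal(fc$ref_bracket[4], "b2")   # empty b3 skipped, flagged
  expect_true(fc$gap[4])
  # constant medians -> all folds 1
  fc2 <- pancreas_weight_foldchange(rep(5, 3), factor(c("a", "b", "c")))
  expect_equal(fc2$fold_change, c(NA, 1, 1))
})

test_that("BH adjustment matches the step-up closed form and two-group tests behave", {
  dm <- data.frame(group = rep(c("ND", "T1D"), each = 5),
                   m1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                   m2 = rep(1, 10),
                   m3 = c(2, 1, 3, 2, 4, 9, 8, 7, 9, 8))
  res <- compare_groups(dm, c("m1", "m2", "m3"), method = "wilcox_bh")
  # hand step-up: p_adj(i) = min_j>=i (m * p_(j) / j), capped at 1
  p <- res$tests$p
  o <- order(p)
  m <- length(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj <- pmin(adj, 1)[order(o)]
  expect_equal(res$tests$p_adj, adj)
  expect_true(all(res$tests$p_adj >= res$tests$p))
  # all-tied metric is degenerate with p = 1
  expect_equal(res$tests$p[res$tests$metric == "m2"], 1)
  expect_match(res$tests$note[res$tests$metric == "m2"], "degenerate")
  # identical groups: no adjusted significance
  dm2 <- data.frame(group = rep(c("A", "B"), each = 4), m = c(1:4, 1:4))
  res2 <- compare_groups(dm2, "m", method = "wilcox_bh")
  expect_gt(res2$tests$p_adj, 0.9)
})

test_that("groups below the minimum n are skipped and flagged", {
  dm <- data.frame(group = c("A", "A", "A", "B", "B"), m = 1:5)
  res <- compare_groups(dm, "m", method = "wilcox_bh")
  expect_match(res$tests$note, "skipped")
  expect_true(is.na(res$tests$p))
})

test_that("Kruskal-Wallis and type II ANOVA plans run with post hoc contrasts", {
  set.seed(5)
  dm <- data.frame(group = rep(c("A", "B", "C"), each = 6),
                   m = c(rnorm(6, 0), rnorm(6, 0.5), rnorm(6, 3)))
  res <- compare_groups(dm, "m", method = "kruskal_tukey")
  expect_equal(res$tests$procedure[1], "Kruskal-Wallis")
  expect_equal(sum(res$tests$procedure == "Tukey post hoc"), 3L)  # 3 pairs
  # long-format factorial: group x bin
  long <- expand.grid(group = c("ND", "T1D"), bin = factor(0:3),
                      rep = 1:5)
  long$value <- rnorm(nrow(long)) + 2 * (long$group == "T1D") *
    (long$bin %in% c("0", "1"))
  res2 <- compare_groups(long, "value", method = "anova2_tukey",
                         stratum_col = "bin")
  expect_true("type II ANOVA" %in% res2$tests$procedure)
  expect_equal(sum(grepl("\\|", res2$tests$comparison)), 4L)  # one per bin
  res3 <- compare_groups(long, "value", method = "anova2_dunnett",
                         stratum_col = "bin", control = "ND")
  expect_equal(sum(grepl("\\|", res3$tests$comparison)), 4L)
  expect_error(compare_groups(long, "value", method = "anova2_dunnett",
                              stratum_col = "bin"), "control")
})

test_that("spatial plots map one point per EO with size increasing in bin", {
  tab <- rbind(eo_row(200, 200, 0, "a"),      # bin 0
               eo_row(6000, 3000, 3000, "b"), # bin 5
               eo_row(90000, 0, 90000, "c"))  # bin 9
  tab$centroid_x_um <- c(10, 50, 90)
  tab$centroid_y_um <- c(10, 50, 90)
  prof <- section_profile(tab, 1, "s1", "d1", "PH")
  p <- spatial_plot(prof, color_by = "bin", age_years = 9, group = "ND")
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  pts <- built$data[[1]]
  expect_equal(nrow(pts), 3L)               # point count = retained EO count
  expect_true(all(diff(pts$size[order(pts$x)]) > 0))  # monotone in bin
  # empty section renders without points
  empty <- section_profile(eo_row(500, 0, 0)[0, ], 1, "s0", "d1", "PH")
  expect_s3_class(spatial_plot(empty), "ggplot")
})
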