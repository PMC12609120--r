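#' Build a section profile from an EO table
#'
#' Wraps one section's object table with its tissue context and runs the
#' table-level pipeline (positivity filter, content classification, size
#' binning).  The endocrine area of the section is the sum of retained
#' object areas.
#'
#' @param eo_table Data frame with at least `area_um2`, `ins_area_um2`,
#'   `gluc_area_um2`.
#' @param tissue_area_mm2 Tissue area of the section in mm^2 (must be > 0).
#' @param section_id,donor_id Identifiers.
#' @param region Pancreas region: `PH` (head), `PB` (body), `PT` (tail),
#'   or `PO` (other/unknown).
#' @param positivity_um2 Per-hormone positivity threshold in um^2.
#' @return An object of class `section_profile`.
#' @export
section_profile <- function(eo_table, tissue_area_mm2, section_id = "s1",
                            donor_id = NA_character_, region = "PO",
                            positivity_um2 = 40) {
  if (!is.finite(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("tissue_area_mm2 must be positive")
  region <- match.arg(region, c("PH", "PB", "PT", "PO"))
  objects <- process_eo_table(eo_table, positivity_um2 = positivity_um2)
  structure(list(section_id = section_id, donor_id = donor_id,
                 region = region, tissue_area_mm2 = tissue_area_mm2,
                 endocrine_area_um2 = sum(objects$area_um2),
                 objects = objects),
            class = "section_profile")
}

#' @export
print.section_profile <- function(x, ...) {
  cat("Section", x$section_id, "| donor", x$donor_id, "| region", x$region, "\n")
  cat(nrow(x$objects), "EOs over", x$tissue_area_mm2, "mm^2 tissue (",
      signif(100 * x$endocrine_area_um2 / (x$tissue_area_mm2 * 1e6), 3),
      "% endocrine area)\n")
  invisible(x)
}

#' Per-section EO metrics
#'
#' Computes the reported metric family for one section: total and per
#' bin x class EO density (count/mm^2), percentage of tissue occupied by
#' endocrine area, per bin x class percentage of total EO count and of
#' total endocrine area, insulin- and glucagon-labeled area as a
#' percentage of tissue per bin, and small/medium/large density sums per
#' class.  Count and area shares each sum to 100% over bins x classes.
#'
#' @param profile A [section_profile()].
#' @return One-row data frame of metrics (plus `section_id`, `donor_id`,
#'   `region`).
#' @export
section_metrics <- function(profile) {
  stopifnot(inherits(profile, "section_profile"))
  obj <- profile$objects
  tt <- profile$tissue_area_mm2
  classes <- eo_content_levels()
  bins <- 0:9
  n_tot <- nrow(obj)
  a_tot <- profile$endocrine_area_um2
  out <- data.frame(section_id = profile$section_id,
                    donor_id = profile$donor_id,
                    region = profile$region,
                    density_total = n_tot / tt,
                    pct_endocrine_area = 100 * a_tot / (tt * 1e6))
  cnt <- matrix(0, 10, 3, dimnames = list(paste0("bin", bins), classes))
  ar <- ins_ar <- gluc_ar <- cnt
  if (n_tot) {
    for (i in seq_len(n_tot)) {
      b <- obj$eo_bin[i] + 1L
      j <- as.integer(obj$content_class[i])
      cnt[b, j] <- cnt[b, j] + 1
      ar[b, j] <- ar[b, j] + obj$area_um2[i]
      ins_ar[b, j] <- ins_ar[b, j] + obj$ins_area_um2[i]
      gluc_ar[b, j] <- gluc_ar[b, j] + obj$gluc_area_um2[i]
    }
  }
  for (j in seq_along(classes)) for (b in bins) {
    key <- paste0(classes[j], "_bin", b)
    out[[paste0("density_", key)]] <- cnt[b + 1L, j] / tt
    out[[paste0("countshare_", key)]] <- if (n_tot) 100 * cnt[b + 1L, j] / n_tot else 0
    out[[paste0("areashare_", key)]] <- if (a_tot > 0) 100 * ar[b + 1L, j] / a_tot else 0
  }
  for (b in bins) {
    out[[paste0("pct_ins_tissue_bin", b)]] <- 100 * sum(ins_ar[b + 1L, ]) / (tt * 1e6)
    out[[paste0("pct_gluc_tissue_bin", b)]] <- 100 * sum(gluc_ar[b + 1L, ]) / (tt * 1e6)
  }
  size_rows <- list(small = 1:4, medium = 5:7, large = 8:10)
  for (j in seq_along(classes)) for (s in names(size_rows)) {
    out[[paste0("density_", classes[j], "_", s)]] <-
      sum(cnt[size_rows[[s]], j]) / tt
  }
  for (s in names(size_rows))
    out[[paste0("density_", s)]] <- sum(cnt[size_rows[[s]], ]) / tt
  for (j in seq_along(classes)) {
    out[[paste0("countshare_", classes[j])]] <-
      if (n_tot) 100 * sum(cnt[, j]) / n_tot else 0
    out[[paste0("areashare_", classes[j])]] <-
      if (a_tot > 0) 100 * sum(ar[, j]) / a_tot else 0
  }
  out
}

#' Aggregate section metrics to donor level
#'
#' Two-stage mean: section metrics are first averaged within each pancreas
#' region, then region means are averaged to give the donor value, so
#' regions contribute equally regardless of how many sections each has.
#'
#' @param profiles List of [section_profile()]s from one donor.
#' @return One-row data frame of donor-level metrics with `donor_id`.
#' @export
aggregate_donor <- function(profiles) {
  if (inherits(profiles, "section_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  m <- do.call(rbind, lapply(profiles, section_metrics))
  num <- names(m)[vapply(m, is.numeric, TRUE)]
  by_region <- aggregate(m[num], by = list(region = m$region), FUN = mean)
  donor <- as.data.frame(t(colMeans(by_region[num])))
  cbind(data.frame(donor_id = m$donor_id[1]), donor)
}

#' Aggregate a list of section profiles to a donor-level metrics table
#'
#' @param profiles List of [section_profile()]s spanning several donors.
#' @return Data frame with one row per donor.
#' @export
aggregate_cohort <- function(profiles) {
  ids <- vapply(profiles, function(p) p$donor_id, "")
  out <- do.call(rbind, lapply(split(profiles, ids), aggregate_donor))
  rownames(out) <- NULL
  out
}

#' Assign the T1D pancreatic endotype
#'
#' T1DE1 is defined by an age at clinical diagnosis under 13 years, T1DE2
#' by diagnosis at 13 years or later (the boundary value 13.0 is T1DE2).
#' Donors who are not T1D, or whose diagnosis age is unknown, get `NA`.
#'
#' @param group Character vector of donor groups.
#' @param age_at_diagnosis_years Numeric vector of diagnosis ages.
#' @return Factor with levels `T1DE1`, `T1DE2`.
#' @export
#' @examples
#' assign_endotype(c("T1D", "T1D", "ND"), c(6, 13, NA))
assign_endotype <- function(group, age_at_diagnosis_years) {
  stopifnot(length(group) == length(age_at_diagnosis_years))
  e <- ifelse(group == "T1D" & !is.na(age_at_diagnosis_years),
              ifelse(age_at_diagnosis_years < 13, "T1DE1", "T1DE2"),
              NA_character_)
  factor(e, levels = c("T1DE1", "T1DE2"))
}

#' Assign progression risk to AAb+ donors
#'
#' An autoantibody-positive donor is high risk iff at least three of the
#' four criteria hold: genetic risk score (GRS1 or GRS2) at or above the
#' 50th percentile, reported insulitis, HLA class I hyperexpression, and
#' IA2A positivity.  Missing flags are treated as `FALSE` with a logged
#' message (the conservative choice).  Non-AAb donors get `NA`.
#'
#' @param group Character vector of donor groups.
#' @param grs_ge_50th,insulitis_reported,hlaI_hyperexpression Logical flags.
#' @param aab_flags Character vector of detected autoantibodies, `";"`
#'   separated (e.g. `"GADA;IA2A"`), or a list of character vectors.
#' @return Factor with levels `high`, `low`.
#' @export
assign_aab_risk <- function(group, grs_ge_50th, insulitis_reported,
                            hlaI_hyperexpression, aab_flags) {
  n <- length(group)
  if (is.list(aab_flags)) {
    ia2a <- vapply(aab_flags, function(f) "IA2A" %in% f, TRUE)
  } else {
    ia2a <- grepl("\\bIA2A\\b", as.character(aab_flags))
  }
  flags <- cbind(grs_ge_50th, insulitis_reported, hlaI_hyperexpression, ia2a)
  if (anyNA(flags)) {
    message("assign_aab_risk: ", sum(is.na(flags)),
            " missing flag(s) treated as FALSE")
    flags[is.na(flags)] <- FALSE
  }
  score <- rowSums(flags)
  r <- ifelse(group %in% c("AAb_single", "AAb_multi"),
              ifelse(score >= 3, "high", "low"), NA_character_)
  factor(r, levels = c("high", "low"))
}

#' Age brackets used for cohort grouping
#'
#' Default brackets: 0-1, 2-6, 7-12, 13-17, and >= 18 years.
#'
#' @param age_years Numeric ages.
#' @param breaks Left edges of the brackets (last bracket is open-ended).
#' @return Ordered factor of brackets.
#' @export
age_bracket <- function(age_years, breaks = c(0, 2, 7, 13, 18)) {
  labs <- c(paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
            paste0(">=", breaks[length(breaks)]))
  cut(age_years, breaks = c(breaks, Inf), labels = labs,
      right = FALSE, ordered_result = TRUE)
}

#' Fold change in median pancreas weight across age brackets
#'
#' For each bracket (in level order), the fold change of its median weight
#' relative to the previous non-empty bracket.  The first bracket has no
#' reference; an empty bracket leaves a gap (no interpolation) and the next
#' non-empty bracket is compared against the last non-empty one, flagged.
#'
#' @param weight_g Numeric pancreas weights in grams.
#' @param bracket Factor of age brackets (e.g. from [age_bracket()]).
#' @return Data frame: `bracket`, `n`, `median_g`, `fold_change`,
#'   `ref_bracket`, `gap` (TRUE when the reference is not the immediately
#'   preceding bracket).
#' @export
#' @examples
#' pancreas_weight_foldchange(c(10, 10, 20, 30), factor(c("a", "a", "b", "c"),
#'   levels = c("a", "b", "c")))
pancreas_weight_foldchange <- function(weight_g, bracket) {
  stopifnot(length(weight_g) == length(bracket))
  bracket <- as.factor(bracket)
  lv <- levels(bracket)
  med <- vapply(lv, function(l) {
    w <- weight_g[bracket == l & !is.na(weight_g)]
    if (length(w)) median(w) else NA_real_
  }, 0)
  n <- vapply(lv, function(l) sum(bracket == l & !is.na(weight_g)), 0L)
  fold <- rep(NA_real_, length(lv))
  ref <- rep(NA_character_, length(lv))
  gap <- rep(FALSE, length(lv))
  last <- NA_integer_
  for (i in seq_along(lv)) {
    if (is.na(med[i])) next
    if (!is.na(last)) {
      fold[i] <- med[i] / med[last]
      ref[i] <- lv[last]
      gap[i] <- last != i - 1L
    }
    last <- i
  }
  data.frame(bracket = lv, n = n, median_g = unname(med),
             fold_change = fold, ref_bracket = ref, gap = gap)
}

# Group means with 95% t-interval on donor-level values.
group_summary <- function(data, metrics, group_col = "group") {
  res <- list()
  for (m in metrics) {
    for (g in unique(data[[group_col]])) {
      x <- data[[m]][data[[group_col]] == g]
      x <- x[!is.na(x)]
      n <- length(x)
      half <- if (n > 1) qt(0.975, n - 1) * sd(x) / sqrt(n) else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        metric = m, group = g, n = n, mean = mean(x),
        ci_lo = mean(x) - half, ci_hi = mean(x) + half)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare donor groups on EO metrics
#'
#' Implements the study's test plan on donor-level values:
#' * `wilcox_bh`: Mann-Whitney U between exactly two groups for each metric
#'   in the family, with Benjamini-Hochberg adjustment across the family.
#' * `kruskal_tukey`: Kruskal-Wallis across >= 3 groups on one metric,
#'   followed by Tukey all-pairs post hoc contrasts on estimated marginal
#'   means.
#' * `anova2_tukey` / `anova2_dunnett`: type II two-factor ANOVA
#'   (group x stratum, e.g. bin or content class) with Tukey all-pairs or
#'   Dunnett versus-control post hoc contrasts within each stratum.  The
#'   choice between Tukey and Dunnett is always explicit, never inferred.
#'
#' Groups with fewer than `min_n` donors cause the test to be skipped and
#' flagged.  Comparisons where all values are tied are reported as
#' degenerate with p = 1.
#'
#' @param data Donor-level data frame.  For the wilcox/kruskal methods it is
#'   wide (one column per metric); for the ANOVA methods it is long with a
#'   `value` column and a stratum column.
#' @param metrics Character vector of metric columns (wilcox_bh), or a
#'   single metric (kruskal_tukey), or the value column name (ANOVA).
#' @param group_col Name of the grouping column.
#' @param method Test plan (see above).
#' @param stratum_col Stratum column for the ANOVA methods.
#' @param control Control group label for Dunnett contrasts.
#' @param min_n Minimum donors per group (default 3).
#' @return A list of class `cohort_result`: `tests` (comparison, statistic,
#'   raw and adjusted p, procedure, note), `summary` (group means with 95%
#'   CI, wide methods only), `method`.
#' @export
compare_groups <- function(data, metrics, group_col = "group",
                           method = c("wilcox_bh", "kruskal_tukey",
                                      "anova2_tukey", "anova2_dunnett"),
                           stratum_col = NULL, control = NULL, min_n = 3) {
  method <- match.arg(method)
  grp <- as.factor(data[[group_col]])
  tab <- table(grp)
  small <- names(tab)[tab < min_n]
  if (length(small))
    return(structure(list(
      tests = data.frame(comparison = NA_character_, statistic = NA_real_,
                         p = NA_real_, p_adj = NA_real_, procedure = method,
                         note = paste("skipped: groups below n =", min_n, ":",
                                      paste(small, collapse = ","))),
      summary = NULL, method = method), class = "cohort_result"))

  if (method == "wilcox_bh") {
    lv <- levels(droplevels(grp))
    if (length(lv) != 2)
      stop("wilcox_bh requires exactly two groups")
    rows <- lapply(metrics, function(m) {
      x <- data[[m]][grp == lv[1]]
      y <- data[[m]][grp == lv[2]]
      if (length(unique(c(x, y))) == 1L)
        return(data.frame(comparison = paste(lv[1], "vs", lv[2]),
                          metric = m, statistic = NA_real_, p = 1,
                          procedure = "Mann-Whitney U",
                          note = "degenerate: all values tied"))
      wt <- suppressWarnings(wilcox.test(x, y))
      data.frame(comparison = paste(lv[1], "vs", lv[2]), metric = m,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 procedure = "Mann-Whitney U", note = "")
    })
    tests <- do.call(rbind, rows)
    tests$p_adj <- p.adjust(tests$p, method = "BH")
    tests <- tests[, c("comparison", "metric", "statistic", "p", "p_adj",
                       "procedure", "note")]
    return(structure(list(tests = tests,
                          summary = group_summary(data, metrics, group_col),
                          method = method), class = "cohort_result"))
  }

  if (method == "kruskal_tukey") {
    m <- metrics[1]
    kw <- kruskal.test(data[[m]], grp)
    fit <- lm(stats::reformulate(group_col, response = m), data = data)
    em <- emmeans::emmeans(fit, specs = group_col)
    ph <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey"))
    tests <- rbind(
      data.frame(comparison = "omnibus", metric = m,
                 statistic = unname(kw$statistic), p = kw$p.value,
                 p_adj = kw$p.value, procedure = "Kruskal-Wallis", note = ""),
      data.frame(comparison = ph$contrast, metric = m,
                 statistic = ph$t.ratio, p = ph$p.value, p_adj = ph$p.value,
                 procedure = "Tukey post hoc", note = ""))
    return(structure(list(tests = tests,
                          summary = group_summary(data, m, group_col),
                          method = method), class = "cohort_result"))
  }

  # type II two-factor ANOVA with per-stratum post hoc contrasts
  if (is.null(stratum_col)) stop("stratum_col required for ANOVA methods")
  value_col <- metrics[1]
  df <- data.frame(value = data[[value_col]],
                   group = grp,
                   stratum = as.factor(data[[stratum_col]]))
  fit <- lm(value ~ group * stratum, data = df)
  an <- car::Anova(fit, type = "II")
  em <- emmeans::emmeans(fit, ~ group | stratum)
  if (method == "anova2_tukey") {
    ph <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey"))
    proc <- "type II ANOVA + Tukey"
  } else {
    if (is.null(control)) stop("`control` required for Dunnett contrasts")
    ref <- which(levels(df$group) == control)
    if (!length(ref)) stop("control group not found: ", control)
    ph <- as.data.frame(emmeans::contrast(em, method = "trt.vs.ctrl",
                                          ref = ref))
    proc <- "type II ANOVA + Dunnett"
  }
  an_rows <- data.frame(comparison = rownames(an)[rownames(an) != "Residuals"],
                        metric = value_col,
                        statistic = an$`F value`[rownames(an) != "Residuals"],
                        p = an$`Pr(>F)`[rownames(an) != "Residuals"],
                        procedure = "type II ANOVA", note = "")
  an_rows$p_adj <- an_rows$p
  ph_rows <- data.frame(comparison = paste(ph$contrast, "|", ph$stratum),
                        metric = value_col, statistic = ph$t.ratio,
                        p = ph$p.value, p_adj = ph$p.value,
                        procedure = proc, note = "")
  tests <- rbind(an_rows[, c("comparison", "metric", "statistic", "p",
                             "p_adj", "procedure", "note")], ph_rows)
  structure(list(tests = tests, summary = NULL, method = method),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort comparison (", x$method, ")\n", sep = "")
  print(head(x$tests, 20))
  if (nrow(x$tests) > 20) cat("...", nrow(x$tests) - 20, "more rows\n")
  invisible(x)
}
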