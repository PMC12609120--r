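#' Construct a cohort profile
#'
#' A cohort profile defines the expected endocrine-object population of one
#' donor group as a 10 x 3 density matrix: EO count per mm^2 of tissue for
#' bins 0-9 by hormone-content class.
#'
#' @param group_label One of `ND`, `T1D`, `AAb_single`, `AAb_multi`.
#' @param age_years Representative donor age for the group.
#' @param density_matrix 10 x 3 non-negative matrix (rows bins 0-9, columns
#'   `InsOnly`, `InsGluc`, `GlucOnly`) of EO densities in count/mm^2.
#' @return An object of class `cohort_profile` with the class mixture
#'   (column shares of total density) attached.
#' @export
cohort_profile <- function(group_label, age_years, density_matrix) {
  group_label <- match.arg(group_label, c("ND", "T1D", "AAb_single", "AAb_multi"))
  density_matrix <- as.matrix(density_matrix)
  if (!all(dim(density_matrix) == c(10L, 3L)))
    stop("density_matrix must be 10 bins x 3 classes")
  if (any(density_matrix < 0) || any(!is.finite(density_matrix)))
    stop("densities must be finite and non-negative")
  colnames(density_matrix) <- eo_content_levels()
  rownames(density_matrix) <- paste0("bin", 0:9)
  stopifnot(age_years >= 0)
  mix <- colSums(density_matrix) / sum(density_matrix)
  structure(list(group_label = group_label, age_years = age_years,
                 density = density_matrix, class_mix = mix),
            class = "cohort_profile")
}

# density matrix from total density, class mixture, and per-class bin
# distributions (each a length-10 vector summing to 1)
build_density <- function(total, mix, bins_by_class) {
  m <- sapply(seq_len(3), function(j) total * mix[j] * bins_by_class[[j]])
  colnames(m) <- eo_content_levels()
  m
}

#' Default non-diabetic (ND) cohort profile
#'
#' Emulates the EO population of an adult donor without diabetes: total
#' density 8 EO/mm^2 with content-class count shares 54.5% Ins+Gluc-,
#' 36.8% Ins+Gluc+, 8.7% Ins-Gluc+; 96% of Ins+Gluc- and 99.1% of
#' Ins-Gluc+ objects fall in the small bins (0-3), while Ins+Gluc+ objects
#' concentrate in the medium and large bins.
#'
#' @param age_years Representative donor age (default 30).
#' @param total_density Total EO density in count/mm^2.
#' @return A [cohort_profile()].
#' @export
nd_profile <- function(age_years = 30, total_density = 8) {
  bins <- list(
    InsOnly = c(0.96 * c(0.55, 0.27, 0.13, 0.05), 0.04 * c(0.6, 0.3, 0.1), 0, 0, 0),
    InsGluc = c(0.04, 0.06, 0.08, 0.12, 0.20, 0.20, 0.15, 0.09, 0.04, 0.02),
    GlucOnly = c(0.991 * c(0.60, 0.25, 0.10, 0.05), 0.009 * c(0.7, 0.3), 0, 0, 0, 0))
  cohort_profile("ND", age_years,
                 build_density(total_density, c(0.545, 0.368, 0.087), bins))
}

#' Default type 1 diabetes (T1D) cohort profile
#'
#' Emulates an established-T1D EO population: lower total density (default
#' 4 EO/mm^2), content-class count shares 5.8% Ins+Gluc-, 12.3% Ins+Gluc+,
#' 81.9% Ins-Gluc+, with *zero* Ins+Gluc- density in the small bins (0-3)
#' -- the virtual absence of extraislet beta cells -- and residual
#' Ins+Gluc+ objects confined to medium/large bins.
#'
#' @param age_years Representative donor age (default 30).
#' @param total_density Total EO density in count/mm^2.
#' @return A [cohort_profile()].
#' @export
t1d_profile <- function(age_years = 30, total_density = 4) {
  bins <- list(
    InsOnly = c(0, 0, 0, 0, 0.40, 0.30, 0.15, 0.08, 0.05, 0.02),
    InsGluc = c(0, 0, 0.02, 0.05, 0.13, 0.20, 0.25, 0.20, 0.10, 0.05),
    GlucOnly = c(0.55, 0.25, 0.12, 0.05, 0.02, 0.01, 0, 0, 0, 0))
  cohort_profile("T1D", age_years,
                 build_density(total_density, c(0.058, 0.123, 0.819), bins))
}

#' Default autoantibody-positive (AAb+) cohort profiles
#'
#' Single-AAb donors carry an essentially ND-like EO population; multiple-
#' AAb donors are rendered with the small Ins+Gluc- density halved and a
#' correspondingly higher small Ins-Gluc+ density, reflecting the
#' intermediate phenotype of at-risk donors.
#'
#' @param type `"single"` or `"multi"`.
#' @param age_years Representative donor age.
#' @return A [cohort_profile()].
#' @export
aab_profile <- function(type = c("single", "multi"), age_years = 30) {
  type <- match.arg(type)
  base <- nd_profile(age_years)$density
  if (type == "single")
    return(cohort_profile("AAb_single", age_years, base))
  shift <- base[1:4, "InsOnly"] * 0.5
  base[1:4, "InsOnly"] <- base[1:4, "InsOnly"] - shift
  base[1:4, "GlucOnly"] <- base[1:4, "GlucOnly"] + shift
  cohort_profile("AAb_multi", age_years, base)
}

# bin area boundaries in um^2: [170 * 2^k, 170 * 2^(k+1))
bin_bounds <- function(bin) cbind(lo = 170 * 2^bin, hi = 170 * 2^(bin + 1))

#' Sample a synthetic donor cohort
#'
#' Draws a ground-truthed cohort from a list of [cohort_profile()]s: for
#' every donor, per-section EO counts are Poisson with mean
#' `density x tissue area` (modulated by a mean-one lognormal donor
#' effect), EO areas are uniform within their bin boundaries
#' `[170*2^k, 170*2^(k+1))`, and hormone fractions follow the content
#' class (Ins+Gluc-: all insulin; Ins-Gluc+: all glucagon; Ins+Gluc+: an
#' insulin core fraction drawn in 0.3-0.7).  Sections cycle through the
#' pancreas regions head/body/tail.  The same seed reproduces the cohort
#' byte for byte.
#'
#' @param profiles List of [cohort_profile()]s (one per group).
#' @param n_donors_per_group Donors per profile.
#' @param sections_per_donor Sections per donor (default 3).
#' @param rng_seed Integer seed.
#' @param section_area_mm2 Canvas area of each section in mm^2.
#' @param tissue_fraction Tissue fraction of the canvas.
#' @param microns_per_px Scale for the emitted [section_spec()]s.
#' @param donor_sdlog Donor-level lognormal effect (sdlog; the effect is
#'   normalized to mean 1 so group densities stay unbiased).
#' @return A list of class `eo_cohort`: `sections` (list of `section_spec`
#'   with `section_id`, `donor_id`, `region`, `tissue_area_mm2` attached as
#'   attributes), `donors` (metadata data frame), `profiles`.
#' @export
sample_cohort <- function(profiles, n_donors_per_group,
                          sections_per_donor = 3, rng_seed = 1L,
                          section_area_mm2 = 25, tissue_fraction = 0.9,
                          microns_per_px = 0.5, donor_sdlog = 0.25) {
  if (inherits(profiles, "cohort_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1, n_donors_per_group >= 1,
            sections_per_donor >= 1)
  tissue_mm2 <- section_area_mm2 * tissue_fraction
  # feasibility: expected EO area must fit in the tissue
  for (p in profiles) {
    exp_area <- rowSums(p$density) * tissue_mm2 * rowMeans(bin_bounds(0:9))
    if (sum(exp_area) > 0.5 * tissue_mm2 * 1e6) {
      worst <- which.max(exp_area) - 1L
      stop("requested density infeasible for section size (worst: bin ",
           worst, ")")
    }
  }
  side_px <- ceiling(sqrt(section_area_mm2 * 1e6) / microns_per_px)
  lo_px <- side_px * (1 - sqrt(tissue_fraction)) / 2
  hi_px <- side_px - lo_px
  regions <- rep(c("PH", "PB", "PT"), length.out = sections_per_donor)
  aab_pool <- c("GADA", "mIAA", "IA2A", "ZnT8A")

  with_seed(rng_seed, {
    sections <- list()
    donors <- list()
    for (gi in seq_along(profiles)) {
      p <- profiles[[gi]]
      dens <- p$density
      for (di in seq_len(n_donors_per_group)) {
        donor_id <- sprintf("%s_d%02d", p$group_label, di)
        effect <- rlnorm(1, 0, donor_sdlog) / exp(donor_sdlog^2 / 2)
        age <- max(0, p$age_years + runif(1, -3, 3))
        for (si in seq_len(sections_per_donor)) {
          eos <- list()
          for (b in 0:9) for (j in 1:3) {
            lambda <- dens[b + 1L, j] * tissue_mm2 * effect
            n <- rpois(1, lambda)
            if (n == 0) next
            bb <- bin_bounds(b)
            areas <- runif(n, bb[1], bb[2])
            cls <- eo_content_levels()[j]
            for (a in areas) {
              fi <- switch(cls, InsOnly = 1, GlucOnly = 0,
                           InsGluc = runif(1, 0.3, 0.7))
              eos[[length(eos) + 1L]] <- eo_spec(
                center = runif(2, lo_px, hi_px),
                target_area = a, ins_fraction = fi, gluc_fraction = 1 - fi,
                shape_irregularity = 0.1 + 0.04 * b)
            }
          }
          sp <- section_spec(side_px, side_px, microns_per_px,
                             tissue_fraction, eos,
                             rng_seed = sample.int(.Machine$integer.max, 1))
          attr(sp, "section_id") <- sprintf("%s_s%d", donor_id, si)
          attr(sp, "donor_id") <- donor_id
          attr(sp, "region") <- regions[si]
          attr(sp, "tissue_area_mm2") <- tissue_mm2
          sections[[length(sections) + 1L]] <- sp
        }
        grp <- p$group_label
        duration <- age_dx <- NA_real_
        if (grp == "T1D") {
          age_dx <- runif(1, 0.5, max(1, age - 0.5))
          duration <- age - age_dx
        }
        flags <- switch(grp,
          ND = character(0),
          T1D = sample(aab_pool, sample(1:3, 1)),
          AAb_single = sample(aab_pool, 1),
          AAb_multi = sample(aab_pool, sample(2:4, 1)))
        donors[[length(donors) + 1L]] <- data.frame(
          donor_id = donor_id, group = grp, age_years = age,
          age_at_diagnosis_years = age_dx, duration_years = duration,
          aab_flags = paste(flags, collapse = ";"),
          grs_ge_50th = runif(1) < if (grp %in% c("T1D", "AAb_multi")) 0.6 else 0.3,
          insulitis_reported = grp == "T1D" && runif(1) < 0.3 ||
            grp == "AAb_multi" && runif(1) < 0.2,
          hlaI_hyperexpression = grp %in% c("T1D", "AAb_multi") && runif(1) < 0.3,
          pancreas_weight_g = 70 * (1 - exp(-age / 8)) *
            (if (grp == "T1D") 0.75 else 1) * rlnorm(1, 0, 0.1) + 5)
      }
    }
    structure(list(sections = sections,
                   donors = do.call(rbind, donors),
                   profiles = profiles),
              class = "eo_cohort")
  })
}

#' Ground-truth EO table of a sampled section spec
#'
#' Expands a [section_spec()] into the object table its rendering would
#' yield (areas equal to the specified target areas), so cohort-scale
#' simulations can bypass rasterization.
#'
#' @param spec A `section_spec`.
#' @return Data frame with `object_id`, `area_um2`, `ins_area_um2`,
#'   `gluc_area_um2`, centroid in microns.
#' @export
spec_eo_table <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  n <- length(spec$eo_specs)
  if (n == 0L)
    return(data.frame(object_id = character(0), area_um2 = numeric(0),
                      ins_area_um2 = numeric(0), gluc_area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0)))
  mpp <- spec$microns_per_px
  do.call(rbind, lapply(seq_len(n), function(i) {
    e <- spec$eo_specs[[i]]
    data.frame(object_id = sprintf("eo_%04d", i),
               area_um2 = e$target_area,
               ins_area_um2 = e$ins_fraction * e$target_area,
               gluc_area_um2 = e$gluc_fraction * e$target_area,
               centroid_x_um = e$center[1] * mpp,
               centroid_y_um = e$center[2] * mpp)
  }))
}

#' Section profiles for a sampled cohort
#'
#' Runs the table-level EO pipeline (positivity filter, classification,
#' binning) on every section of a sampled cohort and wraps the results as
#' [section_profile()]s ready for donor-level aggregation.
#'
#' @param cohort An `eo_cohort` from [sample_cohort()].
#' @return List of `section_profile` objects.
#' @export
cohort_section_profiles <- function(cohort) {
  stopifnot(inherits(cohort, "eo_cohort"))
  lapply(cohort$sections, function(sp) {
    section_profile(spec_eo_table(sp),
                    tissue_area_mm2 = attr(sp, "tissue_area_mm2"),
                    section_id = attr(sp, "section_id"),
                    donor_id = attr(sp, "donor_id"),
                    region = attr(sp, "region"))
  })
}
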