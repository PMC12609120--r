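#' Assign an endocrine object to its log2 size bin
#'
#' The EO bin is `floor(log2(area / 170))`: the object's area in square
#' microns is divided by 170 um^2 (the approximate area of one endocrine
#' cell) and log2-transformed, and the result is rounded down.  Bin 0 thus
#' covers 170-340 um^2 (roughly 1-2 cells), each subsequent bin doubling the
#' area range; bin 6 starts at 10,880 um^2, approximately one islet
#' equivalent.  Bins above `max_bin` are clamped with a warning, matching
#' the 0-9 reporting range.
#'
#' @param area_um2 Numeric vector of object areas in square microns; all
#'   values must be >= 170 (smaller objects should have been filtered out).
#' @param max_bin Largest reported bin (default 9).
#' @return Integer vector of bins.
#' @export
#' @examples
#' assign_bin(c(170, 680, 10880))  # 0, 2, 6
assign_bin <- function(area_um2, max_bin = 9L) {
  area_um2 <- as.numeric(area_um2)
  if (any(!is.finite(area_um2))) stop("non-finite area")
  if (any(area_um2 < 170))
    stop("area below the 170 um^2 minimum object size: ",
         paste(head(area_um2[area_um2 < 170], 3), collapse = ", "))
  b <- as.integer(floor(log2(area_um2 / 170)))
  if (any(b > max_bin)) {
    warning(sum(b > max_bin), " object(s) above bin ", max_bin,
            " clamped for reporting")
    b[b > max_bin] <- as.integer(max_bin)
  }
  b
}

#' Size class of an EO bin
#'
#' Bins 0-3 are small EOs (single cells and small clusters), 4-6 medium,
#' 7-9 (and any clamped larger bin) large.
#'
#' @param bin Integer vector of EO bins.
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
eo_size_class <- function(bin) {
  cls <- cut(as.numeric(bin), breaks = c(-0.5, 3.5, 6.5, Inf),
             labels = c("small", "medium", "large"))
  cls
}

#' Detect candidate endocrine objects from stain masks
#'
#' Connected components (8-connectivity by default) of the union of the
#' hormone-positive masks.  Components smaller than `min_area_um2` (default
#' 170 um^2, the approximate size of a single endocrine cell) are discarded.
#' Per-component insulin and glucagon areas are read from the respective
#' masks.  Objects touching the image border are retained but flagged.
#'
#' @param masks A `stain_mask_set` from [assign_pixels()] (needs logical
#'   `ins` and `gluc` matrices and `microns_per_px`).
#' @param min_area_um2 Minimum object area in square microns.
#' @param connectivity 8 (default) or 4.
#' @param compute_morphology If `TRUE`, trace each object's boundary polygon
#'   and attach circularity, solidity, and Feret diameters.
#' @return Data frame of candidates: `object_id`, `area_um2`, `ins_area_um2`,
#'   `gluc_area_um2`, centroid and bbox in microns, `on_border`, and (if
#'   requested) morphology columns plus a `polygon` list column (boundary
#'   rings in microns).
#' @export
detect_eos <- function(masks, min_area_um2 = 170, connectivity = 8,
                       compute_morphology = TRUE) {
  stopifnot(is.list(masks), !is.null(masks$ins), !is.null(masks$gluc))
  mpp <- masks$microns_per_px
  ins <- masks$ins; gluc <- masks$gluc
  union <- ins | gluc
  lab <- label_components(union, connectivity = connectivity)
  nlab <- max(lab)
  empty <- data.frame(object_id = character(0), area_um2 = numeric(0),
                      ins_area_um2 = numeric(0), gluc_area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      bbox_x0_um = numeric(0), bbox_y0_um = numeric(0),
                      bbox_x1_um = numeric(0), bbox_y1_um = numeric(0),
                      on_border = logical(0))
  if (nlab == 0L) return(empty)
  nr <- nrow(union)
  fg <- which(lab > 0L)
  lv <- lab[fg]
  npx <- tabulate(lv, nlab)
  ins_px <- tabulate(lv[ins[fg]], nlab)
  gluc_px <- tabulate(lv[gluc[fg]], nlab)
  keep <- which(npx * mpp^2 >= min_area_um2)
  if (!length(keep)) return(empty)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  res <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    sel <- lv == k
    r <- rows[sel]; cc <- cols[sel]
    rec <- data.frame(
      object_id = sprintf("eo_%04d", i),
      area_um2 = npx[k] * mpp^2,
      ins_area_um2 = ins_px[k] * mpp^2,
      gluc_area_um2 = gluc_px[k] * mpp^2,
      centroid_x_um = mean(cc - 0.5) * mpp,
      centroid_y_um = mean(r - 0.5) * mpp,
      bbox_x0_um = (min(cc) - 1) * mpp,
      bbox_y0_um = (min(r) - 1) * mpp,
      bbox_x1_um = max(cc) * mpp,
      bbox_y1_um = max(r) * mpp,
      on_border = any(r == 1L | r == nrow(union) | cc == 1L | cc == ncol(union)))
    if (compute_morphology) {
      loops <- trace_boundary(r, cc)
      outer <- loops[[1]] * mpp
      mo <- morphology(outer, validate = FALSE)
      # area from pixel counts is authoritative; the polygon supplies shape
      rec$circularity <- 4 * pi * rec$area_um2 / mo$perimeter^2
      hull <- outer[chull(outer[, 1], outer[, 2]), , drop = FALSE]
      rec$solidity <- rec$area_um2 / abs(polygon_area(hull))
      rec$feret_max_um <- mo$feret_max
      rec$feret_min_um <- mo$feret_min
      rec$equivalent_diameter_um <- 2 * sqrt(rec$area_um2 / pi)
      rec$polygon <- I(list(outer))
    }
    res[[i]] <- rec
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter candidate EOs by hormone positivity
#'
#' An object is retained iff its insulin- or glucagon-labeled area exceeds
#' `positivity_um2` (strictly greater than 40 um^2 by default); objects
#' below the threshold for both hormones are treated as staining artifacts
#' and excluded.  Per-hormone positivity flags (`ins_pos`, `gluc_pos`) are
#' attached using the same threshold.
#'
#' @param candidates Data frame with `ins_area_um2` and `gluc_area_um2`.
#' @param positivity_um2 Labeled-area threshold in square microns.
#' @return The retained rows with `ins_pos`/`gluc_pos` columns; the number
#'   of excluded candidates is attached as attribute `n_excluded`.
#' @export
filter_by_positivity <- function(candidates, positivity_um2 = 40) {
  stopifnot(all(c("ins_area_um2", "gluc_area_um2") %in% names(candidates)))
  ins_pos <- candidates$ins_area_um2 > positivity_um2
  gluc_pos <- candidates$gluc_area_um2 > positivity_um2
  keep <- ins_pos | gluc_pos
  out <- candidates[keep, , drop = FALSE]
  out$ins_pos <- ins_pos[keep]
  out$gluc_pos <- gluc_pos[keep]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Classify retained EOs by hormone content
#'
#' Maps the two positivity flags to the exhaustive three-class partition
#' Ins+Gluc- (`InsOnly`), Ins+Gluc+ (`InsGluc`), Ins-Gluc+ (`GlucOnly`).
#' Objects positive for neither hormone cannot occur after
#' [filter_by_positivity()]; encountering one raises an internal-consistency
#' error.
#'
#' @param ins_pos,gluc_pos Logical vectors of per-hormone positivity.
#' @return Factor with levels `InsOnly`, `InsGluc`, `GlucOnly`.
#' @export
classify_content <- function(ins_pos, gluc_pos) {
  stopifnot(length(ins_pos) == length(gluc_pos))
  if (any(!ins_pos & !gluc_pos))
    stop("object positive for neither hormone reached classification; ",
         "run filter_by_positivity() first")
  cls <- ifelse(ins_pos & !gluc_pos, "InsOnly",
                ifelse(ins_pos & gluc_pos, "InsGluc", "GlucOnly"))
  factor(cls, levels = eo_content_levels())
}

#' Run the post-detection EO pipeline on an object table
#'
#' Applies, in order: the 40 um^2 positivity filter, hormone-content
#' classification, log2 size binning, and size-class grouping.  Accepts any
#' table carrying `area_um2`, `ins_area_um2`, and `gluc_area_um2`, so
#' area-quantification outputs can enter the pipeline without images.
#'
#' @param eo_table Data frame of candidate objects.
#' @param positivity_um2 Per-hormone positivity threshold (um^2).
#' @param max_bin Largest reported bin.
#' @return The retained objects with `ins_pos`, `gluc_pos`, `content_class`,
#'   `eo_bin`, and `size_class` columns.
#' @export
process_eo_table <- function(eo_table, positivity_um2 = 40, max_bin = 9L) {
  out <- filter_by_positivity(eo_table, positivity_um2 = positivity_um2)
  if (nrow(out)) {
    out$content_class <- classify_content(out$ins_pos, out$gluc_pos)
    out$eo_bin <- assign_bin(out$area_um2, max_bin = max_bin)
    out$size_class <- eo_size_class(out$eo_bin)
  } else {
    out$content_class <- factor(character(0), levels = eo_content_levels())
    out$eo_bin <- integer(0)
    out$size_class <- eo_size_class(integer(0))
  }
  attr(out, "n_excluded") <- attr(eo_table, "n_excluded") %||%
    attr(out, "n_excluded")
  out
}
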