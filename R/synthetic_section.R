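#' Specify one synthetic endocrine object
#'
#' @param center Numeric length-2: blob center (x, y) in pixels.
#' @param target_area Target object area in square microns.  Objects meant
#'   to be detected should be >= 170 um^2; smaller ones are permitted as
#'   designed-to-be-filtered fixtures.
#' @param ins_fraction,gluc_fraction Fractions of the object's area labeled
#'   for insulin (DAB) and glucagon (red chromogen); must sum to <= 1.  Any
#'   remainder is endocrine but hormone-unlabeled (counterstain only).
#' @param shape_irregularity Non-negative scalar controlling departure from
#'   a circle: 0 gives near-circular blobs; larger values give elongated
#'   superellipses with low-frequency radial perturbation, emulating the
#'   lower circularity and solidity of larger islets.
#' @return An object of class `eo_spec`.
#' @export
eo_spec <- function(center, target_area, ins_fraction = 1,
                    gluc_fraction = 0, shape_irregularity = 0.15) {
  stopifnot(length(center) == 2, is.finite(target_area))
  if (target_area <= 0) stop("degenerate eo_spec: target_area must be > 0")
  if (ins_fraction < 0 || gluc_fraction < 0 ||
      ins_fraction + gluc_fraction > 1 + 1e-9)
    stop("ins_fraction + gluc_fraction must lie in [0, 1]")
  if (shape_irregularity < 0) stop("shape_irregularity must be >= 0")
  structure(list(center = as.numeric(center),
                 target_area = as.numeric(target_area),
                 ins_fraction = ins_fraction,
                 gluc_fraction = gluc_fraction,
                 shape_irregularity = shape_irregularity),
            class = "eo_spec")
}

#' Specify a synthetic stained section
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param microns_per_px Scale in microns per pixel.  The default 0.5 um/px
#'   corresponds to a x20 slide scan.
#' @param tissue_fraction Fraction of the canvas covered by tissue (a
#'   centered rectangle); the remainder is near-white background.
#' @param eo_specs List of [eo_spec()] objects.
#' @param rng_seed Integer seed; fully determines the rendered output.
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(width_px, height_px, microns_per_px = 0.5,
                         tissue_fraction = 1, eo_specs = list(),
                         rng_seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, microns_per_px > 0,
            tissue_fraction > 0, tissue_fraction <= 1)
  eo_specs <- lapply(eo_specs, function(e) {
    if (!inherits(e, "eo_spec")) stop("eo_specs must be a list of eo_spec")
    e
  })
  total_area <- sum(vapply(eo_specs, function(e) e$target_area, 0))
  if (width_px * height_px * microns_per_px^2 < total_area)
    stop("section too small for the specified EO areas")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_px = microns_per_px,
                 tissue_fraction = tissue_fraction,
                 eo_specs = eo_specs,
                 rng_seed = as.integer(rng_seed)),
            class = "section_spec")
}

# Blob outline at unit scale: superellipse with aspect ratio and
# low-frequency radial noise, all governed by shape_irregularity.
blob_outline <- function(irregularity, n_theta = 360L) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  p <- 2 + runif(1, 0, 2) * min(irregularity, 1)
  asp <- 1 + runif(1, 0, 1) * min(irregularity, 1)
  rot <- runif(1, 0, 2 * pi)
  r <- (abs(cos(theta))^p + abs(sin(theta) * asp)^p)^(-1 / p)
  if (irregularity > 0) {
    for (k in 2:5) {
      amp <- rnorm(1, 0, 0.25 * irregularity)
      r <- r * (1 + amp * cos(k * theta + runif(1, 0, 2 * pi)))
    }
  }
  r <- pmax(r, 0.25)
  cbind(x = r * cos(theta + rot), y = r * sin(theta + rot))
}

#' Render a synthetic chromogen-stained section
#'
#' Rasterizes each specified blob (pixel-center rule), lays insulin-labeled
#' pixels in the blob core and glucagon-labeled pixels in the mantle, and
#' composes an 8-bit RGB bright-field image by Beer-Lambert mixing of the
#' stain OD vectors over a near-white background with a light hematoxylin
#' tissue tint.  The returned ground truth lists pixel-exact areas, so
#' downstream detection can be validated object by object.  Blobs that
#' touch or overlap merge into a single ground-truth object (with a
#' warning), exactly as they would for a connected-component detector.
#'
#' @param spec A [section_spec()].
#' @param stains A [stain_model()] providing the OD vectors to render with.
#' @param hematoxylin_conc Length-2: counterstain concentration on tissue
#'   and the extra concentration on endocrine pixels.
#' @param chromogen_conc Chromogen concentration on hormone-labeled pixels
#'   (OD units along the stain vector).
#' @param noise_sd Standard deviation of additive Gaussian OD noise
#'   (default 0: noiseless rendering).
#' @return A list of class `synthetic_section`: `image` (h x w x 3 integer
#'   array, 0-255), `ground_truth` (data frame: `object_id`,
#'   `centroid_x_px`, `centroid_y_px`, bbox in px, `area_um2`,
#'   `ins_area_um2`, `gluc_area_um2`), `tissue_area_mm2`, and the `spec`.
#' @export
render_section <- function(spec, stains = stain_model(),
                           hematoxylin_conc = c(tissue = 0.2, eo = 0.1),
                           chromogen_conc = 1, noise_sd = 0) {
  stopifnot(inherits(spec, "section_spec"), inherits(stains, "stain_model"))
  h <- spec$height_px; w <- spec$width_px; mpp <- spec$microns_per_px
  with_seed(spec$rng_seed, {
    tissue <- matrix(FALSE, h, w)
    s <- sqrt(spec$tissue_fraction)
    r0 <- max(1L, floor(h * (1 - s) / 2) + 1L); r1 <- min(h, ceiling(h * (1 + s) / 2))
    c0 <- max(1L, floor(w * (1 - s) / 2) + 1L); c1 <- min(w, ceiling(w * (1 + s) / 2))
    tissue[r0:r1, c0:c1] <- TRUE

    eo_id <- matrix(0L, h, w)       # painter's id (pre-merge)
    hormone <- matrix(0L, h, w)     # 0 none, 1 ins, 2 gluc
    for (i in seq_along(spec$eo_specs)) {
      e <- spec$eo_specs[[i]]
      out <- blob_outline(e$shape_irregularity)
      a1 <- abs(polygon_area(out))
      scale <- sqrt((e$target_area / mpp^2) / a1)
      poly <- cbind(e$center[1] + scale * out[, 1],
                    e$center[2] + scale * out[, 2])
      cc0 <- max(1L, floor(min(poly[, 1])) ); cc1 <- min(w, ceiling(max(poly[, 1])) + 1L)
      rr0 <- max(1L, floor(min(poly[, 2])) ); rr1 <- min(h, ceiling(max(poly[, 2])) + 1L)
      if (cc1 < cc0 || rr1 < rr0) stop("EO ", i, " lies outside the canvas")
      cc <- rep(cc0:cc1, each = rr1 - rr0 + 1L)
      rr <- rep(rr0:rr1, times = cc1 - cc0 + 1L)
      inb <- point_in_polygon(cc - 0.5, rr - 0.5, poly[, 1], poly[, 2])
      if (!any(inb)) stop("degenerate eo_spec ", i, ": rasterized to zero pixels")
      idx <- (cc[inb] - 1L) * h + rr[inb]
      # core/mantle hormone layout: innermost fraction insulin, then glucagon
      d2 <- (cc[inb] - 0.5 - e$center[1])^2 + (rr[inb] - 0.5 - e$center[2])^2
      ord <- order(d2)
      n <- length(idx)
      n_ins <- round(e$ins_fraction * n)
      n_gluc <- min(n - n_ins, round(e$gluc_fraction * n))
      hz <- integer(n)
      if (n_ins > 0) hz[ord[seq_len(n_ins)]] <- 1L
      if (n_gluc > 0) hz[ord[n_ins + seq_len(n_gluc)]] <- 2L
      eo_id[idx] <- i
      hormone[idx] <- hz
      tissue[idx] <- TRUE
    }

    eo_mask <- eo_id > 0L
    lab <- label_components(eo_mask, connectivity = 8)
    n_obj <- max(lab)
    if (n_obj < length(spec$eo_specs) && length(spec$eo_specs) > 0)
      warning("overlapping or touching EO specs merged: ",
              length(spec$eo_specs), " specs -> ", n_obj,
              " objects; ground truth recomputed on merged components")
    gt <- data.frame(object_id = character(0), centroid_x_px = numeric(0),
                     centroid_y_px = numeric(0), bbox_x0 = numeric(0),
                     bbox_y0 = numeric(0), bbox_x1 = numeric(0),
                     bbox_y1 = numeric(0), area_um2 = numeric(0),
                     ins_area_um2 = numeric(0), gluc_area_um2 = numeric(0))
    if (n_obj > 0L) {
      fg <- which(lab > 0L)
      lv <- lab[fg]
      rows <- ((fg - 1L) %% h) + 1L
      cols <- ((fg - 1L) %/% h) + 1L
      hz <- hormone[fg]
      gt <- do.call(rbind, lapply(seq_len(n_obj), function(k) {
        sel <- lv == k
        data.frame(
          object_id = sprintf("gt_%04d", k),
          centroid_x_px = mean(cols[sel] - 0.5),
          centroid_y_px = mean(rows[sel] - 0.5),
          bbox_x0 = min(cols[sel]) - 1, bbox_y0 = min(rows[sel]) - 1,
          bbox_x1 = max(cols[sel]), bbox_y1 = max(rows[sel]),
          area_um2 = sum(sel) * mpp^2,
          ins_area_um2 = sum(sel & hz == 1L) * mpp^2,
          gluc_area_um2 = sum(sel & hz == 2L) * mpp^2)
      }))
      rownames(gt) <- NULL
    }

    # compose image in OD space, then invert to intensities
    conc_h <- hematoxylin_conc[[1]] * tissue + hematoxylin_conc[[2]] * eo_mask
    conc_i <- chromogen_conc * (hormone == 1L)
    conc_g <- chromogen_conc * (hormone == 2L)
    v <- stains$vectors
    I0 <- stains$background_intensity
    img <- array(0L, dim = c(h, w, 3))
    for (ch in 1:3) {
      od <- conc_h * v["hematoxylin", ch] + conc_i * v["ins", ch] +
        conc_g * v["gluc", ch]
      if (noise_sd > 0) od <- pmax(0, od + rnorm(h * w, 0, noise_sd))
      img[, , ch] <- as.integer(pmin(pmax(round(I0[ch] * 10^(-od)), 0), I0[ch]))
    }

    structure(list(image = img, ground_truth = gt,
                   tissue_area_mm2 = sum(tissue) * mpp^2 / 1e6,
                   spec = spec),
              class = "synthetic_section")
  })
}
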