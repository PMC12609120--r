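#' Convert an RGB image to optical density
#'
#' Beer-Lambert inversion: `OD = -log10((I + eps) / I0)` per channel, where
#' `I0` is the unstained background intensity.  Stain amounts mix additively
#' in OD space, which is what makes linear deconvolution possible.
#'
#' @param image Numeric array `h x w x 3` of intensities in `[0, I0]`.
#' @param background_intensity Length-3 positive RGB background intensity I0.
#' @param eps Small stabilizer added to intensities before the log, in
#'   intensity units.  The default of 1 shifts OD by < 0.003 at 8-bit depth
#'   while avoiding `log(0)` at fully absorbed pixels.
#' @return Numeric array `h x w x 3` of non-negative optical densities.
#' @export
#' @examples
#' img <- array(255, dim = c(2, 2, 3))
#' range(to_optical_density(img))  # background pixels have OD ~ 0
to_optical_density <- function(image, background_intensity = c(255, 255, 255),
                               eps = 1) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an h x w x 3 array")
  I0 <- as.numeric(background_intensity)
  if (length(I0) != 3L || any(!is.finite(I0)) || any(I0 == 0))
    stop("background_intensity must be 3 nonzero finite values")
  od <- image
  for (ch in 1:3) od[, , ch] <- -log10((image[, , ch] + eps) / I0[ch])
  od[od < 0] <- 0
  od
}

#' Assign pixels to stains by maximal OD projection
#'
#' Each pixel whose OD vector magnitude exceeds the model's floor is assigned
#' winner-take-all to the stain vector with the maximal projection (dot
#' product with the unit stain vector).  A pixel counts as positive for a
#' chromogen only if it is assigned to that chromogen *and* its projection
#' exceeds that stain's OD threshold.  Ties are broken toward hematoxylin,
#' the conservative choice.  Where two chromogens overlap strongly only the
#' stronger one is counted, which under-counts dual hormone-positive pixels;
#' this is an inherent limit of winner-take-all chromogen deconvolution.
#'
#' @param od_image Numeric `h x w x 3` OD array from [to_optical_density()].
#' @param model A [stain_model()].
#' @param microns_per_px Image scale in microns per pixel, carried on the
#'   returned masks.
#' @return An object of class `stain_mask_set`: a list with one logical
#'   `h x w` mask per stain (mutually exclusive), plus `assigned` (integer
#'   stain index per pixel, 0 = unstained) and `microns_per_px`.
#' @export
assign_pixels <- function(od_image, model, microns_per_px = 0.5) {
  stopifnot(inherits(model, "stain_model"))
  if (length(dim(od_image)) != 3L || dim(od_image)[3] != 3L)
    stop("`od_image` must be an h x w x 3 array")
  h <- dim(od_image)[1]; w <- dim(od_image)[2]
  odm <- matrix(od_image, nrow = h * w, ncol = 3L)
  proj <- odm %*% t(model$vectors)          # n x nstain
  mag <- sqrt(rowSums(odm^2))
  stained <- mag >= model$od_floor
  # winner-take-all; ties.method = "first" with hematoxylin in column 1
  # breaks exact ties toward the counterstain
  win <- max.col(proj, ties.method = "first")
  win[!stained] <- 0L
  nst <- nrow(model$vectors)
  masks <- vector("list", nst)
  names(masks) <- rownames(model$vectors)
  for (s in seq_len(nst)) {
    pos <- win == s
    if (s > 1L) pos <- pos & proj[, s] > model$od_threshold[s]
    masks[[s]] <- matrix(pos, nrow = h, ncol = w)
  }
  structure(
    c(masks, list(assigned = matrix(win, h, w),
                  microns_per_px = microns_per_px)),
    class = "stain_mask_set")
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
# Pixel centers exactly on an edge follow the half-open convention of the
# crossing test; polygon vertices are (x, y) in the same units as px/py.
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  if (n && xs[1] == xs[n] && ys[1] == ys[n]) { xs <- xs[-n]; ys <- ys[-n]; n <- n - 1L }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Quantify hormone-positive areas inside polygon annotations
#'
#' Counts chromogen-positive pixels whose centers fall inside each annotation
#' polygon (even-odd rule) and converts counts to areas with the mask scale.
#' This mirrors per-object area quantification: for every annotation it
#' reports the insulin- and glucagon-labeled areas and the total polygon
#' area, all in square microns.
#'
#' @param masks A `stain_mask_set` from [assign_pixels()] (or a compatible
#'   list with logical `ins` and `gluc` matrices and `microns_per_px`).
#' @param annotations A list of annotations; each either a 2-column matrix of
#'   polygon vertices (x, y in microns) or a list with elements `id` and
#'   `polygon` (as returned by [read_geojson_annotations()]).
#' @return Data frame with one row per annotation: `annotation_id`,
#'   `ins_area_um2`, `gluc_area_um2`, `total_area_um2`, `empty` (flag for
#'   polygons that cover no pixel center).
#' @export
quantify_areas <- function(masks, annotations) {
  stopifnot(is.list(masks), !is.null(masks$ins), !is.null(masks$gluc))
  mpp <- masks$microns_per_px
  ins <- masks$ins; gluc <- masks$gluc
  h <- nrow(ins); w <- ncol(ins)
  out <- data.frame(annotation_id = character(0), ins_area_um2 = numeric(0),
                    gluc_area_um2 = numeric(0), total_area_um2 = numeric(0),
                    empty = logical(0))
  for (k in seq_along(annotations)) {
    a <- annotations[[k]]
    if (is.list(a) && !is.null(a$polygon)) {
      poly <- a$polygon; id <- as.character(a$id %||% k)
    } else {
      poly <- a; id <- as.character(names(annotations)[k] %||% k)
      if (is.null(names(annotations)) || !nzchar(id)) id <- as.character(k)
    }
    poly <- as.matrix(poly)
    if (nrow(poly) < 3L) stop("annotation ", id, " has fewer than 3 vertices")
    # candidate pixels: bounding box of the polygon, in pixel indices
    c0 <- max(1L, floor(min(poly[, 1]) / mpp) + 1L)
    c1 <- min(w, ceiling(max(poly[, 1]) / mpp))
    r0 <- max(1L, floor(min(poly[, 2]) / mpp) + 1L)
    r1 <- min(h, ceiling(max(poly[, 2]) / mpp))
    if (c1 < c0 || r1 < r0) {
      out[nrow(out) + 1L, ] <- list(id, 0, 0, 0, TRUE)
      next
    }
    cc <- rep(c0:c1, each = r1 - r0 + 1L)
    rr <- rep(r0:r1, times = c1 - c0 + 1L)
    px <- (cc - 0.5) * mpp
    py <- (rr - 0.5) * mpp
    inp <- point_in_polygon(px, py, poly[, 1], poly[, 2])
    if (!any(inp)) {
      out[nrow(out) + 1L, ] <- list(id, 0, 0, 0, TRUE)
      next
    }
    idx <- (cc[inp] - 1L) * h + rr[inp]
    out[nrow(out) + 1L, ] <- list(
      id,
      sum(ins[idx]) * mpp^2,
      sum(gluc[idx]) * mpp^2,
      sum(inp) * mpp^2,
      FALSE)
  }
  out
}
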