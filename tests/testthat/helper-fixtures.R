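# Shared fixture builders for the test suite.

# A minimal stain-mask set built directly from logical matrices.
make_masks <- function(ins, gluc, mpp = 1) {
  structure(list(hematoxylin = matrix(FALSE, nrow(ins), ncol(ins)),
                 ins = ins, gluc = gluc,
                 assigned = matrix(0L, nrow(ins), ncol(ins)),
                 microns_per_px = mpp),
            class = "stain_mask_set")
}

# Logical matrix with a filled disc of radius r (pixels) centered at (cx, cy).
disc_mask <- function(nr, nc, cy, cx, r) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - 0.5 - cy)^2 + (cols - 0.5 - cx)^2 <= r^2
}

# Rectangle mask rows r0:r1, cols c0:c1.
rect_mask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# An EO table row builder for table-level pipeline tests.
eo_row <- function(area, ins, gluc, id = "x") {
  data.frame(object_id = id, area_um2 = area,
             ins_area_um2 = ins, gluc_area_um2 = gluc)
}

# Brute-force Feret oracle: caliper extent at 0.1 degree steps.
feret_bruteforce <- function(points, step_deg = 0.1) {
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(ang, function(a) {
    p <- points[, 1] * cos(a) + points[, 2] * sin(a)
    diff(range(p))
  }, 0)
  c(feret_max = max(widths), feret_min = min(widths))
}

# Regular n-gon of unit radius.
ngon <- function(n, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}
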