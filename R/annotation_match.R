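#' Match two annotation sets for the same section
#'
#' Reconciles object tables produced by two analysis platforms on the same
#' section.  Candidate pairs are scored by the sum distance of their
#' centroids and their four bounding-box corner coordinates (equal
#' weights), and matched greedily in ascending score order, one-to-one,
#' under a maximum-score gate.  Matched pairs whose EO bins differ by more
#' than `bin_diff_max` (default 1) are rejected as cross-platform
#' disagreements.  The coefficient of determination of `area_B` regressed
#' on `area_A` is reported before and after the bin-difference filter.
#'
#' @param a,b Data frames with columns `object_id`, `centroid_x_um`,
#'   `centroid_y_um`, `bbox_x0_um`, `bbox_y0_um`, `bbox_x1_um`,
#'   `bbox_y1_um`, `area_um2`, in the same coordinate frame and units.
#' @param max_score Maximum admissible score for a pair; default is twice
#'   the 95th percentile of nearest-neighbor centroid distances from `a`
#'   to `b`.
#' @param bin_diff_max Maximum tolerated |bin difference| for a retained
#'   pair.
#' @return An object of class `match_result`: `pairs` (matched pairs with
#'   scores, bins, and a `retained` flag), `r_squared_before`,
#'   `r_squared_after`, `n_matched`, `n_rejected`, `unmatched_a`,
#'   `unmatched_b`.
#' @export
match_annotations <- function(a, b, max_score = NULL, bin_diff_max = 1) {
  need <- c("object_id", "centroid_x_um", "centroid_y_um", "bbox_x0_um",
            "bbox_y0_um", "bbox_x1_um", "bbox_y1_um", "area_um2")
  for (nm in need) {
    if (!nm %in% names(a)) stop("set A lacks column ", nm)
    if (!nm %in% names(b)) stop("set B lacks column ", nm)
  }
  na <- nrow(a); nb <- nrow(b)
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), bin_a = integer(0),
                      bin_b = integer(0), retained = logical(0))
  if (na == 0L || nb == 0L)
    return(structure(list(pairs = empty, r_squared_before = NA_real_,
                          r_squared_after = NA_real_, n_matched = 0L,
                          n_rejected = 0L, unmatched_a = a$object_id,
                          unmatched_b = b$object_id),
                     class = "match_result"))
  cd <- sqrt(outer(a$centroid_x_um, b$centroid_x_um, "-")^2 +
             outer(a$centroid_y_um, b$centroid_y_um, "-")^2)
  score <- cd +
    abs(outer(a$bbox_x0_um, b$bbox_x0_um, "-")) +
    abs(outer(a$bbox_y0_um, b$bbox_y0_um, "-")) +
    abs(outer(a$bbox_x1_um, b$bbox_x1_um, "-")) +
    abs(outer(a$bbox_y1_um, b$bbox_y1_um, "-"))
  if (is.null(max_score)) {
    nn <- apply(cd, 1, min)
    max_score <- 2 * quantile(nn, 0.95) + sqrt(.Machine$double.eps)
  }
  ord <- order(score, rep(seq_len(na), nb), rep(seq_len(nb), each = na))
  used_a <- logical(na); used_b <- logical(nb)
  ia <- ((ord - 1L) %% na) + 1L
  ib <- ((ord - 1L) %/% na) + 1L
  sel_a <- integer(0); sel_b <- integer(0); sel_s <- numeric(0)
  for (k in seq_along(ord)) {
    if (score[ord[k]] > max_score) break
    i <- ia[k]; j <- ib[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    sel_a <- c(sel_a, i); sel_b <- c(sel_b, j); sel_s <- c(sel_s, score[ord[k]])
  }
  if (!length(sel_a))
    return(structure(list(pairs = empty, r_squared_before = NA_real_,
                          r_squared_after = NA_real_, n_matched = 0L,
                          n_rejected = 0L, unmatched_a = a$object_id,
                          unmatched_b = b$object_id),
                     class = "match_result"))
  area_a <- a$area_um2[sel_a]; area_b <- b$area_um2[sel_b]
  ratio <- median(area_b / area_a)
  if (!is.finite(ratio) || ratio < 0.25 || ratio > 4)
    warning("gross area-scale disagreement between sets (median ratio ",
            signif(ratio, 3), "); check units")
  bin_a <- suppressWarnings(assign_bin(pmax(area_a, 170)))
  bin_b <- suppressWarnings(assign_bin(pmax(area_b, 170)))
  retained <- abs(bin_a - bin_b) <= bin_diff_max
  r2 <- function(x, y) {
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(1)
    # identical sets give an exact fit; the perfect-fit warning is expected
    suppressWarnings(summary(lm(y ~ x))$r.squared)
  }
  pairs_df <- data.frame(id_a = a$object_id[sel_a], id_b = b$object_id[sel_b],
                         score = sel_s, area_a = area_a, area_b = area_b,
                         bin_a = bin_a, bin_b = bin_b, retained = retained)
  pairs_df <- pairs_df[order(pairs_df$score, pairs_df$id_a), ]
  rownames(pairs_df) <- NULL
  structure(list(pairs = pairs_df,
                 r_squared_before = r2(area_a, area_b),
                 r_squared_after = r2(area_a[retained], area_b[retained]),
                 n_matched = length(sel_a),
                 n_rejected = sum(!retained),
                 unmatched_a = a$object_id[!used_a],
                 unmatched_b = b$object_id[!used_b]),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Annotation match:", x$n_matched, "pairs,", x$n_rejected,
      "rejected by bin-difference filter\n")
  cat("R^2 before:", signif(x$r_squared_before, 6),
      "| after:", signif(x$r_squared_after, 6), "\n")
  invisible(x)
}
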