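#' Default stain optical-density vectors
#'
#' RGB optical-density unit vectors for the three stains used on
#' insulin/glucagon dual-labeled pancreas sections: hematoxylin counterstain,
#' DAB (insulin chromogen), and a red AP chromogen (glucagon).  The
#' hematoxylin and DAB vectors are the widely used Ruifrok & Johnston values;
#' the red-chromogen vector is the Fiji "Fast Red" vector, shipped as a
#' documented, overridable stand-in for Warp Red, whose published OD vector
#' is not standardized.
#'
#' @return A 3 x 3 numeric matrix; rows `hematoxylin`, `ins`, `gluc`, columns
#'   R, G, B.  Rows are unit vectors in OD space.
#' @export
#' @examples
#' default_stain_vectors()
default_stain_vectors <- function() {
  v <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    ins         = c(0.269, 0.568, 0.778),  # DAB
    gluc        = c(0.214, 0.851, 0.478)   # Fast Red stand-in for Warp Red
  )
  colnames(v) <- c("R", "G", "B")
  v / sqrt(rowSums(v^2))
}

#' Construct a stain model for color deconvolution
#'
#' A stain model bundles the RGB optical-density vectors of the hematoxylin
#' counterstain and up to two chromogens, the per-stain OD positivity
#' thresholds, and the background (unstained, bright-field) intensity.
#'
#' @param vectors Numeric matrix with 2 or 3 rows (stains) and 3 columns
#'   (R, G, B OD components).  Rows are normalized to unit length; the first
#'   row is treated as the hematoxylin counterstain.
#' @param od_threshold Numeric vector of per-stain positive-staining
#'   thresholds in OD units (recycled to the number of stains).
#' @param background_intensity Length-3 positive RGB intensity of unstained
#'   background (I0), on the scale of the images to be analyzed.
#' @param od_floor Minimum OD vector magnitude for a pixel to be considered
#'   stained at all; pixels below it stay unassigned.
#' @return An object of class `stain_model`.
#' @export
#' @examples
#' m <- stain_model()
#' m$vectors
stain_model <- function(vectors = default_stain_vectors(),
                        od_threshold = 0.15,
                        background_intensity = c(255, 255, 255),
                        od_floor = 0.05) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L || nrow(vectors) < 2L || nrow(vectors) > 3L)
    stop("`vectors` must be a 2- or 3-row matrix of RGB OD components")
  if (any(!is.finite(vectors)) || any(vectors < 0))
    stop("stain OD vectors must be finite and non-negative")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length stain vector")
  vectors <- vectors / nrm
  if (is.null(rownames(vectors)))
    rownames(vectors) <- c("hematoxylin", "ins", "gluc")[seq_len(nrow(vectors))]
  # pairwise non-collinearity
  g <- vectors %*% t(vectors)
  off <- g[upper.tri(g)]
  if (any(abs(off) > 0.999))
    stop("stain vectors must be pairwise non-collinear")
  od_threshold <- rep_len(as.numeric(od_threshold), nrow(vectors))
  if (any(od_threshold < 0)) stop("od_threshold must be >= 0")
  background_intensity <- as.numeric(background_intensity)
  if (length(background_intensity) != 3L || any(background_intensity <= 0))
    stop("background_intensity must be 3 positive values")
  structure(
    list(vectors = vectors,
         od_threshold = stats::setNames(od_threshold, rownames(vectors)),
         background_intensity = background_intensity,
         od_floor = od_floor),
    class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("Stain model (", nrow(x$vectors), " stains)\n", sep = "")
  print(round(x$vectors, 3))
  cat("OD thresholds:", paste(names(x$od_threshold),
                              round(x$od_threshold, 3), collapse = ", "), "\n")
  cat("Background I0:", paste(x$background_intensity, collapse = ","),
      " | OD floor:", x$od_floor, "\n")
  invisible(x)
}
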