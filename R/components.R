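#' Label connected components of a binary mask
#'
#' Connected-component labeling with 8-connectivity (default) or
#' 4-connectivity.  8-connectivity treats diagonally touching pixels as
#' contiguous, matching the visual contiguity of compact chromogen blobs.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 for background, components
#'   numbered from 1.
#' @export
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
#' max(label_components(m, 8))  # diagonal touch: one component
#' max(label_components(m, 4))  # two components
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  cl <- ((fg - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    rr <- r + o[1]; cc <- cl + o[2]
    ok <- rr >= 1L & rr <= nr & cc <= nc        # cc >= 1 always (offsets >= 0)
    nb <- (cc[ok] - 1L) * nr + rr[ok]
    hit <- id[nb] > 0L
    if (any(hit))
      edges <- c(edges, rbind(id[fg[ok]][hit], id[nb][hit]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber in first-pixel order for determinism
  first <- tapply(seq_along(fg), memb, min)
  rk <- rank(first)
  lab[fg] <- as.integer(rk[memb])
  lab
}

# Trace the boundary loops of a set of pixels along pixel edges.
#
# Pixels are given as (row, col) indices; pixel (r, c) occupies the unit
# square x in [c-1, c], y in [r-1, r] (y downward).  Each pixel contributes
# four directed edges with a consistent orientation; edges shared by two
# pixels cancel, and the remainder are chained into closed loops.  At pinch
# vertices (diagonal touches) the walk takes the most-clockwise turn, which
# carries it through into the diagonal neighbor so the component stays one
# loop.  Returns a list of loops (closed 2-column matrices of vertex
# coordinates in pixel units) with the outer loop (largest |area|) first.
trace_boundary <- function(rows, cols) {
  n <- length(rows)
  stopifnot(n == length(cols), n >= 1L)
  # directed edges around each pixel: top ->, right v, bottom <-, left ^
  x0 <- c(cols - 1L, cols,      cols,      cols - 1L)
  y0 <- c(rows - 1L, rows - 1L, rows,      rows)
  x1 <- c(cols,      cols,      cols - 1L, cols - 1L)
  y1 <- c(rows - 1L, rows,      rows,      rows - 1L)
  S <- max(max(cols), max(rows)) + 2
  vk0 <- x0 * S + y0
  vk1 <- x1 * S + y1
  ek <- vk0 * S * S + vk1
  rk <- vk1 * S * S + vk0
  keep <- !(ek %in% rk)
  x0 <- x0[keep]; y0 <- y0[keep]; x1 <- x1[keep]; y1 <- y1[keep]
  vk0 <- vk0[keep]; vk1 <- vk1[keep]
  m <- length(x0)
  # outgoing-edge lookup by start-vertex key
  ord <- order(vk0)
  sk <- vk0[ord]
  used <- logical(m)
  loops <- list()
  areas <- numeric(0)
  for (start in seq_len(m)) {
    if (used[start]) next
    cur <- start
    vx <- numeric(0); vy <- numeric(0)
    repeat {
      used[cur] <- TRUE
      vx <- c(vx, x0[cur]); vy <- c(vy, y0[cur])
      tk <- vk1[cur]
      if (tk == vk0[start] && length(vx) > 1L) break
      lo <- findInterval(tk - 0.5, sk) + 1L
      hi <- findInterval(tk, sk)
      cand <- if (hi >= lo) ord[seq.int(lo, hi)] else integer(0)
      cand <- cand[!used[cand]]
      if (!length(cand)) {
        if (tk == vk0[start]) break
        stop("boundary tracing failed: open chain")   # should not happen
      }
      if (length(cand) > 1L) {
        # pinch vertex: prefer the most clockwise turn
        dx <- x1[cur] - x0[cur]; dy <- y1[cur] - y0[cur]
        cr <- dx * (y1[cand] - y0[cand]) - dy * (x1[cand] - x0[cand])
        cand <- cand[which.min(cr)]
      }
      cur <- cand[1L]
      if (cur == start) break
    }
    vx <- c(vx, vx[1]); vy <- c(vy, vy[1])
    loops[[length(loops) + 1L]] <- cbind(x = vx, y = vy)
    areas <- c(areas, abs(polygon_area(cbind(vx, vy))))
  }
  loops[order(areas, decreasing = TRUE)]
}
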