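#' Extract the closed boundary contour of a 2D mask
#'
#' Traces the boundary of the union of unit pixel squares as an ordered,
#' closed, axis-aligned polygon in mm coordinates (pixel centres at integer
#' coordinates, so vertices lie at half-integers). Because the polygon
#' follows the pixel edges exactly, its shoelace area equals the mask's voxel
#' count; collinear runs are collapsed, so a filled w x h rectangle yields a
#' 4-corner polygon and a single voxel yields a unit square.
#'
#' @param mask logical (or 0/1) matrix; must be non-empty and a single
#'   4-connected component.
#' @return A numeric matrix with columns `x_mm`, `y_mm` (columns and rows of
#'   the mask respectively), vertices ordered counter-clockwise; the first
#'   vertex is not repeated at the end.
#' @export
extract_contour <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  if (!any(m)) stopf("empty mask: no contour to extract")
  if (max(EBImage::bwlabel(m)) > 1L)
    stopf("mask has multiple connected components")
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  inner <- pad[2:(ny + 1L), 2:(nx + 1L)]
  idx <- which(inner)
  i <- ((idx - 1L) %% ny) + 1L   # row = y
  j <- ((idx - 1L) %/% ny) + 1L  # col = x
  # boundary edges, directed with the interior on the left; coordinates are
  # doubled so corner positions are exact integers
  up    <- !pad[cbind(i, j + 1L)]       # neighbour at i-1 (y-1)
  down  <- !pad[cbind(i + 2L, j + 1L)]  # neighbour at i+1
  left  <- !pad[cbind(i + 1L, j)]       # neighbour at j-1 (x-1)
  right <- !pad[cbind(i + 1L, j + 2L)]  # neighbour at j+1
  x2 <- 2L * j; y2 <- 2L * i
  e <- rbind(
    cbind(x2[up] - 1L, y2[up] - 1L, x2[up] + 1L, y2[up] - 1L),        # +x
    cbind(x2[right] + 1L, y2[right] - 1L, x2[right] + 1L, y2[right] + 1L), # +y
    cbind(x2[down] + 1L, y2[down] + 1L, x2[down] - 1L, y2[down] + 1L),    # -x
    cbind(x2[left] - 1L, y2[left] + 1L, x2[left] - 1L, y2[left] - 1L))    # -y
  nE <- nrow(e)
  dir <- c(rep(0L, sum(up)), rep(1L, sum(right)), rep(2L, sum(down)),
           rep(3L, sum(left)))  # 0:+x 1:+y 2:-x 3:-y
  key <- function(x, y) paste(x, y)
  out_map <- split(seq_len(nE), key(e[, 1], e[, 2]))
  used <- logical(nE)
  loops <- list()
  for (start in seq_len(nE)) {
    if (used[start]) next
    cur <- start
    verts_x <- integer(0); verts_y <- integer(0)
    repeat {
      used[cur] <- TRUE
      verts_x <- c(verts_x, e[cur, 1]); verts_y <- c(verts_y, e[cur, 2])
      nxt <- out_map[[key(e[cur, 3], e[cur, 4])]]
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      if (length(nxt) > 1L) {
        # pinch corner: prefer the left-most turn so the outer boundary
        # stays one loop
        turn <- (dir[nxt] - dir[cur]) %% 4L  # 1 = left, 0 = straight, 3 = right
        pref <- order(match(turn, c(1L, 0L, 3L)))
        nxt <- nxt[pref]
      }
      cur <- nxt[1]
    }
    loops[[length(loops) + 1L]] <- cbind(verts_x, verts_y) / 2
  }
  area <- vapply(loops, polygon_area, numeric(1))
  poly <- loops[[which.max(abs(area))]]
  # collapse collinear runs
  n <- nrow(poly)
  if (n > 2) {
    prev <- rbind(poly[n, ], poly[-n, ])
    nxt <- rbind(poly[-1, ], poly[1, ])
    keep <- (nxt[, 1] - prev[, 1]) * (poly[, 2] - prev[, 2]) !=
      (poly[, 1] - prev[, 1]) * (nxt[, 2] - prev[, 2])
    poly <- poly[keep, , drop = FALSE]
  }
  colnames(poly) <- c("x_mm", "y_mm")
  poly
}

#' Shoelace area of a closed polygon
#'
#' @param poly two-column vertex matrix (closing edge implied).
#' @return Signed area (positive for counter-clockwise orientation).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}
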