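# Polygon geometry helpers (vertices as n x 2 matrix, implicit closure) ----

shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_perimeter <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Proper crossing test between segments p1-p2 and p3-p4 (shared endpoints
# of adjacent polygon edges are not crossings).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex), incl. the (1, n) wrap pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' FAZ boundary trace
#'
#' Represents a manually traced foveal avascular zone boundary as an ordered
#' closed polygon in pixel coordinates (the closing edge back to the first
#' vertex is implicit), with the physical pixel pitch.
#'
#' @param polygon Numeric n x 2 matrix (or data frame) of `(x, y)` vertices,
#'   0-based pixel-center coordinates, n >= 3. Must be a simple
#'   (non-self-intersecting) polygon.
#' @param pixel_pitch mm per pixel.
#' @param check Verify simplicity (O(n^2); disable for very long traces you
#'   already trust).
#' @return Object of class `faz_trace`.
#' @export
faz_trace <- function(polygon, pixel_pitch, check = TRUE) {
  xy <- as.matrix(polygon)[, 1:2, drop = FALSE]
  storage.mode(xy) <- "double"
  if (nrow(xy) >= 2L && all(xy[1, ] == xy[nrow(xy), ])) {
    xy <- xy[-nrow(xy), , drop = FALSE]  # drop explicit closure
  }
  if (nrow(xy) < 3L) stop("a FAZ trace needs at least 3 vertices")
  if (anyNA(xy)) stop("FAZ trace contains missing coordinates")
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive")
  if (check && !polygon_is_simple(xy)) {
    stop("FAZ trace polygon is self-intersecting")
  }
  structure(list(polygon = xy, pixel_pitch = pixel_pitch), class = "faz_trace")
}

#' Read a FAZ boundary polygon CSV
#'
#' @param path CSV with header `x_px,y_px`, one vertex per row, implicit
#'   closure.
#' @param pixel_pitch mm per pixel.
#' @return A [faz_trace].
#' @export
read_faz_trace <- function(path, pixel_pitch) {
  if (!file.exists(path)) stop("FAZ polygon file not found: ", path)
  dat <- utils::read.csv(path)
  faz_trace(dat, pixel_pitch)
}

#' Extract a FAZ trace from a binary FAZ mask
#'
#' Converts a pixel mask of the avascular zone to a boundary polygon by
#' marching-squares contour extraction at level 0.5, then feeds the same
#' polygon computation as a manual trace. The longest closed contour is
#' used.
#'
#' @param mask Logical (or 0/1) matrix, `TRUE` inside the FAZ.
#' @param pixel_pitch mm per pixel.
#' @return A [faz_trace].
#' @export
faz_trace_from_mask <- function(mask, pixel_pitch) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) stop("FAZ mask is empty")
  # contourLines works on z[x, y] over coordinate grids; feed rows as x so
  # that returned $x are row positions and $y column positions.
  cl <- grDevices::contourLines(x = seq_len(nrow(m)) - 1,
                                y = seq_len(ncol(m)) - 1, z = m, levels = 0.5)
  if (length(cl) == 0L) stop("no contour found in FAZ mask")
  lens <- vapply(cl, function(cc) length(cc$x), integer(1))
  cc <- cl[[which.max(lens)]]
  # cc$x follows rows (y image coord), cc$y follows columns (x image coord)
  faz_trace(cbind(x = cc$y, y = cc$x), pixel_pitch, check = FALSE)
}

#' FAZ area, perimeter and circularity
#'
#' Computes the foveal avascular zone area (shoelace formula, mm^2),
#' perimeter (sum of edge lengths including the closing edge, mm) and
#' circularity `4 * pi * Area / Perimeter^2`, which is 1 for a perfect
#' circle and decreases as the boundary becomes more irregular.
#'
#' @param trace A [faz_trace].
#' @return Object of class `faz_metrics`: list with `faza` (mm^2), `fazp`
#'   (mm), `fazc` (dimensionless, in (0, 1] up to polygonal quantization).
#' @export
faz_metrics <- function(trace) {
  if (!inherits(trace, "faz_trace")) stop("`trace` must be a faz_trace")
  p <- trace$pixel_pitch
  faza <- shoelace_area(trace$polygon) * p^2
  fazp <- polygon_perimeter(trace$polygon) * p
  if (faza <= 0 || fazp <= 0) stop("degenerate FAZ trace (zero area or perimeter)")
  structure(list(faza = faza, fazp = fazp, fazc = 4 * pi * faza / fazp^2),
            class = "faz_metrics")
}

#' @export
print.faz_metrics <- function(x, ...) {
  cat(sprintf("<faz_metrics> area %.4g mm^2, perimeter %.4g mm, circularity %.4g\n",
              x$faza, x$fazp, x$fazc))
  invisible(x)
}
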