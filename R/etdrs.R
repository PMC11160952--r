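#' Fovea-centered ETDRS sector masks
#'
#' Builds the standard ETDRS grid (central subfield diameter 1 mm, inner
#' ring 1-3 mm, outer ring 3-6 mm) in pixel space around a manually
#' annotated FAZ center. Each pixel is assigned by the Euclidean distance of
#' its center from the grid center, in mm, using half-open radial bins
#' `[0, 0.5)`, `[0.5, 1.5)`, `[1.5, 3.0]`. Coordinates are 0-based with
#' `x` = column and `y` = row.
#'
#' @param center Numeric `(x, y)` pixel coordinates of the FAZ center
#'   (0-based, pixel-center convention). Must lie inside the image.
#' @param pixel_pitch mm per pixel.
#' @param image_size Image side length in pixels.
#' @return An object of class `etdrs_grid`: list with `center`,
#'   `pixel_pitch`, `radii` (0.5, 1.5, 3.0 mm), logical sector masks
#'   `central`, `ir`, `or_`, `total`, and `clipped` (TRUE when the 6-mm disc
#'   does not fit inside the image).
#' @export
build_grid <- function(center, pixel_pitch, image_size) {
  if (length(center) != 2L || !is.numeric(center)) {
    stop("`center` must be numeric (x, y)")
  }
  x0 <- center[[1]]; y0 <- center[[2]]
  if (x0 < 0 || y0 < 0 || x0 > image_size - 1 || y0 > image_size - 1) {
    stop("grid center lies outside the image")
  }
  xs <- (seq_len(image_size) - 1) - x0   # column offsets
  ys <- (seq_len(image_size) - 1) - y0   # row offsets
  # distance in mm from the center for every pixel (rows x cols)
  d <- pixel_pitch * sqrt(outer(ys^2, xs^2, `+`))
  radii <- c(central = 0.5, inner = 1.5, outer = 3.0)
  central <- d < 0.5
  ir <- d >= 0.5 & d < 1.5
  or_ <- d >= 1.5 & d <= 3.0
  total <- d <= 3.0
  # clipped when the 6-mm disc reaches beyond the pixel-center lattice by
  # more than half a pixel (an exactly 6-mm field does not warn)
  r_px <- 3.0 / pixel_pitch
  clipped <- (x0 - r_px < -0.5) || (y0 - r_px < -0.5) ||
    (x0 + r_px > image_size - 0.5) || (y0 + r_px > image_size - 0.5)
  if (clipped) {
    warning("6-mm ETDRS disc is clipped at the image border")
  }
  structure(
    list(center = c(x = x0, y = y0), pixel_pitch = pixel_pitch,
         radii = radii, central = central, ir = ir, or_ = or_,
         total = total, clipped = clipped),
    class = "etdrs_grid"
  )
}

#' @export
print.etdrs_grid <- function(x, ...) {
  cat(sprintf("<etdrs_grid> center (%.1f, %.1f) px, pitch %.4g mm/px%s\n",
              x$center[["x"]], x$center[["y"]], x$pixel_pitch,
              if (x$clipped) " [clipped]" else ""))
  cat(sprintf("  pixels: central %d, IR %d, OR %d, total %d\n",
              sum(x$central), sum(x$ir), sum(x$or_), sum(x$total)))
  invisible(x)
}

#' Read a FAZ-center annotation
#'
#' Accepts either a single `x,y` coordinate pair or a FAZ boundary polygon
#' CSV (columns `x_px,y_px`, one vertex per row), in which case the polygon
#' centroid is returned. Coordinates are 0-based pixels.
#'
#' @param path Path to the annotation CSV.
#' @return Numeric `(x, y)`.
#' @export
read_faz_center <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  has_header <- grepl("[A-Za-z]", lines[[1]])
  dat <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         header = has_header)
  if (ncol(dat) < 2L || nrow(dat) < 1L) {
    stop("malformed annotation file: ", path)
  }
  xy <- as.matrix(dat[, 1:2])
  if (!is.numeric(xy) || anyNA(xy)) stop("malformed annotation file: ", path)
  if (nrow(xy) == 1L) {
    c(x = xy[1, 1], y = xy[1, 2])
  } else {
    cen <- polygon_centroid(xy)
    c(x = cen[[1]], y = cen[[2]])
  }
}
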