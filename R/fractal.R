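#' Box-counting fractal dimension of a binary vessel map
#'
#' Covers the image with a grid of boxes of side `s` anchored at the
#' top-left corner and counts the boxes `N(s)` containing at least one
#' foreground pixel, for `s` on a dyadic ladder `{2, 4, 8, ...}` up to a
#' quarter of the image side. The fractal dimension is the negative slope of
#' the ordinary least-squares fit of `log N(s)` against `log s`; the fit
#' uses all ladder points with no automatic linear-range selection.
#'
#' @param mask Logical/binary matrix or a `vessel_map`.
#' @param restrict Optional logical matrix; only foreground pixels inside
#'   this region are counted (e.g. the 6-mm ETDRS disc).
#' @param box_sizes Optional integer vector of box sides overriding the
#'   dyadic ladder (e.g. powers of 3 for a Sierpinski carpet fixture). At
#'   least 3 sizes are required.
#' @param offset_average Average `N(s)` over four grid anchor offsets
#'   instead of the single top-left anchoring (off by default).
#' @return Object of class `fractal_result`: list with `fd`, `box_sizes`,
#'   `counts`, `r_squared`.
#' @export
fractal_dimension <- function(mask, restrict = NULL, box_sizes = NULL,
                              offset_average = FALSE) {
  m <- if (inherits(mask, "vessel_map")) mask$mask else mask
  m <- if (is.logical(m)) m else m > 0
  if (!is.null(restrict)) {
    if (!identical(dim(restrict), dim(m))) stop("`restrict` must share the mask shape")
    m <- m & restrict
  }
  idx <- which(m)
  if (length(idx) == 0L) stop("mask is empty (after restriction)")
  nr <- nrow(m)
  size <- min(dim(m))
  if (is.null(box_sizes)) {
    box_sizes <- 2^(1:floor(log2(size / 4)))
  }
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 3L) stop("need at least 3 box sizes for the log-log fit")
  row0 <- (idx - 1L) %% nr       # 0-based pixel coordinates
  col0 <- (idx - 1L) %/% nr
  count_boxes <- function(s, dr, dc) {
    br <- (row0 + dr) %/% s
    bc <- (col0 + dc) %/% s
    length(unique(br * (max(bc) + 1) + bc))
  }
  counts <- vapply(box_sizes, function(s) {
    if (offset_average) {
      h <- s %/% 2L
      mean(c(count_boxes(s, 0L, 0L), count_boxes(s, h, 0L),
             count_boxes(s, 0L, h), count_boxes(s, h, h)))
    } else {
      count_boxes(s, 0L, 0L)
    }
  }, numeric(1))
  # OLS of log N(s) on log s on all ladder points
  lx <- log(box_sizes); ly <- log(counts)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  resid <- ly - mean(ly) - slope * (lx - mean(lx))
  ss_tot <- sum((ly - mean(ly))^2)
  structure(
    list(fd = -slope, box_sizes = box_sizes, counts = counts,
         r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1),
    class = "fractal_result"
  )
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("<fractal_result> fd %.4f (R^2 %.4f), %d box sizes [%d..%d]\n",
              x$fd, x$r_squared, length(x$box_sizes), min(x$box_sizes),
              max(x$box_sizes)))
  invisible(x)
}

#' @export
plot.fractal_result <- function(x, ...) {
  graphics::plot(log(x$box_sizes), log(x$counts),
                 xlab = "log box size", ylab = "log N(s)",
                 main = sprintf("Box-counting fit, fd = %.3f", x$fd), ...)
  graphics::abline(stats::lm(log(x$counts) ~ log(x$box_sizes)), lty = 2)
  invisible(x)
}
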