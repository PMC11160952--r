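#' Canonical oracle shapes for fractal and circularity checks
#'
#' Deterministic fixtures with closed-form properties: the Sierpinski carpet
#' (box-counting dimension log 8 / log 3), a filled disc (area pi r^2), a
#' one-pixel-wide horizontal line (dimension 1), a checkerboard (density
#' 1/2), and an axis-aligned square polygon (area a^2, perimeter 4a).
#'
#' @param name One of `"sierpinski_carpet"`, `"filled_disc"`, `"line"`,
#'   `"checkerboard"`, `"square_polygon"`.
#' @param size Side length: pixels for the grids (a power of 3 for the
#'   carpet; the disc uses radius `size / 2 - 1`), side length `a` for the
#'   square polygon.
#' @return A logical matrix for the grid fixtures, or an n x 2 vertex
#'   matrix for `square_polygon`.
#' @export
make_fixture <- function(name = c("sierpinski_carpet", "filled_disc", "line",
                                  "checkerboard", "square_polygon"),
                         size) {
  name <- match.arg(name)
  if (!is.numeric(size) || length(size) != 1L || size <= 0) {
    stop("`size` must be a positive scalar")
  }
  switch(name,
    sierpinski_carpet = {
      level <- log(size, base = 3)
      if (abs(level - round(level)) > 1e-9) {
        stop("carpet size must be a power of 3")
      }
      m <- matrix(TRUE, 1, 1)
      for (i in seq_len(round(level))) {
        n <- nrow(m)
        big <- matrix(FALSE, 3 * n, 3 * n)
        for (bi in 0:2) for (bj in 0:2) {
          if (bi == 1 && bj == 1) next
          big[bi * n + seq_len(n), bj * n + seq_len(n)] <- m
        }
        m <- big
      }
      m
    },
    filled_disc = {
      size <- as.integer(size)
      r <- size / 2 - 1
      cx <- (size - 1) / 2
      xs <- (seq_len(size) - 1) - cx
      outer(xs^2, xs^2, `+`) <= r^2
    },
    line = {
      size <- as.integer(size)
      m <- matrix(FALSE, size, size)
      m[ceiling(size / 2), ] <- TRUE
      m
    },
    checkerboard = {
      size <- as.integer(size)
      outer(seq_len(size), seq_len(size), `+`) %% 2 == 0
    },
    square_polygon = {
      cbind(x = c(0, size, size, 0), y = c(0, 0, size, size))
    }
  )
}
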