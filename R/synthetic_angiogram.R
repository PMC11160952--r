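# Synthetic en-face angiogram generator: paired eyes with known ground
# truth (capillary mesh, big arcade vessels, FAZ polygon).

# Deterministic per-stream seed derivation so fellow eyes and patients use
# disjoint, reproducible random streams from one top-level seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + stream * 1299709) %% 2147483647)
}

#' Parameters of the synthetic angiogram generator
#'
#' Defaults emulate a fovea-centered 6x6 mm scan sampled at 500x500 pixels
#' (0.012 mm/px): a capillary mesh covering about a fifth of the macular
#' disc, a few bright arcade vessels, and a mildly irregular FAZ of mean
#' radius 0.3 mm.
#'
#' @param image_size Pixels per side.
#' @param pixel_pitch mm per pixel; `image_size * pixel_pitch` must cover at
#'   least 6 mm.
#' @param capillary_fraction Target capillary coverage fraction in (0, 1),
#'   measured inside the 6-mm disc outside the FAZ and big vessels.
#' @param n_big_vessels Number of thick arcade vessel branches (may be 0).
#' @param big_vessel_width Width of the big vessels in pixels.
#' @param faz_mean_radius Mean FAZ radius in mm (< 1.5).
#' @param faz_irregularity Radial perturbation amplitude in `[0, 1)`; 0
#'   yields a near-circular FAZ (circularity ~ 1) and larger values a more
#'   irregular boundary.
#' @param vessel_intensity_mean Capillary pixel intensity (8-bit units).
#' @param background_intensity_mean Background intensity.
#' @param big_vessel_intensity Intensity of the big vessels; kept well above
#'   the capillary intensity so the high-coefficient threshold isolates
#'   them.
#' @param noise_sd Gaussian intensity noise SD (applied then clipped to
#'   `[0, 255]` and rounded to 8-bit).
#' @param left_capillary_deficit Optional planted reduction of the left
#'   eye's capillary fraction (e.g. 0.01 lowers left coverage by 1 point).
#' @param seed Integer seed; the same seed reproduces bit-identical images
#'   and ground truth.
#' @return A validated list of class `image_gen_params`.
#' @export
image_gen_params <- function(image_size = 500L, pixel_pitch = 0.012,
                             capillary_fraction = 0.22, n_big_vessels = 3L,
                             big_vessel_width = 6, faz_mean_radius = 0.3,
                             faz_irregularity = 0.2,
                             vessel_intensity_mean = 90,
                             background_intensity_mean = 10,
                             big_vessel_intensity = 255,
                             noise_sd = 10, left_capillary_deficit = 0,
                             seed = 1L) {
  if (capillary_fraction <= 0 || capillary_fraction >= 1) {
    stop("`capillary_fraction` must lie in (0, 1)")
  }
  if (faz_mean_radius >= 1.5) stop("`faz_mean_radius` must be < 1.5 mm")
  if (image_size * pixel_pitch < 6.0) {
    stop("image must cover at least 6 mm (image_size * pixel_pitch >= 6)")
  }
  if (faz_irregularity < 0 || faz_irregularity >= 1) {
    stop("`faz_irregularity` must lie in [0, 1)")
  }
  if (n_big_vessels < 0 || big_vessel_width <= 0) {
    stop("invalid big-vessel parameters")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (left_capillary_deficit < 0 || left_capillary_deficit >= capillary_fraction) {
    stop("`left_capillary_deficit` must be in [0, capillary_fraction)")
  }
  structure(
    list(image_size = as.integer(image_size), pixel_pitch = pixel_pitch,
         capillary_fraction = capillary_fraction,
         n_big_vessels = as.integer(n_big_vessels),
         big_vessel_width = big_vessel_width,
         faz_mean_radius = faz_mean_radius,
         faz_irregularity = faz_irregularity,
         vessel_intensity_mean = vessel_intensity_mean,
         background_intensity_mean = background_intensity_mean,
         big_vessel_intensity = big_vessel_intensity,
         noise_sd = noise_sd,
         left_capillary_deficit = left_capillary_deficit,
         seed = as.integer(seed)),
    class = "image_gen_params"
  )
}

# Even-odd point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# FAZ boundary: 72 radial spokes with uniformly perturbed radii smoothed by
# a circular 5-point moving average; monotone map from irregularity to
# boundary roughness (and hence to circularity).
make_faz_polygon <- function(center, radius_px, irregularity, n_spokes = 72L) {
  theta <- seq(0, 2 * pi, length.out = n_spokes + 1L)[-(n_spokes + 1L)]
  u <- stats::runif(n_spokes, -1, 1)
  r <- radius_px * (1 + irregularity * u)
  if (irregularity > 0) {
    rp <- c(r[(n_spokes - 1):n_spokes], r, r[1:2])
    r <- stats::filter(rp, rep(1 / 5, 5), sides = 2)[3:(n_spokes + 2)]
  }
  cbind(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
}

# Rasterize continuous centerline points with a disc brush of given radius.
stamp_points <- function(mask, xs, ys, radius) {
  nr <- nrow(mask)
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, , drop = FALSE]
  cx <- round(xs); cy <- round(ys)
  for (k in seq_len(nrow(off))) {
    cc <- cx + off$dx[k]; rr <- cy + off$dy[k]
    keep <- rr >= 0 & rr < nr & cc >= 0 & cc < nr
    mask[cbind(rr[keep] + 1L, cc[keep] + 1L)] <- TRUE
  }
  mask
}

# Big arcade vessels: smooth random-heading curves entering from one image
# edge, steered away from the foveal center, optionally with one branch.
draw_big_vessels <- function(size, n_vessels, width, center, avoid_radius) {
  mask <- matrix(FALSE, size, size)
  if (n_vessels == 0L) return(mask)
  for (v in seq_len(n_vessels)) {
    edge <- sample.int(4L, 1L)
    pos0 <- stats::runif(1, 0.1, 0.9) * (size - 1)
    start <- switch(edge,
                    c(pos0, 0), c(pos0, size - 1), c(0, pos0), c(size - 1, pos0))
    heading <- switch(edge, pi / 2, -pi / 2, 0, pi) +
      stats::runif(1, -0.4, 0.4)
    pts <- draw_vessel_curve(start, heading, size, center, avoid_radius)
    mask <- stamp_points(mask, pts[, 1], pts[, 2], width / 2)
    # one branch from a random point of the parent curve
    if (nrow(pts) > 40L) {
      b0 <- sample(20:(nrow(pts) - 10L), 1L)
      bh <- atan2(pts[b0 + 5L, 2] - pts[b0, 2], pts[b0 + 5L, 1] - pts[b0, 1]) +
        sample(c(-1, 1), 1L) * stats::runif(1, 0.4, 0.8)
      bpts <- draw_vessel_curve(pts[b0, ], bh, size, center, avoid_radius,
                                max_steps = round(size / 3))
      mask <- stamp_points(mask, bpts[, 1], bpts[, 2], width / 2.8)
    }
  }
  mask
}

draw_vessel_curve <- function(start, heading, size, center, avoid_radius,
                              max_steps = NULL) {
  if (is.null(max_steps)) max_steps <- round(size * 0.9)
  step <- 2
  xs <- numeric(max_steps); ys <- numeric(max_steps)
  x <- start[1]; y <- start[2]
  turn <- stats::rnorm(max_steps, 0, 0.06)
  for (i in seq_len(max_steps)) {
    heading <- heading + turn[i]
    # steer away from the fovea so arcades skirt the FAZ
    dcx <- x - center[1]; dcy <- y - center[2]
    dist <- sqrt(dcx^2 + dcy^2)
    if (dist < avoid_radius) {
      away <- atan2(dcy, dcx)
      dh <- ((away - heading + pi) %% (2 * pi)) - pi
      heading <- heading + 0.25 * dh
    }
    x <- x + step * cos(heading); y <- y + step * sin(heading)
    if (x < 0 || y < 0 || x > size - 1 || y > size - 1) {
      return(cbind(xs[seq_len(i - 1L)], ys[seq_len(i - 1L)]))
    }
    xs[i] <- x; ys[i] <- y
  }
  cbind(xs, ys)
}

# Capillary mesh: short random-walk strokes accumulated until the coverage
# fraction inside the 6-mm disc (outside FAZ and big vessels) reaches the
# target.
draw_capillaries <- function(size, target, region, forbidden) {
  mask <- matrix(FALSE, size, size)
  area <- sum(region)
  stroke_len <- 40L
  repeat {
    cov <- sum(mask & region) / area
    if (cov >= target) break
    need_px <- (target - cov) * area
    n_strokes <- max(10L, ceiling(need_px / (stroke_len * 1.3)))
    sx <- stats::runif(n_strokes, 0, size - 1)
    sy <- stats::runif(n_strokes, 0, size - 1)
    h0 <- stats::runif(n_strokes, 0, 2 * pi)
    for (s in seq_len(n_strokes)) {
      h <- cumsum(c(h0[s], stats::rnorm(stroke_len - 1L, 0, 0.35)))
      x <- round(sx[s] + cumsum(cos(h)))
      y <- round(sy[s] + cumsum(sin(h)))
      keep <- x >= 0 & x < size & y >= 0 & y < size
      ij <- cbind(y[keep] + 1L, x[keep] + 1L)
      ij <- ij[!forbidden[ij], , drop = FALSE]
      mask[ij] <- TRUE
    }
  }
  mask
}

generate_one_eye <- function(params, seed, capillary_fraction) {
  set.seed(seed)
  size <- params$image_size
  center <- c((size - 1) / 2, (size - 1) / 2)
  faz_r_px <- params$faz_mean_radius / params$pixel_pitch
  faz_poly <- make_faz_polygon(center, faz_r_px, params$faz_irregularity)

  big <- draw_big_vessels(size, params$n_big_vessels, params$big_vessel_width,
                          center, faz_r_px + 0.6 / params$pixel_pitch)

  # pixel lattice geometry: 6-mm measurement disc and FAZ interior
  xs <- (seq_len(size) - 1) - center[1]
  disc6 <- sqrt(outer(xs^2, xs^2, `+`)) <= 3.0 / params$pixel_pitch
  gx <- rep(seq_len(size) - 1, each = size)   # column (x) per pixel
  gy <- rep(seq_len(size) - 1, times = size)  # row (y) per pixel
  near <- abs(gx - center[1]) < faz_r_px * 2 + 4 &
    abs(gy - center[2]) < faz_r_px * 2 + 4
  faz_mask <- matrix(FALSE, size, size)
  faz_mask[cbind(gy[near] + 1L, gx[near] + 1L)] <-
    points_in_polygon(gx[near], gy[near], faz_poly)

  cap <- draw_capillaries(size, capillary_fraction,
                          region = disc6 & !faz_mask & !big,
                          forbidden = faz_mask | big)

  img <- matrix(params$background_intensity_mean, size, size)
  img[cap] <- params$vessel_intensity_mean
  img[big] <- params$big_vessel_intensity
  if (params$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, params$noise_sd)
  }
  img[] <- round(pmin(255, pmax(0, img)))

  vessel_mask <- cap | big
  truth <- structure(
    list(vessel_mask = vessel_mask, big_vessel_mask = big,
         capillary_mask = cap, faz_polygon = faz_poly, faz_mask = faz_mask,
         true_capillary_fraction = sum(cap & disc6 & !big) / sum(disc6 & !big)),
    class = "angiogram_truth"
  )
  list(pixels = img, truth = truth)
}

#' Generate a synthetic paired-eye angiogram with ground truth
#'
#' Draws a right and a left en-face angiogram with identical generation
#' parameters except for an optional planted left-eye capillary deficit.
#' Capillaries are bright random-walk strokes on a darker background, big
#' arcade vessels are brighter still, the FAZ is cleared of capillaries
#' around the image center, and Gaussian noise is added and clipped to
#' 8-bit range. The same seed reproduces bit-identical output.
#'
#' @param params An [image_gen_params()] list.
#' @param plexus Plexus label attached to the images.
#' @param patient_id Patient identifier attached to the images.
#' @return List with `right`, `left` ([enface_image]s) and `truth_right`,
#'   `truth_left` (ground truth: `vessel_mask`, `big_vessel_mask`,
#'   `capillary_mask`, `faz_polygon`, `faz_mask`,
#'   `true_capillary_fraction`).
#' @export
generate_angiogram_pair <- function(params = image_gen_params(),
                                    plexus = "SCP",
                                    patient_id = "synthetic") {
  if (!inherits(params, "image_gen_params")) {
    params <- do.call(image_gen_params, params)
  }
  right <- generate_one_eye(params, derive_seed(params$seed, 1L),
                            params$capillary_fraction)
  left <- generate_one_eye(params, derive_seed(params$seed, 2L),
                           params$capillary_fraction - params$left_capillary_deficit)
  list(
    right = enface_image(right$pixels, params$pixel_pitch, "right", plexus,
                         patient_id),
    left = enface_image(left$pixels, params$pixel_pitch, "left", plexus,
                        patient_id),
    truth_right = right$truth,
    truth_left = left$truth
  )
}
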