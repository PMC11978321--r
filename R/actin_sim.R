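#' Single-channel confocal image container
#'
#' @param pixels numeric intensity matrix (arbitrary units), one optical
#'   section, one channel.
#' @param pixel_size pixel size, m/px.
#' @param cell_id label.
#' @param cell_mask optional logical matrix marking the cell body.
#' @return object of class \code{actin_image}.
#' @export
actin_image <- function(pixels, pixel_size, cell_id = "cell", cell_mask = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 cell_id = as.character(cell_id), cell_mask = cell_mask),
            class = "actin_image")
}

#' @export
print.actin_image <- function(x, ...) {
  cat(sprintf("<actin_image> %s: %d x %d px at %.0f nm/px\n", x$cell_id,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size * 1e9))
  invisible(x)
}

#' Parameters for the synthetic actin-section generator
#'
#' The generated scene is a mid-cell optical section of a phalloidin-stained
#' spherical cell: a bright cortical ring at the cell boundary, smooth
#' cytosolic filament polylines, optional sub-resolution puncta, all blurred
#' by a Gaussian point-spread function over a constant background with
#' Gaussian noise. Defaults describe a ~15 um cell imaged at 100 nm/px with
#' a confocal-scale PSF (sigma 120 nm); cortex intensity is kept >= 2x the
#' filament intensity so cortex removal is always exercised.
#'
#' @param image_size image side, px.
#' @param pixel_size m/px.
#' @param cell_radius cell radius, m.
#' @param cortex_width cortical ring thickness, m.
#' @param cortex_intensity,filament_intensity,background intensities, AU.
#' @param n_filaments number of cytosolic filaments.
#' @param filament_length_mean,filament_length_sd filament length draw, m.
#' @param n_puncta number of sub-resolution puncta.
#' @param puncta_intensity puncta peak intensity, AU.
#' @param psf_sigma point-spread sigma, m.
#' @param noise_sd additive Gaussian noise SD, AU.
#' @return object of class \code{actin_synth_params}.
#' @export
actin_synth_params <- function(image_size = 192L, pixel_size = 100e-9,
                               cell_radius = 7.5e-6, cortex_width = 0.4e-6,
                               cortex_intensity = 200,
                               n_filaments = 27L,
                               filament_length_mean = 1.8e-6,
                               filament_length_sd = 0.5e-6,
                               filament_intensity = 80,
                               n_puncta = 0L, puncta_intensity = 60,
                               psf_sigma = 120e-9,
                               background = 10, noise_sd = 4) {
  stopifnot(image_size >= 16L, pixel_size > 0, cell_radius > 0,
            cortex_width > 0, n_filaments >= 0L, n_puncta >= 0L,
            filament_length_mean > 0, filament_length_sd >= 0,
            psf_sigma >= 0, noise_sd >= 0)
  if (2 * cell_radius >= image_size * pixel_size)
    stop("image too small to contain the cell disk")
  structure(as.list(environment()), class = "actin_synth_params")
}

#' WT-like and KO-like actin scene presets
#'
#' \code{"wt"}: an extended network of many long filaments (ground-truth
#' total around 48 um per cell); \code{"ko"}: a few short fragments plus
#' puncta (total around 7 um).
#'
#' @param kind "wt" or "ko".
#' @param ... overrides passed to \code{\link{actin_synth_params}}.
#' @return an \code{actin_synth_params}.
#' @export
actin_preset <- function(kind = c("wt", "ko"), ...) {
  kind <- match.arg(kind)
  if (kind == "wt") {
    actin_synth_params(n_filaments = 27L, filament_length_mean = 1.8e-6,
                       filament_length_sd = 0.5e-6, n_puncta = 3L, ...)
  } else {
    actin_synth_params(n_filaments = 8L, filament_length_mean = 0.86e-6,
                       filament_length_sd = 0.2e-6, n_puncta = 15L, ...)
  }
}

# Random smooth polyline of target arc length inside a disk: a correlated
# random walk with bounded turning so the chord structure is gentle and
# measured skeleton length tracks arc length. Returns n x 2 matrix of (x, y)
# in metres relative to image origin.
random_filament <- function(length_m, centre, max_r, step = 100e-9,
                            turn_sd = 0.12) {
  n_steps <- max(2L, ceiling(length_m / step - 1e-9))
  theta <- stats::runif(1, 0, 2 * pi)
  r0 <- max_r * sqrt(stats::runif(1)) * 0.9
  phi <- stats::runif(1, 0, 2 * pi)
  pt <- centre + r0 * c(cos(phi), sin(phi))
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- pt
  for (i in seq_len(n_steps)) {
    theta <- theta + stats::rnorm(1, 0, turn_sd)
    prop <- pt + step * c(cos(theta), sin(theta))
    # reflect off the allowed disk; as a last resort pull the point radially
    # back inside so filaments never approach the cortex band
    if (sqrt(sum((prop - centre)^2)) > max_r) {
      theta <- theta + pi / 2
      prop <- pt + step * c(cos(theta), sin(theta))
      if (sqrt(sum((prop - centre)^2)) > max_r) {
        theta <- theta + pi
        prop <- pt + step * c(cos(theta), sin(theta))
      }
      rp <- sqrt(sum((prop - centre)^2))
      if (rp > max_r) prop <- centre + (prop - centre) * (max_r / rp)
    }
    pt <- prop
    pts[i + 1L, ] <- pt
  }
  pts
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

# stamp a polyline onto the image grid (max-combine), sub-pixel sampling
rasterize_polyline <- function(img, pts, pixel_size, intensity) {
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    L <- sqrt(sum((b - a)^2))
    ns <- max(2L, ceiling(L / (pixel_size / 3)))
    t <- seq(0, 1, length.out = ns)
    xs <- a[1L] + t * (b[1L] - a[1L])
    ys <- a[2L] + t * (b[2L] - a[2L])
    cc <- pmin(pmax(round(xs / pixel_size) + 1L, 1L), ncol(img))
    rr <- pmin(pmax(round(ys / pixel_size) + 1L, 1L), nrow(img))
    ii <- cbind(rr, cc)
    img[ii] <- pmax(img[ii], intensity)
  }
  img
}

#' Simulate a mid-cell actin section with known ground truth
#'
#' @param params an \code{\link{actin_synth_params}}.
#' @param seed integer seed; identical params + seed give bit-identical
#'   images.
#' @param cell_id label.
#' @return list with \code{image} (an \code{\link{actin_image}} whose
#'   \code{cell_mask} is the true cell disk) and \code{truth} (list:
#'   \code{filaments} data.frame(filament_id, length_um),
#'   \code{total_length_um}, \code{n_puncta}).
#' @export
simulate_actin_image <- function(params, seed = 1L, cell_id = "cell") {
  stopifnot(inherits(params, "actin_synth_params"))
  p <- params
  set.seed(as.integer(seed))
  n <- p$image_size
  centre <- rep((n - 1) / 2 * p$pixel_size, 2L)

  xs <- (seq_len(n) - 1) * p$pixel_size
  dx <- outer(rep(1, n), xs - centre[1L])
  dy <- outer(xs - centre[2L], rep(1, n))
  rr <- sqrt(dx^2 + dy^2)
  cell_mask <- rr <= p$cell_radius

  img <- matrix(0, n, n)
  # cortical ring: annulus just inside the cell boundary
  ring <- rr <= p$cell_radius & rr >= p$cell_radius - p$cortex_width
  img[ring] <- p$cortex_intensity

  # filaments: confined to the interior, clear of the cortex band
  interior_r <- p$cell_radius - p$cortex_width - 0.7e-6
  if (interior_r <= 0 && p$n_filaments > 0L)
    stop("cell too small to host cytosolic filaments")
  fil_len <- numeric(0)
  if (p$n_filaments > 0L) {
    for (fi in seq_len(p$n_filaments)) {
      target <- max(0.3e-6,
                    stats::rnorm(1, p$filament_length_mean, p$filament_length_sd))
      if (target > 2 * p$cell_radius)
        stop("filament longer than the cell diameter")
      pts <- random_filament(target, centre, interior_r)
      fil_len <- c(fil_len, polyline_length(pts))
      img <- rasterize_polyline(img, pts, p$pixel_size, p$filament_intensity)
    }
  }

  # puncta: sub-resolution single-pixel seeds (blur spreads them)
  if (p$n_puncta > 0L) {
    for (pi in seq_len(p$n_puncta)) {
      r0 <- interior_r * sqrt(stats::runif(1))
      phi <- stats::runif(1, 0, 2 * pi)
      pos <- centre + r0 * c(cos(phi), sin(phi))
      rc <- pmin(pmax(round(pos / p$pixel_size) + 1L, 1L), n)
      img[rc[2L], rc[1L]] <- max(img[rc[2L], rc[1L]], p$puncta_intensity)
    }
  }

  img <- gaussian_blur(img, p$psf_sigma / p$pixel_size)
  img <- img + p$background
  if (p$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, p$noise_sd), n, n)

  truth <- list(
    filaments = if (length(fil_len))
      data.frame(filament_id = seq_along(fil_len), length_um = fil_len * 1e6)
    else data.frame(filament_id = integer(0), length_um = numeric(0)),
    total_length_um = sum(fil_len) * 1e6,
    n_puncta = p$n_puncta)
  list(image = actin_image(img, p$pixel_size, cell_id = cell_id,
                           cell_mask = cell_mask),
       truth = truth)
}
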