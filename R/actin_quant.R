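#' Rolling-ball background subtraction
#'
#' The background surface is a morphological opening (grayscale erosion then
#' dilation) with a disk structuring element of the given radius; structures
#' smaller than the element survive subtraction, smooth background does not.
#' The surface is computed from a lightly pre-smoothed copy of the image (as
#' ImageJ's rolling-ball does): eroding raw noise would bias the surface
#' several noise-SDs low and leave a constant pedestal in the subtracted
#' image. Output intensities are clamped at zero.
#'
#' @param img an \code{\link{actin_image}}.
#' @param radius_px element radius in pixels (default 20).
#' @return an \code{actin_image} with background removed.
#' @export
subtract_background <- function(img, radius_px = 20L) {
  stopifnot(inherits(img, "actin_image"), radius_px >= 1L)
  if (2L * radius_px + 1L > min(dim(img$pixels)))
    stop("rolling-ball radius larger than the image")
  bg <- grey_open(gaussian_blur(img$pixels, 1), radius_px)
  out <- pmax(img$pixels - bg, 0)
  actin_image(out, img$pixel_size, img$cell_id, img$cell_mask)
}

#' Gaussian smoothing
#'
#' Isotropic separable Gaussian with border renormalization (a constant
#' image is preserved exactly); \code{sigma_px = 0} is the identity.
#'
#' @param img an \code{\link{actin_image}}.
#' @param sigma_px kernel sigma in pixels (default 1).
#' @return smoothed \code{actin_image}.
#' @export
smooth_image <- function(img, sigma_px = 1) {
  stopifnot(inherits(img, "actin_image"), sigma_px >= 0)
  actin_image(gaussian_blur(img$pixels, sigma_px), img$pixel_size,
              img$cell_id, img$cell_mask)
}

#' Threshold an image to a binary mask of actin structures
#'
#' @param img an \code{\link{actin_image}}.
#' @param method threshold selection: \code{"background"} (default) uses
#'   \code{median + 3 * MAD} of the image -- the robust background-noise
#'   threshold appropriate when the structures of interest are a small, dim
#'   pixel population over a subtracted background; \code{"otsu"} is the
#'   two-class between-class-variance threshold; \code{"multiotsu"} the
#'   lower boundary of a three-class Otsu split; a single numeric value is a
#'   manual threshold. The variance-based methods fail on these images
#'   because the bright cortical ring dominates the histogram's variance and
#'   the filament class is too small to claim its own mode.
#' @return list: \code{mask} (logical matrix, foreground = structure),
#'   \code{threshold} (the value used, recorded for provenance).
#' @export
binarize <- function(img, method = "background") {
  stopifnot(inherits(img, "actin_image"))
  thr <- if (is.numeric(method)) {
    as.numeric(method)
  } else if (identical(method, "otsu")) {
    otsu_threshold(img$pixels)
  } else if (identical(method, "multiotsu")) {
    multiotsu_thresholds(img$pixels)[1L]
  } else if (identical(method, "background")) {
    v <- as.numeric(img$pixels)
    if (stats::mad(v) == 0 && stats::sd(v) == 0)
      stop("cannot auto-threshold a constant image; supply a manual threshold")
    stats::median(v) + 3 * stats::mad(v)
  } else stop("unknown threshold method: ", method)
  list(mask = img$pixels > thr, threshold = thr)
}

#' Skeletonize a binary mask and measure skeleton lengths
#'
#' Topological (Zhang-Suen) thinning to 1-px-wide centerlines, then
#' 8-connected skeletons are identified and measured. Length is the sum of
#' inter-pixel steps: \code{1 * pixel_size} for 4-neighbor steps,
#' \code{sqrt(2) * pixel_size} for diagonal steps; a diagonal step is not
#' counted when its two pixels already share an orthogonal skeleton neighbor
#' (otherwise corners would be counted twice). A single isolated pixel has
#' length 0.
#'
#' Thinning erodes roughly half the mask width from each end of an elongated
#' structure (the rounded cap shrinks to a point), which systematically
#' shortens measured filaments by about one mask-width each. With
#' \code{extend_tips = TRUE} (default) every endpoint of a skeleton with at
#' least 4 pixels is extended along its local direction and the Euclidean
#' extension length added. When the \code{intensity} image is supplied the
#' extension stops at the half-maximum crossing of the structure's plateau
#' intensity -- the 50\% contour of a blurred step edge passes through the
#' true edge, so this end localizer is unbiased against the point-spread
#' widening of the mask; without it the extension stops at the mask
#' boundary. The extension is a no-op when the mask is already 1 px wide
#' (the skeleton fills it). Sub-resolution blobs (under 4 skeleton pixels)
#' are never extended, so puncta stay below the length filter.
#'
#' @param mask logical matrix.
#' @param pixel_size m/px.
#' @param extend_tips debias endpoint erosion (default TRUE).
#' @param intensity optional numeric matrix (the image the mask was
#'   thresholded from) enabling half-maximum tip localization.
#' @return list of skeleton records, each a list with \code{id},
#'   \code{pixels} (n x 2 matrix of row, col), \code{length} (m).
#' @export
skeletonize_and_measure <- function(mask, pixel_size, extend_tips = TRUE,
                                    intensity = NULL) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)), pixel_size > 0)
  mask <- mask > 0
  if (!any(mask)) return(list())
  skel <- thin_mask(mask)
  lab <- label_components(skel)
  if (lab$n == 0L) return(list())
  nr <- nrow(skel)

  # extend one endpoint along the local skeleton direction; returns the
  # Euclidean extension length in pixels. Stops at the half-plateau
  # intensity crossing when an intensity image is available, else at the
  # mask boundary.
  tip_extension <- function(cm, endpoint, halfmax) {
    # local direction: from the farthest skeleton pixel within 4 steps
    frontier <- matrix(endpoint, 1L)
    seen <- matrix(FALSE, nrow(cm), ncol(cm))
    seen[endpoint[1L], endpoint[2L]] <- TRUE
    far <- endpoint
    for (depth in 1:4) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        r <- frontier[i, 1L]; c <- frontier[i, 2L]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1L && rr <= nrow(cm) && cc >= 1L && cc <= ncol(cm) &&
              cm[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            nxt <- rbind(nxt, c(rr, cc))
          }
        }
      }
      if (is.null(nxt)) break
      frontier <- nxt
      far <- frontier[1L, ]
    }
    dir <- endpoint - far
    nrm <- sqrt(sum(dir^2))
    if (nrm == 0) return(0)
    dir <- dir / nrm
    ext <- 0
    for (t in seq(0.25, 10, by = 0.25)) {
      p <- round(endpoint + t * dir)
      if (p[1L] < 1L || p[1L] > nrow(mask) ||
          p[2L] < 1L || p[2L] > ncol(mask)) break
      if (!is.null(intensity)) {
        if (intensity[p[1L], p[2L]] < halfmax) break
      } else {
        if (!mask[p[1L], p[2L]]) break
      }
      if (cm[p[1L], p[2L]]) next    # still on the skeleton (1-px masks)
      ext <- t
    }
    ext
  }

  lapply(seq_len(lab$n), function(i) {
    cm <- lab$labels == i
    px <- which(cm, arr.ind = TRUE)
    len <- pair_steps(cm) * pixel_size
    if (extend_tips && nrow(px) >= 4L) {
      # endpoints: skeleton pixels with exactly one 8-neighbor in the component
      nb_count <- matrix(0L, nrow(cm), ncol(cm))
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        nb_count <- nb_count + shift_mat(cm, dr, dc, FALSE)
      }
      ends <- which(cm & nb_count == 1L, arr.ind = TRUE)
      halfmax <- if (!is.null(intensity)) stats::median(intensity[px]) / 2 else NA
      if (nrow(ends) > 0L)
        for (e in seq_len(nrow(ends)))
          len <- len + tip_extension(cm, ends[e, ], halfmax) * pixel_size
    }
    list(id = i, pixels = px, length = len)
  })
}

#' Remove cortical skeletons
#'
#' The cortical actin shell forms one or two long skeletons tracing the cell
#' perimeter; these are excluded from cytosolic network statistics. Each
#' skeleton's fraction of pixels lying within \code{band_width} of the
#' cell-mask boundary is computed, and skeletons with fraction >=
#' \code{overlap_threshold} are removed. A skeleton whose cytosolic part
#' falls apart into two or more pieces when its in-band pixels are excised
#' has merged with the cortex ring through the band (filaments reaching the
#' cell boundary chain the ring into one component); such skeletons are
#' split -- the cortical portion is removed and the cytosolic branches are
#' kept as separate re-measured records. A skeleton that merely grazes the
#' band without disconnecting is kept whole. If no mask is supplied one is
#' derived by heavy smoothing, low thresholding and hole filling of the
#' image.
#'
#' @param records skeleton records from \code{\link{skeletonize_and_measure}}.
#' @param cell_mask logical matrix of the cell body, or NULL to derive from
#'   \code{img}.
#' @param pixel_size m/px.
#' @param band_width boundary band width, m (default 0.5 um).
#' @param overlap_threshold removal threshold on the overlap fraction
#'   (default 0.8).
#' @param img an \code{\link{actin_image}}, needed only when
#'   \code{cell_mask} is NULL.
#' @return list: \code{records} (retained, with \code{cortex_overlap} field
#'   added), \code{removed} (cortical records), \code{cell_mask} used.
#' @export
remove_cortex <- function(records, cell_mask = NULL, pixel_size,
                          band_width = 0.5e-6, overlap_threshold = 0.8,
                          img = NULL) {
  if (is.null(cell_mask)) {
    if (is.null(img)) stop("no cell mask supplied and no image to derive it from")
    sm <- gaussian_blur(img$pixels, 3)
    thr <- stats::quantile(sm, 0.5) + 2 * stats::mad(sm)
    rough <- sm > thr
    lab <- label_components(rough)
    if (lab$n == 0L) stop("cannot derive a cell body mask from the image")
    sizes <- tabulate(lab$labels[lab$labels > 0L], lab$n)
    cell_mask <- fill_holes(lab$labels == which.max(sizes))
  }
  band_px <- max(1L, round(band_width / pixel_size))
  boundary <- cell_mask & !binary_erode(cell_mask, 1.5)
  band <- binary_dilate(boundary, band_px)
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  keep <- list(); removed <- list()
  add_keep <- function(rec) keep[[length(keep) + 1L]] <<- rec
  for (rec in records) {
    in_band <- band[rec$pixels]
    ov <- mean(in_band)
    rec$cortex_overlap <- ov
    if (ov >= overlap_threshold) {
      removed[[length(removed) + 1L]] <- rec
    } else if (any(in_band)) {
      # does excising the in-band pixels disconnect the skeleton?
      cm <- matrix(FALSE, nr, nc)
      cm[rec$pixels[!in_band, , drop = FALSE]] <- TRUE
      lab <- label_components(cm)
      if (lab$n >= 2L) {
        # merged through the cortex: keep cytosolic branches separately
        for (i in seq_len(lab$n)) {
          sub <- lab$labels == i
          px <- which(sub, arr.ind = TRUE)
          add_keep(list(id = rec$id + i / 100, pixels = px,
                        length = pair_steps(sub) * pixel_size,
                        cortex_overlap = 0))
        }
        rec$pixels <- rec$pixels[in_band, , drop = FALSE]
        removed[[length(removed) + 1L]] <- rec
      } else {
        add_keep(rec)
      }
    } else {
      add_keep(rec)
    }
  }
  list(records = keep, removed = removed, cell_mask = cell_mask)
}

#' Length-filter skeletons and summarize per cell
#'
#' Drops skeletons shorter than \code{min_length} (sub-resolution), then
#' reports the per-cell total cytosolic length and mean structure length.
#'
#' @param records skeleton records (post cortex removal).
#' @param min_length minimum retained length, m (default 250 nm).
#' @return list: \code{total_length} (m), \code{mean_length} (m, 0 if no
#'   structure), \code{n_structures}, \code{lengths} (m, retained).
#' @export
filter_and_summarize <- function(records, min_length = 250e-9) {
  lens <- vapply(records, `[[`, numeric(1), "length")
  keep <- lens >= min_length
  lens <- lens[keep]
  list(total_length = sum(lens),
       mean_length = if (length(lens)) mean(lens) else 0,
       n_structures = length(lens),
       lengths = lens)
}

#' Full actin quantification of one optical section
#'
#' Background subtraction, smoothing, thresholding, skeletonization, cortex
#' exclusion and length filtering in the standard order, returning per-cell
#' metrics plus a provenance record of every parameter actually used.
#'
#' @param img an \code{\link{actin_image}}.
#' @param config a \code{\link{run_config}} (image parameters are taken from
#'   it).
#' @return list of class \code{actin_metrics}: \code{total_length_um},
#'   \code{mean_length_um}, \code{n_structures}, \code{lengths_um},
#'   \code{records} (retained records), \code{n_cortex_removed},
#'   \code{provenance}.
#' @export
quantify_actin <- function(img, config = run_config()) {
  stopifnot(inherits(img, "actin_image"))
  work <- subtract_background(img, config$rolling_ball_radius)
  work <- smooth_image(work, config$smooth_sigma)
  bz <- binarize(work, config$threshold_method)
  recs <- skeletonize_and_measure(bz$mask, img$pixel_size,
                                  intensity = work$pixels)
  cx <- remove_cortex(recs, cell_mask = img$cell_mask,
                      pixel_size = img$pixel_size,
                      band_width = config$cortex_band,
                      overlap_threshold = config$cortex_overlap,
                      img = img)
  fs <- filter_and_summarize(cx$records, config$min_skeleton_length)
  structure(list(cell_id = img$cell_id,
                 total_length_um = fs$total_length * 1e6,
                 mean_length_um = fs$mean_length * 1e6,
                 n_structures = fs$n_structures,
                 lengths_um = fs$lengths * 1e6,
                 records = cx$records,
                 n_cortex_removed = length(cx$removed),
                 provenance = list(threshold = bz$threshold,
                                   rolling_ball_radius = config$rolling_ball_radius,
                                   smooth_sigma = config$smooth_sigma,
                                   cortex_band_m = config$cortex_band,
                                   cortex_overlap = config$cortex_overlap,
                                   min_skeleton_length_m = config$min_skeleton_length)),
            class = "actin_metrics")
}

#' Cohort summary of actin metrics
#'
#' @param metrics list of \code{actin_metrics} (one per cell).
#' @return data.frame with cohort mean and SEM of the per-cell total and
#'   mean structure lengths.
#' @export
actin_cohort_summary <- function(metrics) {
  tot <- vapply(metrics, `[[`, numeric(1), "total_length_um")
  mn <- vapply(metrics, `[[`, numeric(1), "mean_length_um")
  data.frame(n_cells = length(metrics),
             total_mean_um = mean(tot), total_sem_um = sem(tot),
             structure_mean_um = mean(mn), structure_sem_um = sem(mn))
}
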