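#' Baseline model of the off-contact approach region
#'
#' Identifies the off-contact part of the approach (samples farther from the
#' surface than a provisional contact position), fits the baseline force
#' there (constant offset by default, optional linear tilt), and reports the
#' span of the flat region and the residual noise SD. A span shorter than
#' \code{min_span} raises the (non-fatal) \code{short_baseline} QC condition.
#'
#' @param curve a \code{\link{force_curve}}.
#' @param min_span minimum acceptable flat-baseline span, m (default 500 nm).
#' @param fit_slope also remove a linear tilt (default FALSE: offset only).
#' @return list of class \code{baseline_model}: \code{offset} (N),
#'   \code{slope} (N/m), \code{span} (m), \code{noise_sd} (N),
#'   \code{short_baseline} (logical), \code{n_baseline} (samples used).
#' @export
detect_baseline <- function(curve, min_span = 500e-9, fit_slope = FALSE) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$approach$z_m
  F_raw <- curve$k * curve$approach$d_m
  n <- length(z)

  # Rough pass: the first samples (farthest from the surface) estimate the
  # baseline level robustly; a sustained rise locates provisional contact.
  n0 <- max(20L, min(30L, n %/% 4L))
  off0 <- stats::median(F_raw[seq_len(n0)])
  sd0 <- stats::mad(F_raw[seq_len(n0)])
  thr0 <- off0 + 3 * max(sd0, 1e-15)
  above <- F_raw > thr0
  # provisional contact: first index after which force stays above threshold
  stays <- rev(cumprod(rev(above))) > 0
  i_contact <- if (any(stays)) which(stays)[1L] else n + 1L

  # Baseline region: everything clearly before provisional contact.
  guard <- 5L
  i_end <- max(i_contact - guard, n0)
  idx <- seq_len(min(i_end, n))
  zb <- z[idx]; fb <- F_raw[idx]
  if (fit_slope && length(idx) >= 3L) {
    fit <- stats::lm.fit(cbind(1, zb), fb)
    offset <- fit$coefficients[[1L]]
    slope <- fit$coefficients[[2L]]
    resid <- fit$residuals
  } else {
    offset <- mean(fb)
    slope <- 0
    resid <- fb - offset
  }
  span <- abs(zb[1L] - zb[length(zb)])
  noise_sd <- if (length(resid) > 1L) stats::sd(resid) else 0
  structure(list(offset = offset, slope = slope, span = span,
                 noise_sd = noise_sd,
                 short_baseline = span < min_span,
                 n_baseline = length(idx)),
            class = "baseline_model")
}

#' Provisional contact-point estimate
#'
#' Scans the baseline-corrected approach toward the surface for the first
#' sample whose force exceeds \code{q * noise_sd} and stays above it for all
#' subsequent samples, then refines by extrapolating the shallow-contact
#' region to zero force on the linearized Hertz scale (\eqn{F^{2/3}} is
#' linear in tip position for spherical contact at small depth). The result
#' seeds the joint (E, contact point) fit; it is reported in tip-position
#' coordinates \code{h = z - d}.
#'
#' @param curve a \code{\link{force_curve}}.
#' @param baseline a \code{baseline_model} from \code{\link{detect_baseline}}.
#' @param q noise multiple for the crossing threshold (default 3).
#' @param refine apply the Hertz-linearized extrapolation (default TRUE).
#' @return contact position h0 in metres (tip coordinate).
#' @export
estimate_contact_point <- function(curve, baseline, q = 3, refine = TRUE) {
  stopifnot(inherits(curve, "force_curve"), inherits(baseline, "baseline_model"))
  z <- curve$approach$z_m
  F <- curve$k * curve$approach$d_m - (baseline$offset + baseline$slope * z)
  h <- z - F / curve$k
  thr <- max(q * baseline$noise_sd, 1e-16)
  above <- F > thr
  stays <- rev(cumprod(rev(above))) > 0
  if (!any(stays))
    stop("nonconvergent: force never rises above the noise threshold ",
         "(no contact found)")
  i0 <- which(stays)[1L]
  h0 <- h[i0]
  if (!refine) return(h0)

  # Hertz-linearized refinement: over the shallow contact region
  # (thr .. 25*thr, capped) F^(2/3) ~ c * (h0 - h); extrapolate to F = 0.
  Fcap <- min(25 * thr, max(F))
  idx <- which(F > thr & F <= Fcap & seq_along(F) >= i0 - 2L)
  if (length(idx) >= 4L) {
    y <- F[idx]^(2 / 3)
    fit <- stats::lm.fit(cbind(1, h[idx]), y)
    b0 <- fit$coefficients[[1L]]; b1 <- fit$coefficients[[2L]]
    if (is.finite(b1) && b1 < 0) {
      h_ext <- -b0 / b1
      # accept only if the extrapolation stays near the crossing sample
      if (abs(h_ext - h0) < 500e-9) h0 <- h_ext
    }
  }
  h0
}

#' Detect membrane-pinching events
#'
#' A pinch is a transient force drop after contact: the force falls by more
#' than \code{drop_threshold} below its running maximum within an indentation
#' window shorter than \code{window_width}, then resumes rising. Detection
#' runs on a lightly smoothed force to keep the false-positive rate low at
#' 10 pN instrument noise.
#'
#' @param delta indentation depths (m), increasing.
#' @param force baseline-corrected forces (N) at \code{delta}.
#' @param drop_threshold minimum drop to call a pinch, N (default 50 pN).
#' @param window_width maximum indentation extent of the dip, m (default 50 nm).
#' @return list(detected = logical, location = indentation depth of the
#'   deepest dip (m) or NA).
#' @export
detect_pinch <- function(delta, force, drop_threshold = 50e-12,
                         window_width = 50e-9) {
  n <- length(force)
  if (n < 5L) return(list(detected = FALSE, location = NA_real_))
  sm <- stats::filter(force, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- force[is.na(sm)]
  sm <- as.numeric(sm)
  runmax <- cummax(sm)
  dip <- runmax - sm
  cand <- which(dip >= drop_threshold)
  if (length(cand) == 0L) return(list(detected = FALSE, location = NA_real_))
  # group candidate samples into events; an event must be short in delta and
  # the force must recover (running max increases again afterwards)
  splits <- split(cand, cumsum(c(1, diff(cand) > 3)))
  for (ev in splits) {
    lo <- ev[1L]; hi <- ev[length(ev)]
    # extend to the full dip (where dip > threshold/2) around the event
    while (lo > 1L && dip[lo - 1L] > drop_threshold / 2) lo <- lo - 1L
    while (hi < n && dip[hi + 1L] > drop_threshold / 2) hi <- hi + 1L
    width <- delta[min(hi, n)] - delta[max(lo, 1L)]
    recovers <- hi < n && max(sm[(hi + 1L):n]) >= runmax[hi]
    if (width <= window_width && recovers) {
      imax <- ev[which.max(dip[ev])]
      return(list(detected = TRUE, location = delta[imax]))
    }
  }
  list(detected = FALSE, location = NA_real_)
}

#' Correct a force curve and fit the contact model
#'
#' Applies the standard corrections -- baseline subtraction, force
#' \code{F = k d}, tip position \code{h = z - d} (cantilever-bending
#' correction) -- then jointly fits Young's modulus \code{E} and the contact
#' point \code{h_c} by least squares of the chosen contact model over the
#' samples from just above contact down to the set-point sample. \code{E}
#' enters the model linearly, so it is profiled out and the optimization is
#' one-dimensional in \code{h_c}, seeded by
#' \code{\link{estimate_contact_point}}.
#'
#' QC flags raised: \code{short_baseline} (flat region < \code{min_span}),
#' \code{pinch} (see \code{\link{detect_pinch}}), \code{nonconvergent} (no
#' contact found, optimizer failure, or E at its bounds),
#' \code{bad_residual} (rms residual > \code{residual_tol} x set point),
#' \code{depth_ratio_warn} (advisory: max indentation > 10\% of the cell
#' diameter when diameter metadata is supplied).
#'
#' @param curve a \code{\link{force_curve}}.
#' @param model a \code{\link{contact_model}}.
#' @param min_span,fit_slope passed to \code{\link{detect_baseline}}.
#' @param q passed to \code{\link{estimate_contact_point}}.
#' @param residual_tol bad_residual threshold as a fraction of the set point.
#' @param E_bounds allowed modulus range, Pa.
#' @param cell_diameter optional cell diameter (m) for the depth-ratio check.
#' @param pinch_opts list(drop_threshold =, window_width =) for
#'   \code{\link{detect_pinch}}.
#' @return Object of class \code{curve_fit_result}: fields \code{E} (Pa),
#'   \code{contact_point} (m, tip coordinate), \code{max_indentation} (m),
#'   \code{rms_residual} (N), \code{n_fit_points}, \code{qc} (list with
#'   \code{flags}, \code{baseline_span}, \code{depth_ratio}), plus labels.
#' @export
correct_and_fit <- function(curve, model = contact_model(),
                            min_span = 500e-9, fit_slope = FALSE, q = 3,
                            residual_tol = 0.05,
                            E_bounds = c(1, 1e6),
                            cell_diameter = NULL,
                            pinch_opts = list(drop_threshold = 50e-12,
                                              window_width = 50e-9)) {
  stopifnot(inherits(curve, "force_curve"), inherits(model, "contact_model"))
  flags <- character(0)
  baseline <- detect_baseline(curve, min_span = min_span, fit_slope = fit_slope)
  if (baseline$short_baseline) flags <- c(flags, "short_baseline")

  z <- curve$approach$z_m
  F <- curve$k * curve$approach$d_m - (baseline$offset + baseline$slope * z)
  h <- z - F / curve$k

  h0 <- tryCatch(estimate_contact_point(curve, baseline, q = q),
                 error = function(e) NA_real_)
  if (is.na(h0)) {
    return(new_curve_fit_result(curve, E = NA_real_, contact_point = NA_real_,
                                max_indentation = NA_real_,
                                rms_residual = NA_real_, n_fit_points = 0L,
                                flags = c(flags, "nonconvergent"),
                                baseline = baseline, depth_ratio = NA_real_))
  }

  # fit window: a pad of pre-contact samples down to the set-point sample
  pad <- 300e-9
  sel <- which(h <= h0 + pad)
  hw <- h[sel]; Fw <- F[sel]

  ssr_profile <- function(h_c) {
    phi <- contact_force_unit(pmax(h_c - hw, 0), model)
    s2 <- sum(phi^2)
    if (s2 == 0) return(list(ssr = sum(Fw^2), E = NA_real_))
    Ered <- sum(Fw * phi) / s2
    r <- Fw - Ered * phi
    list(ssr = sum(r^2), E = Ered * (1 - model$nu^2))
  }
  win <- 250e-9
  opt <- stats::optimize(function(hc) ssr_profile(hc)$ssr,
                         lower = h0 - win, upper = h0 + win, tol = 1e-12)
  h_c <- opt$minimum
  prof <- ssr_profile(h_c)
  E <- prof$E

  if (!is.finite(E) || E <= E_bounds[1L] || E >= E_bounds[2L]) {
    flags <- c(flags, "nonconvergent")
    E <- NA_real_
  }

  delta <- pmax(h_c - h, 0)
  max_ind <- max(delta)
  rms <- sqrt(prof$ssr / length(Fw))
  if (is.finite(E) && rms > residual_tol * curve$setpoint)
    flags <- c(flags, "bad_residual")

  # pinch detection on the corrected contact region
  inc <- which(delta > 0)
  if (length(inc) >= 5L) {
    pk <- detect_pinch(delta[inc], F[inc],
                       drop_threshold = pinch_opts$drop_threshold,
                       window_width = pinch_opts$window_width)
    if (pk$detected) flags <- c(flags, "pinch")
  }

  depth_ratio <- NA_real_
  if (!is.null(cell_diameter) && is.finite(cell_diameter) && cell_diameter > 0) {
    depth_ratio <- max_ind / cell_diameter
    if (depth_ratio > 0.1) flags <- c(flags, "depth_ratio_warn")
  }

  new_curve_fit_result(curve, E = E, contact_point = h_c,
                       max_indentation = max_ind, rms_residual = rms,
                       n_fit_points = length(Fw), flags = flags,
                       baseline = baseline, depth_ratio = depth_ratio)
}

new_curve_fit_result <- function(curve, E, contact_point, max_indentation,
                                 rms_residual, n_fit_points, flags,
                                 baseline, depth_ratio) {
  structure(list(E = E, contact_point = contact_point,
                 max_indentation = max_indentation,
                 rms_residual = rms_residual,
                 n_fit_points = as.integer(n_fit_points),
                 qc = list(flags = unique(flags),
                           baseline_span = baseline$span,
                           noise_sd = baseline$noise_sd,
                           depth_ratio = depth_ratio),
                 cell_id = curve$cell_id,
                 curve_index = curve$curve_index,
                 group = curve$group),
            class = "curve_fit_result")
}

#' Does a curve fit pass quality control?
#'
#' A curve passes iff none of \code{short_baseline}, \code{pinch},
#' \code{nonconvergent}, \code{bad_residual} is flagged;
#' \code{depth_ratio_warn} is advisory only and never fails a curve.
#'
#' @param fit a \code{curve_fit_result}.
#' @return logical.
#' @export
qc_pass <- function(fit) {
  stopifnot(inherits(fit, "curve_fit_result"))
  !any(fit$qc$flags %in% c("short_baseline", "pinch", "nonconvergent",
                           "bad_residual"))
}

#' @export
print.curve_fit_result <- function(x, ...) {
  cat(sprintf("<curve_fit_result> %s #%d: E = %s Pa, delta_max = %.3g um, flags = [%s]\n",
              x$cell_id, x$curve_index,
              if (is.finite(x$E)) sprintf("%.1f", x$E) else "NA",
              x$max_indentation * 1e6,
              paste(x$qc$flags, collapse = ", ")))
  invisible(x)
}
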