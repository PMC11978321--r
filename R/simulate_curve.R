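#' Parameters for the synthetic force-curve generator
#'
#' Defaults reproduce the acquisition used throughout: a 20 um colloidal
#' probe (R = 10 um) on a 0.06 N/m cantilever, 1 nN set point, 3.5 um piezo
#' travel at 1 um/s, incompressible sample (nu = 0.5).
#'
#' @param E_true ground-truth Young's modulus, Pa.
#' @param R probe radius, m.
#' @param nu Poisson ratio, in (0, 0.5].
#' @param k spring constant, N/m.
#' @param setpoint approach force set point, N.
#' @param z_length piezo travel, m.
#' @param speed extend speed, m/s (metadata only).
#' @param sample_spacing piezo step between samples, m.
#' @param contact_frac fraction of the travel spent off-contact before the
#'   surface is reached; controls the baseline span.
#' @param baseline_offset,baseline_slope baseline force artifact: recorded
#'   force off contact is \code{offset + slope * z} (N, N/m).
#' @param noise_sd per-sample force noise SD, N. Default 10 pN.
#' @param adhesion_depth depth of the tip-sample adhesion dip on retract, N.
#' @param pinch optional membrane-pinch artifact: a list
#'   \code{list(depth =, width =, position =)} giving a transient force drop
#'   of \code{depth} N with full width \code{width} m centred at indentation
#'   \code{position} m.
#' @param model contact model generating the response: "sneddon_sphere" or
#'   "paraboloid".
#' @return A validated parameter list of class \code{synth_curve_params}.
#' @export
synth_curve_params <- function(E_true, R = 10e-6, nu = 0.5, k = 0.06,
                               setpoint = 1e-9, z_length = 3.5e-6,
                               speed = 1e-6, sample_spacing = 5e-9,
                               contact_frac = 0.3,
                               baseline_offset = 0, baseline_slope = 0,
                               noise_sd = 10e-12, adhesion_depth = 0,
                               pinch = NULL,
                               model = c("sneddon_sphere", "paraboloid")) {
  model <- match.arg(model)
  stopifnot(E_true > 0, R > 0, nu > 0, nu <= 0.5, k > 0, setpoint > 0,
            z_length > 0, sample_spacing > 0, noise_sd >= 0,
            adhesion_depth >= 0, contact_frac > 0, contact_frac < 1)
  if (!is.null(pinch))
    stopifnot(is.list(pinch), all(c("depth", "width", "position") %in% names(pinch)),
              pinch$depth > 0, pinch$width > 0, pinch$position > 0)
  structure(list(E_true = E_true, R = R, nu = nu, k = k, setpoint = setpoint,
                 z_length = z_length, speed = speed,
                 sample_spacing = sample_spacing, contact_frac = contact_frac,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 adhesion_depth = adhesion_depth, pinch = pinch, model = model),
            class = "synth_curve_params")
}

# Gaussian dip used for pinch (on approach, in indentation coordinate) and
# adhesion (on retract, just off contact). FWHM equals `width`.
gaussian_dip <- function(x, centre, width, depth) {
  sd <- width / (2 * sqrt(2 * log(2)))
  depth * exp(-(x - centre)^2 / (2 * sd^2))
}

#' Simulate one force-distance curve
#'
#' Forward model of a colloidal-probe indentation: the piezo height sweeps
#' down by \code{z_length}; off contact the recorded force is the baseline
#' artifact plus noise; past the contact point the cantilever deflection
#' \code{d} solves the self-consistency \code{k d = F_contact(h_c - (z - d))}
#' so that the standard corrections (baseline subtraction, tip position
#' \code{h = z - d}, indentation \code{delta = h_c - h}) recover the contact
#' model exactly. The approach terminates at the first sample whose contact
#' force reaches the set point; the retract mirrors the approach with an
#' optional adhesion dip.
#'
#' @param params a \code{\link{synth_curve_params}}.
#' @param seed integer seed; identical params + seed give bit-identical curves.
#' @param cell_id,curve_index,group labels stamped on the curve.
#' @return A \code{\link{force_curve}}. The true contact point (tip-position
#'   coordinate) is attached as attribute \code{"h_c_true"}.
#' @export
simulate_curve <- function(params, seed = 1L, cell_id = "cell",
                           curve_index = 1L, group = NA_character_) {
  stopifnot(inherits(params, "synth_curve_params"))
  p <- params
  model <- contact_model(p$model, R = p$R, nu = p$nu)
  Ered <- p$E_true / (1 - p$nu^2)

  # Feasibility: indentation depth + cantilever bending needed for the set
  # point must fit in the on-contact part of the travel.
  delta_sp <- contact_depth_at_force(p$setpoint, model, p$E_true)
  travel_needed <- delta_sp + p$setpoint / p$k
  travel_avail <- (1 - p$contact_frac) * p$z_length
  if (travel_needed > travel_avail)
    stop(sprintf(paste0("set point unreachable: E = %g Pa needs %.3g um of ",
                        "on-contact travel but only %.3g um is available ",
                        "(z_length %.3g um, contact_frac %.2f)"),
                 p$E_true, travel_needed * 1e6, travel_avail * 1e6,
                 p$z_length * 1e6, p$contact_frac))

  z <- seq(p$z_length, 0, by = -p$sample_spacing)
  h_c <- (1 - p$contact_frac) * p$z_length   # true contact point, tip coords

  # Solve k d = F(h_c - z + d) for d at each z past contact (vectorized Newton).
  d_true <- numeric(length(z))
  past <- z < h_c
  if (any(past)) {
    zc <- z[past]
    d <- pmax(h_c - zc, 0) * 0   # start at 0
    for (it in 1:60) {
      delta <- h_c - zc + d
      g <- p$k * d - Ered * contact_force_unit(delta, model)
      gp <- p$k - Ered * contact_stiffness_unit(delta, model)
      # gp stays positive here (cell stiffness << cantilever stiffness)
      step <- g / gp
      d <- d - step
      d[d < 0] <- 0
      if (max(abs(step)) < 1e-15) break
    }
    d_true[past] <- d
  }
  F_contact <- p$k * d_true

  # truncate at the first sample reaching the set point
  hit <- which(F_contact >= p$setpoint)
  if (length(hit) == 0L)
    stop("set point not reached on the sampled grid; decrease sample_spacing")
  keep <- seq_len(hit[1L])
  z <- z[keep]; d_true <- d_true[keep]; F_contact <- F_contact[keep]

  set.seed(as.integer(seed))
  noise_app <- if (p$noise_sd > 0) stats::rnorm(length(z), 0, p$noise_sd) else numeric(length(z))
  F_meas <- F_contact + p$baseline_offset + p$baseline_slope * z + noise_app

  if (!is.null(p$pinch)) {
    delta <- pmax(h_c - (z - d_true), 0)
    F_meas <- F_meas - gaussian_dip(delta, p$pinch$position, p$pinch$width,
                                    p$pinch$depth) * (delta > 0)
  }
  approach <- data.frame(z_m = z, d_m = F_meas / p$k)

  # retract mirrors the approach; adhesion appears as a dip just off contact
  z_r <- rev(z)
  d_r <- rev(d_true)
  noise_ret <- if (p$noise_sd > 0) stats::rnorm(length(z_r), 0, p$noise_sd) else numeric(length(z_r))
  F_ret <- p$k * d_r + p$baseline_offset + p$baseline_slope * z_r + noise_ret
  if (p$adhesion_depth > 0) {
    h_r <- z_r - d_r
    F_ret <- F_ret - gaussian_dip(h_r, h_c + 150e-9, 200e-9, p$adhesion_depth) *
      (h_r > h_c)
  }
  retract <- data.frame(z_m = z_r, d_m = F_ret / p$k)

  fc <- force_curve(approach, retract, k = p$k, setpoint = p$setpoint,
                    R = p$R, speed = p$speed, cell_id = cell_id,
                    curve_index = curve_index, group = group)
  attr(fc, "h_c_true") <- h_c
  fc
}

#' Softest modulus measurable under given acquisition parameters
#'
#' A cell is only measurable if the set-point force is reached within the
#' on-contact part of the piezo travel: indentation depth at the set point
#' plus the cantilever bending must fit in \code{(1 - contact_frac) *
#' z_length}. Returns the Young's modulus at which they exactly fit; softer
#' cells cannot be acquired (the approach would run out of travel below the
#' set point).
#'
#' @param params a \code{\link{synth_curve_params}} (its \code{E_true} is
#'   ignored).
#' @return modulus floor, Pa.
#' @export
feasible_E_floor <- function(params) {
  stopifnot(inherits(params, "synth_curve_params"))
  model <- contact_model(params$model, R = params$R, nu = params$nu)
  travel <- (1 - params$contact_frac) * params$z_length -
    params$setpoint / params$k
  # force is linear in E: the floor is where F(travel; E) = setpoint
  params$setpoint * (1 - params$nu^2) / contact_force_unit(travel, model)
}

#' Simulate the 15-indentation series on one cell
#'
#' Curve #1 is generated with modulus \code{E_cell * first_shift_factor}
#' (the repositioning shift seen between the first and second indentation);
#' curves 2..n use \code{E_cell}. Noise is independent across curves but the
#' whole series is reproducible from \code{seed}.
#'
#' @param E_cell the cell's Young's modulus, Pa.
#' @param params a \code{\link{synth_curve_params}}; its \code{E_true} is
#'   overridden per curve.
#' @param n_curves number of repeat indentations (default 15).
#' @param first_shift_factor multiplicative modulus shift on curve #1 only.
#' @param seed integer master seed for the cell.
#' @param cell_id,group labels.
#' @param artifact per-curve artifact descriptors: optional list of lists
#'   with elements \code{short_baseline} (logical) and \code{pinch}
#'   (NULL or pinch list), recycled from \code{NULL} = none.
#' @return list of \code{\link{force_curve}}.
#' @export
simulate_cell <- function(E_cell, params, n_curves = 15L,
                          first_shift_factor = 1, seed = 1L,
                          cell_id = "cell", group = NA_character_,
                          artifact = NULL) {
  stopifnot(n_curves >= 1L, E_cell > 0, first_shift_factor > 0)
  seeds <- substream_seeds(seed, n_curves)
  lapply(seq_len(n_curves), function(i) {
    E_i <- if (i == 1L) E_cell * first_shift_factor else E_cell
    p_i <- params
    p_i$E_true <- E_i
    if (!is.null(artifact) && length(artifact) >= i && !is.null(artifact[[i]])) {
      a <- artifact[[i]]
      if (isTRUE(a$short_baseline)) p_i$contact_frac <- 0.1
      if (!is.null(a$pinch)) p_i$pinch <- a$pinch
    }
    simulate_curve(p_i, seed = seeds[i], cell_id = cell_id,
                   curve_index = i, group = group)
  })
}
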