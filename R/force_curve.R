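#' Force-distance curve
#'
#' One approach/retract pair in instrument coordinates: piezo height \code{z}
#' (metres, decreasing toward the sample during approach) and cantilever
#' deflection \code{d} (metres), plus calibration metadata. Force is
#' \code{k * d}; tip position is \code{h = z - d}.
#'
#' @param approach data.frame with numeric columns \code{z_m}, \code{d_m},
#'   ordered surface-ward (z strictly decreasing), at least 50 samples.
#' @param retract data.frame with the same columns, z strictly increasing;
#'   may be empty (the retract segment is carried but never analyzed).
#' @param k cantilever spring constant, N/m.
#' @param setpoint force set point, N.
#' @param R probe radius, m.
#' @param speed extend speed, m/s (metadata only).
#' @param cell_id,curve_index,group identification labels; \code{curve_index}
#'   is 1-based within a cell.
#' @return Object of class \code{force_curve}.
#' @export
force_curve <- function(approach, retract = NULL, k, setpoint = 1e-9,
                        R = 10e-6, speed = 1e-6,
                        cell_id = "cell", curve_index = 1L, group = NA_character_) {
  stopifnot(is.data.frame(approach), all(c("z_m", "d_m") %in% names(approach)))
  if (nrow(approach) < 50L)
    stop("approach segment must have at least 50 samples, got ", nrow(approach))
  dz <- diff(approach$z_m)
  if (!all(dz < 0))
    stop("approach z must be strictly decreasing (ordered surface-ward)")
  if (!is.null(retract) && nrow(retract) > 1L && !all(diff(retract$z_m) > 0))
    stop("retract z must be strictly increasing")
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  if (curve_index < 1L) stop("curve_index is 1-based and must be >= 1")
  structure(list(approach = approach, retract = retract,
                 k = k, setpoint = setpoint, R = R, speed = speed,
                 cell_id = as.character(cell_id),
                 curve_index = as.integer(curve_index),
                 group = as.character(group)),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s #%d (%s): %d approach samples, k = %g N/m, setpoint = %g nN\n",
              x$cell_id, x$curve_index, x$group, nrow(x$approach),
              x$k, x$setpoint * 1e9))
  invisible(x)
}
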