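#' Spherical-indenter contact model
#'
#' Describes the tip-sample contact mechanics used both to simulate and to
#' fit approach curves. Two variants are supported:
#' \describe{
#'   \item{\code{"paraboloid"}}{the textbook Hertz approximation for a sphere
#'     indenting an elastic half-space at small indentation-to-radius ratio,
#'     \eqn{F = (4/3) (E / (1 - \nu^2)) \sqrt{R}\, \delta^{3/2}}.}
#'   \item{\code{"sneddon_sphere"}}{the exact rigid-sphere solution, where the
#'     contact radius \eqn{a} solves
#'     \eqn{\delta = (a/2) \log((R+a)/(R-a))} and
#'     \eqn{F = (E/(1-\nu^2)) [ (a^2 + R^2)/2 \log((R+a)/(R-a)) - a R ]}.
#'     It reduces to the paraboloid form as \eqn{\delta/R \to 0} and exceeds
#'     it at finite depth.}
#' }
#'
#' @param kind "paraboloid" or "sneddon_sphere".
#' @param R probe (sphere) radius in metres. Default 10e-6, a 20 um bead.
#' @param nu Poisson ratio, in (0, 0.5]. Default 0.5 (incompressible cell).
#' @return An object of class \code{contact_model}.
#' @export
contact_model <- function(kind = c("sneddon_sphere", "paraboloid"),
                          R = 10e-6, nu = 0.5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(R), length(R) == 1L, R > 0,
            is.numeric(nu), length(nu) == 1L, nu > 0, nu <= 0.5)
  structure(list(kind = kind, R = R, nu = nu), class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("<contact_model> %s: R = %.3g um, nu = %.2f\n",
              x$kind, x$R * 1e6, x$nu))
  invisible(x)
}

# Contact radius a for the Sneddon sphere at given indentation depth(s).
# Vectorized Newton iteration on delta(a) = (a/2) log((R+a)/(R-a)),
# seeded with the Hertz estimate a ~ sqrt(R * delta).
sneddon_contact_radius <- function(delta, R, tol = 1e-14, maxit = 60L) {
  a <- pmin(sqrt(R * pmax(delta, 0)), 0.99 * R)
  pos <- delta > 0
  if (!any(pos)) return(rep(0, length(delta)))
  for (i in seq_len(maxit)) {
    L <- log((R + a[pos]) / (R - a[pos]))
    f <- a[pos] / 2 * L - delta[pos]
    fp <- L / 2 + a[pos] * R / (R^2 - a[pos]^2)
    step <- f / fp
    a_new <- a[pos] - step
    # keep iterates inside (0, R)
    a_new[a_new <= 0] <- a[pos][a_new <= 0] / 2
    a_new[a_new >= R] <- (a[pos][a_new >= R] + R) / 2
    conv <- max(abs(a_new - a[pos]) / R)
    a[pos] <- a_new
    if (conv < tol) break
  }
  a[!pos] <- 0
  a
}

# Model force at unit reduced modulus E/(1-nu^2) = 1. Force is linear in E,
# which the fitter exploits by profiling E out of the least squares.
contact_force_unit <- function(delta, model) {
  stopifnot(inherits(model, "contact_model"))
  delta <- pmax(delta, 0)
  R <- model$R
  if (model$kind == "paraboloid") {
    (4 / 3) * sqrt(R) * delta^1.5
  } else {
    a <- sneddon_contact_radius(delta, R)
    out <- numeric(length(delta))
    pos <- a > 0
    if (any(pos)) {
      L <- log((R + a[pos]) / (R - a[pos]))
      out[pos] <- (a[pos]^2 + R^2) / 2 * L - a[pos] * R
    }
    out
  }
}

#' Contact force for a spherical indenter
#'
#' Evaluates the contact force at indentation depth \code{delta} for a given
#' Young's modulus. \code{F(0) = 0}; the force is strictly increasing in both
#' \code{delta} and \code{E}.
#'
#' @param delta indentation depth(s) in metres, must be >= 0.
#' @param model a \code{\link{contact_model}}.
#' @param E Young's modulus in Pa.
#' @return Force(s) in newtons, same length as \code{delta}.
#' @export
contact_force <- function(delta, model, E) {
  stopifnot(inherits(model, "contact_model"), is.numeric(E), E > 0)
  if (any(delta < 0)) stop("indentation depth must be >= 0")
  if (model$kind == "sneddon_sphere" && any(delta >= model$R * log(2e16)))
    stop("indentation too deep for the Sneddon sphere solution (a -> R)")
  E / (1 - model$nu^2) * contact_force_unit(delta, model)
}

# d(force)/d(delta) at unit reduced modulus; used by the curve simulator's
# Newton solve for the deflection self-consistency.
contact_stiffness_unit <- function(delta, model) {
  delta <- pmax(delta, 0)
  R <- model$R
  if (model$kind == "paraboloid") {
    2 * sqrt(R) * sqrt(delta)
  } else {
    # dF/ddelta = dF/da / (ddelta/da) = 2 a R / ... simplifies to 2 a / (ddelta/da)...
    # Use chain rule explicitly.
    a <- sneddon_contact_radius(delta, R)
    out <- numeric(length(delta))
    pos <- a > 0
    if (any(pos)) {
      ap <- a[pos]
      L <- log((R + ap) / (R - ap))
      dF_da <- ap * L + (ap^2 + R^2) / 2 * (1 / (R + ap) + 1 / (R - ap)) - R
      ddelta_da <- L / 2 + ap * R / (R^2 - ap^2)
      out[pos] <- dF_da / ddelta_da
    }
    out
  }
}

# Indentation depth at which the contact force reaches `force` (inverse model),
# at Young's modulus E. Monotone, solved by bisection.
contact_depth_at_force <- function(force, model, E) {
  stopifnot(force > 0)
  Ered <- E / (1 - model$nu^2)
  f <- function(d) Ered * contact_force_unit(d, model) - force
  # paraboloid inversion is closed-form; the sphere force is slightly below
  # the paraboloid at equal depth, so the sphere needs a bit more depth --
  # expand the bracket upward until the root is enclosed.
  hi <- (force / ((4 / 3) * Ered * sqrt(model$R)))^(2 / 3) * 1.0000001
  if (model$kind == "paraboloid")
    return(hi / 1.0000001)
  while (f(hi) < 0) hi <- hi * 1.5
  stats::uniroot(f, lower = 0, upper = hi, tol = 1e-15)$root
}
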