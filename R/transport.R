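## Closed-form 1-D advection-diffusion transport of a tracer from an overlying
## brine reservoir into sediment pore water (Ogata-Banks / Shackelford form).

#' Physical parameters of the 1-D brine-to-sediment transport model
#'
#' Bundles, for one tracer, the effective sediment diffusion coefficient
#' `Ds` (free-water diffusivity corrected for tortuosity), the average linear
#' pore-water velocity `Vs` (positive downward), the retardation factor `Rd`
#' (1 for nonreactive tracers such as Cl-), and the two concentration
#' end-members: `C0`, the brine-side boundary value held at the
#' sediment-water interface (z = 0), and `Cbg`, the far-field background the
#' profile relaxes to at depth (for Mediterranean settings, seawater values).
#'
#' The coefficient of hydrodynamic dispersion equals `Ds` when `Rd = 1`; the
#' `Rd` slot in the solution is honoured if a retarded tracer is supplied.
#'
#' @param Ds Effective sediment diffusion coefficient, m^2 s^-1. Must be > 0.
#' @param Vs Average linear pore-water (advection) velocity, m s^-1,
#'   positive downward. Must be >= 0.
#' @param C0 Tracer value in the brine at the sediment-water interface
#'   (mmol kg^-1 for ions; permil vs VSMOW for water isotopes).
#' @param Cbg Background (deep, far-field) tracer value, same units as `C0`.
#'   Equal to `C0` only in degenerate (constant-profile) cases.
#' @param Rd Retardation factor, dimensionless, >= 1. Default 1.
#' @return An object of class `transport_params`.
#' @examples
#' transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 4720, Cbg = 61)
#' @export
transport_params <- function(Ds, Vs, C0, Cbg = 0, Rd = 1) {
  stopifnot(is.numeric(Ds), length(Ds) == 1L,
            is.numeric(Vs), length(Vs) == 1L,
            is.numeric(C0), length(C0) == 1L,
            is.numeric(Cbg), length(Cbg) == 1L,
            is.numeric(Rd), length(Rd) == 1L)
  if (!all(is.finite(c(Ds, Vs, C0, Cbg, Rd))))
    stop("transport_params: all parameters must be finite", call. = FALSE)
  if (Ds <= 0) stop("transport_params: Ds must be > 0", call. = FALSE)
  if (Vs < 0) stop("transport_params: Vs must be >= 0 (positive downward)", call. = FALSE)
  if (Rd < 1) stop("transport_params: Rd must be >= 1", call. = FALSE)
  structure(list(Ds = Ds, Vs = Vs, C0 = C0, Cbg = Cbg, Rd = Rd),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  cat(sprintf("  Ds  = %.4g m^2/s   Vs = %.4g m/s   Rd = %g\n", x$Ds, x$Vs, x$Rd))
  cat(sprintf("  C0  = %.4g (brine boundary)   Cbg = %.4g (background)\n", x$C0, x$Cbg))
  invisible(x)
}

#' Depth-ordered tracer profile
#'
#' A set of tracer observations at strictly increasing depths below the
#' sediment-water interface (pore-water profiles) or below the top of the
#' halocline (interface profiles).
#'
#' @param depths Depths, m, z >= 0, strictly increasing, length >= 2.
#' @param values Tracer values at those depths; no missing values.
#' @param tracer Identity tag, e.g. `"Mg"`, `"Cl"`, `"dD"`.
#' @param units Unit tag, e.g. `"mmol/kg"` or `"permil"`.
#' @return An object of class `tracer_profile` (also a data.frame with
#'   columns `depth_m`, `value`).
#' @examples
#' tracer_profile(c(0, 0.5, 1), c(4720, 3000, 1500), tracer = "Mg")
#' @export
tracer_profile <- function(depths, values, tracer = "tracer", units = "mmol/kg") {
  depths <- as.numeric(depths); values <- as.numeric(values)
  if (length(depths) != length(values))
    stop("tracer_profile: depths and values must have the same length", call. = FALSE)
  if (length(depths) < 2L)
    stop("tracer_profile: need at least 2 observations", call. = FALSE)
  if (anyNA(depths) || anyNA(values) || !all(is.finite(c(depths, values))))
    stop("tracer_profile: missing or non-finite values are not allowed", call. = FALSE)
  if (any(depths < 0))
    stop("tracer_profile: depths must be >= 0 m", call. = FALSE)
  if (any(diff(depths) <= 0))
    stop("tracer_profile: depths must be strictly increasing", call. = FALSE)
  structure(data.frame(depth_m = depths, value = values),
            tracer = tracer, units = units,
            class = c("tracer_profile", "data.frame"))
}

#' @export
print.tracer_profile <- function(x, ...) {
  cat(sprintf("<tracer_profile> %s [%s], %d depths, %.3g-%.3g m\n",
              attr(x, "tracer"), attr(x, "units"), nrow(x),
              min(x$depth_m), max(x$depth_m)))
  print.data.frame(head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Scaled complementary error function erfcx(x) = exp(x^2) erfc(x), stable for
# all real x (the naive product overflows beyond x ~ 26). Computed in log
# space through pnorm's asymptotic tail expansion.
erfcx <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos))
    out[pos] <- exp(x[pos]^2 + log(2) + pnorm(-x[pos] * sqrt(2), log.p = TRUE))
  if (any(!pos)) # erfcx(-x) = 2 exp(x^2) - erfcx(x)
    out[!pos] <- 2 * exp(x[!pos]^2) -
      exp(x[!pos]^2 + log(2) + pnorm(x[!pos] * sqrt(2), log.p = TRUE))
  out
}

erfc <- function(x) 2 * pnorm(-x * sqrt(2))

# Dimensionless solution F(z, t) in [0, 1] of
#   dC/dt = Dh d2C/dz2 - Vs dC/dz,  C(0, t) = 1, C(z, 0) = 0,
# with Dh = Ds and the Rd slot honoured:
#   F = 1/2 [ erfc((z - Vs t) / (2 sqrt(Dh t / Rd)))
#           + exp(Vs z / Dh) erfc((z + Vs t) / (2 sqrt(Dh t / Rd))) ].
# The second term is evaluated as erfcx(b) * exp(a - b^2) with a = Vs z / Dh,
# b = (z + Vs t)/(2 sqrt(Dh t / Rd)); the exponent is expanded exactly as
#   a - b^2 = -[Rd z^2 + (2 Rd - 4) Vs z t + Rd (Vs t)^2] / (4 Dh t)
# so no catastrophic cancellation or overflow occurs at depth.
transport_F <- function(z, t, Ds, Vs, Rd = 1) {
  s <- 2 * sqrt(Ds * t / Rd)
  b <- (z + Vs * t) / s
  expo <- -(Rd * z^2 + (2 * Rd - 4) * Vs * z * t + Rd * (Vs * t)^2) / (4 * Ds * t)
  f <- 0.5 * (erfc((z - Vs * t) / s) + erfcx(b) * exp(expo))
  pmin(pmax(f, 0), 1)
}

#' Closed-form tracer concentration beneath a brine reservoir
#'
#' Analytical solution of the 1-D advection-diffusion equation
#' `dC/dt = Ds d2C/dz2 - Vs dC/dz` for a sediment column initially at the
#' background value `Cbg`, whose surface (z = 0) is held at the brine value
#' `C0` from time 0 onward:
#' `C(z,t) = Cbg + (C0 - Cbg) * F(z,t)` where `F` is the classical
#' complementary-error-function solution
#' `F = 1/2 [erfc((z - Vs t)/(2 sqrt(Dh t/Rd))) + exp(Vs z/Dh) erfc((z + Vs t)/(2 sqrt(Dh t/Rd)))]`
#' with `Dh = Ds`. The dimensionless kernel is mapped affinely onto
#' `[Cbg, C0]` so tracers with a non-zero deep background (e.g. deuterium
#' relaxing to seawater values) are handled by the same equation. The
#' `exp * erfc` product is evaluated through the scaled complementary error
#' function, so the solution is stable at any depth.
#'
#' @param z Depth below the sediment-water interface, m, >= 0 (vectorised).
#' @param t Time since brine emplacement, s, > 0 (scalar).
#' @param params A [transport_params()] object.
#' @return Tracer value(s) at depth `z` and time `t`, units of `C0`.
#' @examples
#' p <- transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 4720, Cbg = 61)
#' analytic_concentration(0, 2.2e10, p)       # boundary: 4720
#' analytic_concentration(c(0.5, 1, 2), 2.2e10, p)
#' @export
analytic_concentration <- function(z, t, params) {
  stopifnot(inherits(params, "transport_params"))
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("analytic_concentration: t must be a single finite value > 0", call. = FALSE)
  if (anyNA(z) || !all(is.finite(z)))
    stop("analytic_concentration: z must be finite", call. = FALSE)
  if (any(z < 0))
    stop("analytic_concentration: z must be >= 0 (m below interface)", call. = FALSE)
  f <- transport_F(z, t, params$Ds, params$Vs, params$Rd)
  params$Cbg + (params$C0 - params$Cbg) * f
}

#' Forward-model a full tracer profile
#'
#' Evaluates [analytic_concentration()] at each depth and wraps the result as
#' a [tracer_profile()]. For `C0 > Cbg` and `Vs >= 0` the modelled profile is
#' monotone non-increasing in depth.
#'
#' @inheritParams analytic_concentration
#' @param depths Depths, m, strictly increasing, length >= 2 (a single depth
#'   of 0 is also accepted and returns `C0`).
#' @param tracer,units Tags forwarded to [tracer_profile()].
#' @return A [tracer_profile()]; or a plain numeric value when a single depth
#'   is supplied.
#' @examples
#' p <- transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 4720, Cbg = 61)
#' profile_curve(seq(0, 3.2, by = 0.4), 2.2e10, p, tracer = "Mg")
#' @export
profile_curve <- function(depths, t, params, tracer = "tracer", units = "mmol/kg") {
  vals <- analytic_concentration(depths, t, params)
  if (length(depths) == 1L) return(vals)
  tracer_profile(depths, vals, tracer = tracer, units = units)
}

#' Convert model time in seconds to years
#'
#' Uses the Julian year, 1 yr = 3.15576e7 s (365.25 d), which reproduces the
#' conventional rounding of emplacement timings (2.2e10 s is about 700 yr,
#' 31.55e9 s about 1,000 yr, 63.1e9 s about 2,000 yr).
#'
#' @param t Time, s, >= 0 (vectorised).
#' @return Time in years.
#' @examples
#' seconds_to_years(2.2e10)   # 697.1
#' @export
seconds_to_years <- function(t) {
  if (anyNA(t) || !all(is.finite(t)) || any(t < 0))
    stop("seconds_to_years: t must be finite and >= 0", call. = FALSE)
  t / 3.15576e7
}

#' Years to seconds (inverse of [seconds_to_years()])
#' @param years Time in Julian years, >= 0.
#' @return Time in seconds.
#' @export
years_to_seconds <- function(years) {
  if (anyNA(years) || !all(is.finite(years)) || any(years < 0))
    stop("years_to_seconds: years must be finite and >= 0", call. = FALSE)
  years * 3.15576e7
}

#' Scale an effective sediment diffusion coefficient between tracers
#'
#' Adapts a free-water diffusivity to sediment conditions by the ratio
#' established for a reference tracer:
#' `Ds_target = Ds_ref * (Dfree_target / Dfree_ref)`. This is how the
#' deuterium sediment diffusivity is derived from the chloride one (the
#' tortuosity correction cancels in the ratio).
#'
#' @param Ds_ref Effective sediment diffusivity of the reference tracer,
#'   m^2 s^-1, > 0.
#' @param Dfree_ref Free-water diffusivity of the reference tracer, > 0.
#' @param Dfree_target Free-water diffusivity of the target tracer, > 0.
#' @return Effective sediment diffusivity of the target tracer, m^2 s^-1.
#' @examples
#' scale_diffusivity(2.4e-10, 2.40e-9, 2.96e-9)  # 2.96e-10
#' @export
scale_diffusivity <- function(Ds_ref, Dfree_ref, Dfree_target) {
  args <- c(Ds_ref, Dfree_ref, Dfree_target)
  if (anyNA(args) || !all(is.finite(args)) || any(args <= 0))
    stop("scale_diffusivity: all arguments must be finite and > 0", call. = FALSE)
  Ds_ref * (Dfree_target / Dfree_ref)
}
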