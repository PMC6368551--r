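## Seeded synthetic-data generators: pore-water profiles from the forward
## transport model, interface haloclines, and exact-mass peak lists. Each
## generator is a pure function of its arguments including the seed.

#' Measurement-noise specification
#'
#' @param kind `"relative-gaussian"` (sigma is a fraction of the true value)
#'   or `"absolute-gaussian"` (sigma in tracer units).
#' @param sigma Noise scale, >= 0. Defaults reflect typical instrument
#'   precision: 2% relative for ion chromatography, ~0.5 permil absolute for
#'   isotope-ratio measurements of dD.
#' @param seed Integer seed, or `NULL` for no reseeding.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("relative-gaussian", "absolute-gaussian"),
                       sigma = 0.02, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("noise_spec: sigma must be a single value >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, seed = seed), class = "noise_spec")
}

apply_noise <- function(values, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(values)
  gen <- function() {
    eps <- rnorm(length(values))
    if (noise$kind == "relative-gaussian") values * (1 + noise$sigma * eps)
    else values + noise$sigma * eps
  }
  if (is.null(noise$seed)) gen() else withr::with_seed(noise$seed, gen())
}

#' Bundled transport-parameter presets
#'
#' Forward-model parameter sets for the Mediterranean Ridge brine systems:
#' * `"hephaestus_mg"` — Mg2+, Ds 2.4e-10 m2/s, Vs 9.51e-11 m/s,
#'   C0 4720, Cbg 61 mmol/kg; default emplacement time 2.2e10 s (~700 yr).
#' * `"hephaestus_cl"` — Cl-, same transport constants, C0 9120,
#'   Cbg 630 mmol/kg.
#' * `"hephaestus_dD"` — deuterium, Ds 2.96e-10 m2/s (scaled from the
#'   chloride value by the free-water diffusivity ratio), C0 -16.5,
#'   Cbg +5.1 permil vs VSMOW; absolute 0.5-permil noise.
#' * `"discovery_cl"` — Cl- in Lake Discovery sediments, same transport
#'   constants, C0 10150, Cbg 630 mmol/kg; default time 63.1e9 s (~2000 yr).
#'
#' @param name Preset name.
#' @return A list: `params` ([transport_params()]), `t` (default time, s),
#'   `tracer`, `units`, `noise` (default [noise_spec()]).
#' @examples
#' transport_preset("hephaestus_mg")$params
#' @export
transport_preset <- function(name = c("hephaestus_mg", "hephaestus_cl",
                                      "hephaestus_dD", "discovery_cl")) {
  name <- match.arg(name)
  switch(name,
    hephaestus_mg = list(
      params = transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 4720, Cbg = 61),
      t = 2.2e10, tracer = "Mg", units = "mmol/kg",
      noise = noise_spec("relative-gaussian", 0.02)),
    hephaestus_cl = list(
      params = transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 9120, Cbg = 630),
      t = 2.2e10, tracer = "Cl", units = "mmol/kg",
      noise = noise_spec("relative-gaussian", 0.02)),
    hephaestus_dD = list(
      params = transport_params(Ds = 2.96e-10, Vs = 9.51e-11, C0 = -16.5, Cbg = 5.1),
      t = 2.2e10, tracer = "dD", units = "permil",
      noise = noise_spec("absolute-gaussian", 0.5)),
    discovery_cl = list(
      params = transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 10150, Cbg = 630),
      t = 63.1e9, tracer = "Cl", units = "mmol/kg",
      noise = noise_spec("relative-gaussian", 0.02)))
}

#' Generate a synthetic pore-water tracer profile
#'
#' Forward-models a profile with [profile_curve()] and adds seeded
#' measurement noise. With `sigma = 0` the output reproduces the noise-free
#' model curve exactly.
#'
#' @param params A [transport_params()], or a preset name accepted by
#'   [transport_preset()] (in which case `t`, tracer tag and default noise
#'   come from the preset unless overridden).
#' @param t Emplacement time, s (required when `params` is an object).
#' @param depths Sample depths, m; default a 3.2-m core sampled every 0.2 m
#'   below the interface.
#' @param noise A [noise_spec()].
#' @param seed Convenience override for `noise$seed`.
#' @return A [tracer_profile()] with attribute `truth` holding the
#'   generating parameters and noise-free values.
#' @examples
#' make_pore_profile("hephaestus_mg", seed = 1)
#' @export
make_pore_profile <- function(params, t = NULL,
                              depths = seq(0.1, 3.2, by = 0.2),
                              noise = NULL, seed = NULL) {
  if (is.character(params)) {
    pre <- transport_preset(params)
    if (is.null(t)) t <- pre$t
    if (is.null(noise)) noise <- pre$noise
    tracer <- pre$tracer; units <- pre$units
    params <- pre$params
  } else {
    stopifnot(inherits(params, "transport_params"))
    if (is.null(t)) stop("make_pore_profile: t is required", call. = FALSE)
    if (is.null(noise)) noise <- noise_spec("relative-gaussian", 0.02)
    tracer <- "tracer"; units <- "mmol/kg"
  }
  if (!is.null(seed)) noise$seed <- seed
  clean <- analytic_concentration(depths, t, params)
  prof <- tracer_profile(depths, apply_noise(clean, noise),
                         tracer = tracer, units = units)
  attr(prof, "truth") <- list(params = params, t = t, clean = clean,
                              noise = noise)
  prof
}

#' Generate a synthetic seawater-brine interface halocline
#'
#' Mg2+ vs depth through the halocline, monotone non-decreasing before
#' noise. Defaults reproduce the observed gradient: 70 mM at the top to
#' 4,720 mM at the brine contact over a 3.0-m interface.
#'
#' @param top_mg,bottom_mg Mg2+ at the top and bottom of the interface, mM.
#' @param thickness Interface thickness, m.
#' @param shape `"linear"` or `"logistic"` (sigmoidal halocline, steepness
#'   `k` in units of 1/m, centred mid-interface).
#' @param n Number of samples, evenly spaced from 0 to `thickness`.
#' @param noise A [noise_spec()]; default noiseless.
#' @param k Logistic steepness, 1/m (used only for `shape = "logistic"`).
#' @param seed Convenience override for `noise$seed`.
#' @return A [tracer_profile()] of Mg (mM) vs depth with a `truth` attribute.
#' @examples
#' make_interface_profile(n = 4, shape = "linear")$value  # 70 1620 3170 4720
#' @export
make_interface_profile <- function(top_mg = 70, bottom_mg = 4720,
                                   thickness = 3.0,
                                   shape = c("linear", "logistic"),
                                   n = 31L, noise = noise_spec(sigma = 0),
                                   k = 3, seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(top_mg >= 0, bottom_mg >= top_mg, thickness > 0, n >= 2L)
  if (!is.null(seed)) noise$seed <- seed
  z <- seq(0, thickness, length.out = n)
  frac <- if (shape == "linear") {
    z / thickness
  } else {
    raw <- 1 / (1 + exp(-k * (z - thickness / 2)))
    (raw - raw[1]) / (raw[n] - raw[1]) # pin endpoints to the printed gradient
  }
  clean <- top_mg + (bottom_mg - top_mg) * frac
  prof <- tracer_profile(z, apply_noise(clean, noise),
                         tracer = "Mg", units = "mM")
  attr(prof, "truth") <- list(clean = clean, shape = shape, noise = noise)
  prof
}

#' Generate a synthetic negative-mode peak list from known formulas
#'
#' Computes exact [M-H]- m/z values for the supplied compositions, applies
#' multiplicative ppm jitter `mz = exact * (1 + eps)`,
#' `eps ~ N(0, (ppm_jitter * 1e-6)^2)`, and draws log-normal intensities.
#' The ground-truth table is attached for recovery tests.
#'
#' @param formulas Data.frame with columns `nC, nH, nN, nO, nS`.
#' @param ppm_jitter Mass-error scale, ppm (0 gives exact masses).
#' @param intensity_mu,intensity_sigma Log-normal intensity parameters
#'   (meanlog / sdlog).
#' @param seed Integer seed.
#' @return Data.frame with columns `mz`, `intensity` and attribute `truth`
#'   (the input formulas plus their exact neutral and ion masses).
#' @export
make_peak_list <- function(formulas, ppm_jitter = 0.2,
                           intensity_mu = 10, intensity_sigma = 1,
                           seed = 1L) {
  stopifnot(is.data.frame(formulas),
            all(c("nC", "nH", "nN", "nO", "nS") %in% names(formulas)))
  neutral <- formula_mass(formulas$nC, formulas$nH, formulas$nN,
                          formulas$nO, formulas$nS)
  ion <- neutral - PROTON_MASS
  if (any(ion <= 0))
    stop("make_peak_list: formulas must be heavier than a proton", call. = FALSE)
  peaks <- withr::with_seed(seed, {
    eps <- rnorm(length(ion), 0, ppm_jitter * 1e-6)
    data.frame(mz = ion * (1 + eps),
               intensity = rlnorm(length(ion), intensity_mu, intensity_sigma))
  })
  truth <- formulas
  truth$neutral_mass <- neutral
  truth$mz_exact <- ion
  attr(peaks, "truth") <- truth
  peaks
}

#' Generate a synthetic DOM formula pool
#'
#' Draws a pool of elemental compositions with the statistical character of
#' sulfur-rich brine DOM: a CHO backbone with carbon numbers 6-30, H/C
#' drawn in 0.8-2.0 and O/C in 0.05-0.9 (then rounded to integer counts and
#' parity-adjusted so RDBE is a non-negative integer), nitrogen 0-3 and
#' sulfur 0-3 with sulfur-rich weights (about two thirds of compounds carry
#' S, emulating the sulfurized DOM of euxinic brines), and neutral masses
#' confined to `mass_range` (default 120-650 u; the pool's mean mass falls
#' near 380 u, consistent with small, highly processed DOM of mean
#' molecular weight below 500 u). All draws satisfy the default
#' [element_bounds()] filters, so every pool member is recoverable by
#' [decompose_mass()] at its exact mass.
#'
#' @param n Number of unique formulas.
#' @param seed Integer seed; the pool is a pure function of it.
#' @param mass_range Allowed neutral-mass window, u.
#' @return Data.frame of unique formulas with columns `nC, nH, nN, nO, nS`.
#' @export
synthetic_dom_formulas <- function(n, seed = 1L, mass_range = c(120, 650)) {
  stopifnot(n >= 1, length(mass_range) == 2L, mass_range[1] < mass_range[2])
  bounds <- element_bounds()
  withr::with_seed(seed, {
    out <- data.frame()
    tries <- 0L
    while (nrow(out) < n && tries < 200L) {
      tries <- tries + 1L
      m <- 3L * n
      nC <- sample(6:30, m, replace = TRUE)
      hc <- runif(m, 0.8, 2.0)
      oc <- runif(m, 0.05, 0.9)
      nH <- round(nC * hc)
      nO <- pmin(bounds$O[2], pmax(1L, round(nC * oc)))
      nN <- sample(0:3, m, replace = TRUE, prob = c(0.50, 0.25, 0.15, 0.10))
      nS <- sample(0:3, m, replace = TRUE, prob = c(0.35, 0.40, 0.20, 0.05))
      nH <- nH + (nH + nN) %% 2L # make RDBE an integer (even-electron)
      cand <- data.frame(nC = nC, nH = nH, nN = nN, nO = nO, nS = nS)
      rdbe <- rdbe_of(cand$nC, cand$nH, cand$nN)
      hc2 <- cand$nH / cand$nC
      mass <- formula_mass(cand$nC, cand$nH, cand$nN, cand$nO, cand$nS)
      ok <- rdbe >= 0 & rdbe <= bounds$rdbe_max &
        hc2 >= bounds$hc_range[1] & hc2 <= bounds$hc_range[2] &
        cand$nO / cand$nC <= bounds$oc_range[2] &
        mass >= mass_range[1] & mass <= mass_range[2] & cand$nH >= 1
      out <- unique(rbind(out, cand[ok, , drop = FALSE]))
    }
    if (nrow(out) < n)
      stop("synthetic_dom_formulas: could not draw enough formulas", call. = FALSE)
    out <- out[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Draw random in-bounds CHNOS formulas
#'
#' Uniform draws over the element boxes of `bounds`, rejection-sampled to
#' satisfy the H/C, O/C, RDBE >= 0, integer-RDBE and class (C, H, O > 0)
#' constraints and to stay under `max_mass`. Used to build synthetic DOM
#' pools for recovery simulations.
#'
#' @param n Number of formulas.
#' @param bounds An [element_bounds()].
#' @param seed Integer seed.
#' @param max_mass Upper neutral-mass cut, u (DOM compounds are small;
#'   default 800).
#' @return Data.frame of unique formulas with columns `nC, nH, nN, nO, nS`.
#' @export
random_formulas <- function(n, bounds = element_bounds(), seed = 1L,
                            max_mass = 800) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    out <- data.frame()
    tries <- 0L
    while (nrow(out) < n && tries < 200L) {
      tries <- tries + 1L
      m <- 4L * n
      cand <- data.frame(
        nC = sample(bounds$C[1]:bounds$C[2], m, replace = TRUE),
        nH = sample(bounds$H[1]:bounds$H[2], m, replace = TRUE),
        nN = sample(bounds$N[1]:bounds$N[2], m, replace = TRUE),
        nO = sample(max(1L, bounds$O[1]):bounds$O[2], m, replace = TRUE),
        nS = sample(bounds$S[1]:bounds$S[2], m, replace = TRUE))
      rdbe <- rdbe_of(cand$nC, cand$nH, cand$nN)
      hc <- cand$nH / cand$nC; oc <- cand$nO / cand$nC
      mass <- formula_mass(cand$nC, cand$nH, cand$nN, cand$nO, cand$nS)
      ok <- rdbe >= 0 & rdbe <= bounds$rdbe_max & rdbe %% 1 == 0 &
        hc >= bounds$hc_range[1] & hc <= bounds$hc_range[2] &
        oc >= bounds$oc_range[1] & oc <= bounds$oc_range[2] &
        mass <= max_mass
      out <- unique(rbind(out, cand[ok, , drop = FALSE]))
    }
    if (nrow(out) < n)
      stop("random_formulas: could not draw enough in-bounds formulas",
           call. = FALSE)
    out <- out[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
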