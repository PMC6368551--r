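## Mg2+ / water-activity structure of the seawater-brine interface: layer
## binning, monotone activity curves, and habitability boundaries.

# Named interface layers by Mg2+ concentration, mM. Sampled layer bounds are
# inclusive at both printed endpoints; the unsampled 1500-2080 and 2800-3050
# mM windows are a distinct GAP class rather than being absorbed into a
# neighbour.
layer_table <- function() {
  data.frame(
    name = c("SEAWATER", "UIF", "GAP", "MIF", "GAP", "LIF", "BRINE"),
    lo   = c(0,    70,   1500, 2080, 2800, 3050, 4120),
    hi   = c(70,   1500, 2080, 2800, 3050, 4120, Inf),
    lo_open = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    hi_open = c(TRUE,  FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
}

#' Assign an interface sample to a named layer by its Mg2+ concentration
#'
#' Layers of the seawater-brine halocline, by Mg2+ (mM): SEAWATER below
#' 70; UIF (upper interface) 70-1500; MIF (mid interface) 2080-2800;
#' LIF (lower interface) 3050-4120; BRINE above 4120. The two unsampled
#' windows between named fractions, (1500, 2080) and (2800, 3050) mM,
#' are reported as GAP. Sampled-layer bounds are inclusive at both ends.
#'
#' @param mg Mg2+ concentration(s), mM, >= 0 (vectorised).
#' @return Character vector of layer names.
#' @examples
#' assign_layer(c(10, 1000, 1800, 2500, 2970, 3500, 4500))
#' @export
assign_layer <- function(mg) {
  if (anyNA(mg) || !all(is.finite(mg)) || any(mg < 0))
    stop("assign_layer: mg must be finite and >= 0 (mM)", call. = FALSE)
  lt <- layer_table()
  vapply(mg, function(m) {
    for (i in seq_len(nrow(lt))) {
      above <- if (lt$lo_open[i]) m > lt$lo[i] else m >= lt$lo[i]
      below <- if (lt$hi_open[i]) m < lt$hi[i] else m <= lt$hi[i]
      if (above && below) return(lt$name[i])
    }
    "BRINE" # unreachable: table covers [0, Inf)
  }, character(1))
}

#' Water-activity anchor measurements
#'
#' @param conc MgCl2 concentrations, mol L^-1, >= 0.
#' @param aw Water activities in (0, 1] measured at those concentrations.
#' @param source Label for the brine system the anchors belong to; anchors
#'   from different systems must not be mixed into one curve (water activity
#'   depends on the full ion composition, not MgCl2 alone).
#' @return A data.frame of anchors, class `activity_anchors`.
#' @export
activity_anchors <- function(conc, aw, source = "hephaestus") {
  conc <- as.numeric(conc); aw <- as.numeric(aw)
  stopifnot(length(conc) == length(aw))
  if (anyNA(conc) || anyNA(aw) || any(conc < 0) || any(aw <= 0) || any(aw > 1))
    stop("activity_anchors: need conc >= 0 and 0 < aw <= 1", call. = FALSE)
  structure(data.frame(conc = conc, aw = aw, source = source),
            class = c("activity_anchors", "data.frame"))
}

#' Default water-activity anchors for the Lake Hephaestus system
#'
#' Sparse three-point anchor set: Mediterranean seawater (0.061 M Mg2+,
#' a_w 0.980), the deepest biologically active interface layer (2.97 M,
#' a_w 0.653) and the brine itself (4.72 M, a_w 0.395).
#'
#' @return An [activity_anchors()] data.frame.
#' @export
hephaestus_anchors <- function() {
  activity_anchors(conc = c(0.061, 2.97, 4.72),
                   aw = c(0.980, 0.653, 0.395),
                   source = "hephaestus")
}

#' Fit a monotone water-activity curve through measured anchors
#'
#' Shape-preserving monotone cubic interpolation (Fritsch-Carlson monotone
#' Hermite, PCHIP-type) of water activity against MgCl2 concentration. The
#' interpolant passes through every anchor exactly and is strictly
#' decreasing between anchors; anchor sets that are not strictly decreasing
#' in a_w with concentration are rejected (for a single brine system a_w
#' must fall as MgCl2 rises). Queries outside the anchored range are refused
#' rather than extrapolated.
#'
#' @param anchors An [activity_anchors()] data.frame (or any data.frame with
#'   `conc` and `aw` columns), >= 2 rows, distinct concentrations, a single
#'   `source`.
#' @return An object of class `activity_curve`: callable as `curve_fun(conc)`
#'   through [predict_aw()], with fields `anchors` and `interpolant`.
#' @examples
#' cv <- fit_activity_curve(hephaestus_anchors())
#' predict_aw(cv, c(0.061, 1, 2.97, 4.72))
#' @export
fit_activity_curve <- function(anchors) {
  if (!is.data.frame(anchors) || !all(c("conc", "aw") %in% names(anchors)))
    stop("fit_activity_curve: anchors need conc and aw columns", call. = FALSE)
  if (nrow(anchors) < 2L)
    stop("fit_activity_curve: need at least 2 anchors", call. = FALSE)
  if ("source" %in% names(anchors) && length(unique(anchors$source)) > 1L)
    stop(paste("fit_activity_curve: anchors mix brine systems",
               paste(unique(anchors$source), collapse = ", "),
               "- fit one curve per system (a_w depends on full ion composition)"),
         call. = FALSE)
  ord <- order(anchors$conc)
  conc <- anchors$conc[ord]; aw <- anchors$aw[ord]
  if (any(duplicated(conc)))
    stop("fit_activity_curve: anchor concentrations must be distinct", call. = FALSE)
  if (any(diff(aw) >= 0))
    stop("fit_activity_curve: a_w must be strictly decreasing with concentration",
         call. = FALSE)
  f <- splinefun(conc, aw, method = "monoH.FC")
  structure(list(anchors = data.frame(conc = conc, aw = aw),
                 interpolant = f,
                 range = range(conc)),
            class = "activity_curve")
}

#' Evaluate a fitted activity curve
#'
#' @param curve An `activity_curve` from [fit_activity_curve()].
#' @param conc MgCl2 concentration(s), mol L^-1, within the anchored range.
#' @return Interpolated water activity value(s).
#' @export
predict_aw <- function(curve, conc) {
  stopifnot(inherits(curve, "activity_curve"))
  if (anyNA(conc) || !all(is.finite(conc)))
    stop("predict_aw: conc must be finite", call. = FALSE)
  if (any(conc < curve$range[1] - 1e-12) || any(conc > curve$range[2] + 1e-12))
    stop(sprintf("predict_aw: conc outside anchored range [%g, %g] M",
                 curve$range[1], curve$range[2]), call. = FALSE)
  curve$interpolant(pmin(pmax(conc, curve$range[1]), curve$range[2]))
}

#' @export
print.activity_curve <- function(x, ...) {
  cat(sprintf("<activity_curve> %d anchors, conc %g-%g M, a_w %g-%g\n",
              nrow(x$anchors), x$range[1], x$range[2],
              min(x$anchors$aw), max(x$anchors$aw)))
  invisible(x)
}

#' Locate the depth at which water activity crosses a threshold
#'
#' Converts an Mg2+-vs-depth interface profile to water activity through a
#' fitted [fit_activity_curve()], then finds the depth at which the
#' interpolated a_w crosses `aw_threshold` (linear interpolation in depth
#' between adjacent samples; the shallowest crossing is reported). The
#' default threshold, 0.585, is the recognized water-activity limit for
#' cell division.
#'
#' @param interface_profile A [tracer_profile()] of Mg2+ (mM) vs depth (m),
#'   Mg non-decreasing with depth.
#' @param curve An `activity_curve`; the profile's Mg range must lie within
#'   its anchored range.
#' @param aw_threshold Water-activity threshold, default 0.585.
#' @return A list: `status` (`"crossed"` or `"not-crossed"`) and `depth_m`
#'   (numeric, `NA` when not crossed).
#' @examples
#' prof <- make_interface_profile(n = 31, noise = noise_spec(sigma = 0))
#' cv <- fit_activity_curve(hephaestus_anchors())
#' locate_threshold_depth(prof, cv)
#' @export
locate_threshold_depth <- function(interface_profile, curve, aw_threshold = 0.585) {
  stopifnot(inherits(interface_profile, "tracer_profile"),
            inherits(curve, "activity_curve"))
  if (aw_threshold <= 0 || aw_threshold >= 1)
    stop("locate_threshold_depth: threshold must be in (0, 1)", call. = FALSE)
  z <- interface_profile$depth_m
  aw <- predict_aw(curve, interface_profile$value / 1000) # mM -> M
  if (all(aw > aw_threshold) || all(aw < aw_threshold))
    return(list(status = "not-crossed", depth_m = NA_real_))
  # first index where a_w falls to/through the threshold
  hit <- which(aw <= aw_threshold)[1]
  if (hit == 1L) return(list(status = "crossed", depth_m = z[1]))
  z0 <- z[hit - 1L]; z1 <- z[hit]
  a0 <- aw[hit - 1L]; a1 <- aw[hit]
  depth <- if (a0 == a1) z1 else z0 + (a0 - aw_threshold) / (a0 - a1) * (z1 - z0)
  list(status = "crossed", depth_m = depth)
}

#' Classify the habitability of an interface sample
#'
#' Evaluates both habitability criteria for a sample at Mg2+ concentration
#' `mg`: the empirically observed limit for active microbial communities
#' (no activity below the 2,970 mM Mg2+ layer) and the recognized
#' water-activity limit for cell division (a_w = 0.585), via the fitted
#' activity curve. Both criterion outcomes are reported; the summary status
#' is `below-observed-limit` when mg exceeds the observed limit,
#' otherwise `below-aw-limit` when the local a_w is under the threshold,
#' otherwise `active-window`.
#'
#' @param mg Mg2+ concentration, mM.
#' @param curve An `activity_curve` covering `mg`.
#' @param limits List with `recognized_aw_limit` (default 0.585) and
#'   `observed_mg_limit` (default 2970 mM).
#' @return A list: `status`, `aw` (interpolated), `below_observed_limit`,
#'   `below_aw_limit` (logicals).
#' @examples
#' cv <- fit_activity_curve(hephaestus_anchors())
#' classify_habitability(1000, cv)$status   # "active-window"
#' classify_habitability(3500, cv)$status   # "below-observed-limit"
#' @export
classify_habitability <- function(mg, curve,
                                  limits = list(recognized_aw_limit = 0.585,
                                                observed_mg_limit = 2970)) {
  stopifnot(inherits(curve, "activity_curve"), length(mg) == 1L, mg >= 0)
  aw <- predict_aw(curve, mg / 1000)
  below_obs <- mg > limits$observed_mg_limit
  below_aw <- aw < limits$recognized_aw_limit
  status <- if (below_obs) "below-observed-limit"
            else if (below_aw) "below-aw-limit"
            else "active-window"
  list(status = status, aw = aw,
       below_observed_limit = below_obs, below_aw_limit = below_aw)
}
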