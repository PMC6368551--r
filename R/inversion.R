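## Inversion of the closed-form transport model: estimate the sediment-brine
## contact time (or one other free parameter) by bounded least squares.

#' Fitted sediment-brine contact time
#'
#' Constructor for the result of [fit_age()]; rarely called directly.
#'
#' @param t_seconds Fitted contact time, s, > 0.
#' @param rss Residual sum of squares at the optimum (standardized units^2
#'   for joint fits).
#' @param n_obs Number of observations used.
#' @param per_tracer_rss Named numeric of per-tracer (unstandardized) RSS.
#' @param ci_years Optional c(lower, upper) bootstrap interval, years.
#' @param convergence Logical, TRUE when at least one start converged.
#' @return An object of class `age_estimate`.
#' @export
age_estimate <- function(t_seconds, rss, n_obs, per_tracer_rss = NULL,
                         ci_years = NULL, convergence = TRUE) {
  stopifnot(t_seconds > 0, rss >= 0, n_obs >= 1)
  t_years <- seconds_to_years(t_seconds)
  if (!is.null(ci_years)) {
    stopifnot(length(ci_years) == 2L)
    if (ci_years[1] > t_years || ci_years[2] < t_years)
      stop("age_estimate: interval must contain the point estimate", call. = FALSE)
  }
  structure(list(t_seconds = t_seconds, t_years = t_years, rss = rss,
                 n_obs = n_obs, per_tracer_rss = per_tracer_rss,
                 ci_years = ci_years, convergence = convergence),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("<age_estimate> t = %.4g s = %.1f yr (rss %.4g, n %d)\n",
              x$t_seconds, x$t_years, x$rss, x$n_obs))
  if (!is.null(x$ci_years))
    cat(sprintf("  95%%-type bootstrap CI: [%.1f, %.1f] yr\n",
                x$ci_years[1], x$ci_years[2]))
  if (!is.null(x$per_tracer_rss)) {
    cat("  per-tracer rss:",
        paste(sprintf("%s=%.4g", names(x$per_tracer_rss), x$per_tracer_rss),
              collapse = "  "), "\n")
  }
  invisible(x)
}

# Standardized sum of squared residuals at time t across tracers. Each
# tracer's residuals are divided by its |C0 - Cbg| span so, e.g., a ~4,700 mM
# magnesium profile and a ~20 permil deuterium profile contribute comparably
# to a joint fit.
age_objective <- function(t, profiles, params_list) {
  tot <- 0
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]; pp <- params_list[[i]]
    span <- abs(pp$C0 - pp$Cbg)
    if (span == 0) span <- 1
    pred <- analytic_concentration(pr$depth_m, t, pp)
    tot <- tot + sum(((pr$value - pred) / span)^2)
  }
  tot
}

normalize_fit_inputs <- function(profiles, params) {
  if (inherits(profiles, "tracer_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L)
    stop("fit_age: at least one profile is required", call. = FALSE)
  if (inherits(params, "transport_params"))
    params <- rep(list(params), length(profiles))
  if (length(params) != length(profiles))
    stop("fit_age: need one transport_params per profile", call. = FALSE)
  for (pr in profiles) {
    if (!inherits(pr, "tracer_profile"))
      stop("fit_age: profiles must be tracer_profile objects", call. = FALSE)
    if (nrow(pr) < 3L)
      stop("fit_age: each profile needs at least 3 points", call. = FALSE)
  }
  list(profiles = profiles, params = params)
}

#' Estimate the sediment-brine contact time from pore-water profiles
#'
#' Finds the emplacement time `t` minimizing the summed squared residuals
#' between observed tracer profiles and the closed-form transport model,
#' each tracer standardized by its concentration span `|C0 - Cbg|` so that
#' jointly fitted tracers with very different units contribute comparably.
#' The search is a bounded scalar minimization over `log10(t)` (ages span
#' decades), restarted from `n_starts` log-spaced subintervals of the bounds;
#' the best converged start is returned.
#'
#' @param profiles A [tracer_profile()] or list of them (>= 3 points each).
#' @param params A [transport_params()] (recycled) or a list, one per profile.
#' @param t_bounds Search bounds on t, s, `c(lower, upper)`, 0 < lower < upper.
#' @param n_starts Number of log-spaced subinterval starts (>= 1; default 3).
#' @param tol Relative tolerance on log10(t) (default 1e-10).
#' @return An [age_estimate()].
#' @examples
#' p <- transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 4720, Cbg = 61)
#' prof <- profile_curve(seq(0.1, 3.2, by = 0.25), 2.2e10, p, tracer = "Mg")
#' fit_age(prof, p)$t_years   # ~697
#' @export
fit_age <- function(profiles, params, t_bounds = c(1e8, 1e12),
                    n_starts = 3L, tol = 1e-10) {
  ins <- normalize_fit_inputs(profiles, params)
  profiles <- ins$profiles; params_list <- ins$params
  if (length(t_bounds) != 2L || any(t_bounds <= 0) || t_bounds[1] >= t_bounds[2])
    stop("fit_age: t_bounds must be positive with lower < upper", call. = FALSE)

  obj_log <- function(lt) age_objective(10^lt, profiles, params_list)
  lo <- log10(t_bounds[1]); hi <- log10(t_bounds[2])
  cuts <- seq(lo, hi, length.out = n_starts + 1L)
  best <- NULL
  for (k in seq_len(n_starts)) {
    opt <- tryCatch(
      optimize(obj_log, lower = cuts[k], upper = cuts[k + 1L],
               tol = tol * max(1, abs(hi))),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best))
    stop("fit_age: optimizer failed to converge at all starts", call. = FALSE)
  # polish across subinterval boundaries
  wl <- max(lo, best$minimum - (hi - lo) / n_starts)
  wu <- min(hi, best$minimum + (hi - lo) / n_starts)
  pol <- optimize(obj_log, lower = wl, upper = wu, tol = tol * max(1, abs(hi)))
  if (pol$objective < best$objective) best <- pol

  t_hat <- 10^best$minimum
  per <- vapply(seq_along(profiles), function(i) {
    pred <- analytic_concentration(profiles[[i]]$depth_m, t_hat, params_list[[i]])
    sum((profiles[[i]]$value - pred)^2)
  }, numeric(1))
  names(per) <- vapply(profiles, function(p) attr(p, "tracer"), character(1))
  age_estimate(t_hat, rss = best$objective,
               n_obs = sum(vapply(profiles, nrow, integer(1))),
               per_tracer_rss = per)
}

#' Fit one free transport parameter with the others fixed
#'
#' One-dimensional bounded least squares for exactly one of `t`, `Ds`, `Vs`
#' or `C0`, holding the remaining parameters at the values in `params` (and,
#' for the non-time parameters, at the fixed time `t`). This mirrors the
#' treatment of the deuterium profile, whose sediment diffusivity is fitted
#' with timing shared with the ionic tracers. `t` and `Ds` are searched on a
#' log10 scale; `Vs` and `C0` on a linear scale (their bounds may include 0
#' or negative values).
#'
#' Fitting `t` and `Ds` simultaneously is refused: at small advection they
#' enter the solution essentially as the product `Ds * t` and are not
#' separately identifiable from a single profile.
#'
#' @param profile A [tracer_profile()] (>= 3 points).
#' @param params A [transport_params()] holding the fixed values.
#' @param free One of `"t"`, `"Ds"`, `"Vs"`, `"C0"` (exactly one).
#' @param t Fixed model time, s, required unless `free = "t"`.
#' @param bounds `c(lower, upper)` search bounds for the free parameter.
#' @param n_starts,tol As in [fit_age()].
#' @return A list with `free`, `value` (fitted parameter), and `rss`.
#' @examples
#' p <- transport_params(Ds = 2.96e-10, Vs = 9.51e-11, C0 = -16.5, Cbg = 5.1)
#' prof <- profile_curve(seq(0.1, 3.2, by = 0.25), 2.2e10, p, tracer = "dD")
#' fit_free_parameter(prof, p, free = "Ds", t = 2.2e10,
#'                    bounds = c(1e-11, 1e-9))$value  # ~2.96e-10
#' @export
fit_free_parameter <- function(profile, params, free, t = NULL, bounds,
                               n_starts = 3L, tol = 1e-10) {
  stopifnot(inherits(profile, "tracer_profile"),
            inherits(params, "transport_params"))
  if (nrow(profile) < 3L)
    stop("fit_free_parameter: profile needs at least 3 points", call. = FALSE)
  if (length(free) != 1L)
    stop(paste("fit_free_parameter: exactly one free parameter; t and Ds are",
               "not jointly identifiable (they enter as Ds*t at small Vs)"),
         call. = FALSE)
  if (!free %in% c("t", "Ds", "Vs", "C0"))
    stop("fit_free_parameter: free must be one of t, Ds, Vs, C0", call. = FALSE)
  if (free != "t" && (is.null(t) || t <= 0))
    stop("fit_free_parameter: a fixed t > 0 is required", call. = FALSE)
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("fit_free_parameter: bounds must satisfy lower < upper", call. = FALSE)

  make_obj <- function(value) {
    pl <- unclass(params)
    tt <- t
    if (free == "t") tt <- value else pl[[free]] <- value
    p2 <- transport_params(pl$Ds, pl$Vs, pl$C0, pl$Cbg, pl$Rd)
    pred <- analytic_concentration(profile$depth_m, tt, p2)
    sum((profile$value - pred)^2)
  }

  log_scale <- free %in% c("t", "Ds")
  if (log_scale && any(bounds <= 0))
    stop("fit_free_parameter: bounds for t or Ds must be > 0", call. = FALSE)
  tr <- if (log_scale) log10 else identity
  itr <- if (log_scale) function(x) 10^x else identity
  lo <- tr(bounds[1]); hi <- tr(bounds[2])
  cuts <- seq(lo, hi, length.out = n_starts + 1L)
  best <- NULL
  for (k in seq_len(n_starts)) {
    opt <- tryCatch(
      optimize(function(u) make_obj(itr(u)), lower = cuts[k], upper = cuts[k + 1L],
               tol = tol * max(1, abs(hi), abs(lo))),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best))
    stop("fit_free_parameter: optimizer failed at all starts", call. = FALSE)
  wl <- max(lo, best$minimum - (hi - lo) / n_starts)
  wu <- min(hi, best$minimum + (hi - lo) / n_starts)
  pol <- optimize(function(u) make_obj(itr(u)), lower = wl, upper = wu,
                  tol = tol * max(1, abs(hi), abs(lo)))
  if (pol$objective < best$objective) best <- pol
  # degenerate optima hugging a linear-scale lower bound (e.g. Vs* = 0): accept
  val <- itr(best$minimum)
  if (!log_scale) {
    for (edge in bounds) {
      if (make_obj(edge) <= best$objective) { val <- edge; best$objective <- make_obj(edge) }
    }
  }
  list(free = free, value = val, rss = best$objective)
}

#' Residual-resampling bootstrap interval for the fitted age
#'
#' Refits the contact time on `n_boot` pseudo-profiles built by adding
#' resampled (with replacement) model residuals back onto the fitted curve,
#' preserving the fixed depth design (depths are set by coring, not sampled
#' at random). Returns the percentile interval in years. The interval is
#' widened, if necessary, to include the point estimate (relevant only in
#' near-degenerate noise-free cases where all refits coincide).
#'
#' @inheritParams fit_age
#' @param profile A single [tracer_profile()].
#' @param n_boot Number of bootstrap refits, >= 2 (>= 100 recommended).
#' @param seed Integer seed; the resampling is fully reproducible given it.
#' @param level Interval level, default 0.95.
#' @return An [age_estimate()] with `ci_years` filled in.
#' @export
bootstrap_age_ci <- function(profile, params, n_boot = 1000L, seed = 1L,
                             level = 0.95, t_bounds = c(1e8, 1e12)) {
  stopifnot(inherits(profile, "tracer_profile"))
  if (n_boot < 2L)
    stop("bootstrap_age_ci: n_boot must be >= 2", call. = FALSE)
  est <- fit_age(profile, params, t_bounds = t_bounds)
  fitted <- analytic_concentration(profile$depth_m, est$t_seconds, params)
  res <- profile$value - fitted
  n <- length(res)
  # refit bounds: a generous window around the point estimate, inside t_bounds
  bw <- c(max(t_bounds[1], est$t_seconds / 100), min(t_bounds[2], est$t_seconds * 100))
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- tracer_profile(profile$depth_m, fitted + res[idx],
                           tracer = attr(profile, "tracer"),
                           units = attr(profile, "units"))
      fit_age(pb, params, t_bounds = bw, n_starts = 1L)$t_seconds
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- seconds_to_years(unname(quantile(boots, c(alpha, 1 - alpha), type = 7)))
  ci[1] <- min(ci[1], est$t_years); ci[2] <- max(ci[2], est$t_years)
  age_estimate(est$t_seconds, est$rss, est$n_obs,
               per_tracer_rss = est$per_tracer_rss, ci_years = ci)
}

#' Signed difference between two fitted ages
#'
#' @param a,b [age_estimate()] objects (or numbers of years).
#' @return `b - a` in years: positive when `b` is older.
#' @examples
#' compare_ages(700, 2000)  # 1300
#' @export
compare_ages <- function(a, b) {
  ay <- if (inherits(a, "age_estimate")) a$t_years else as.numeric(a)
  by <- if (inherits(b, "age_estimate")) b$t_years else as.numeric(b)
  if (!is.finite(ay) || !is.finite(by))
    stop("compare_ages: both ages must be finite", call. = FALSE)
  by - ay
}
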