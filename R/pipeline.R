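## End-to-end orchestration: run the dating, interface-habitability and DOM
## stages from a single config and emit a structured, diffable report.

#' Run the full brine-analysis pipeline
#'
#' Executes, per the stages present in `config`:
#' * `ages` — [fit_age()] per tracer and jointly across tracers (residuals
#'   standardized by tracer span), with optional bootstrap intervals;
#' * `interface` — activity-curve fit, layer assignment, threshold-depth
#'   location and habitability classification of an Mg interface profile;
#' * `dom` — formula assignment, class counts/ratios, van Krevelen summary
#'   and sulfur histogram for one or more peak lists, plus pairwise
#'   unique/shared fractions.
#'
#' Stages whose inputs are absent are marked `"skipped"`; a stage failure is
#' caught and reported per-stage (`status = "error"`) without aborting the
#' others. Reruns with the same config are deterministic.
#'
#' @param config A list (or path to a YAML file) with any of:
#'   `tracers` — named list, each with `profile` (a [tracer_profile()] or a
#'   CSV path), `params` (a [transport_params()] or Ds/Vs/C0/Cbg keys) and
#'   optional `t_bounds`;
#'   `boot` — list(n_boot, seed, level) to add bootstrap intervals;
#'   `interface` — list(profile, anchors, aw_threshold);
#'   `dom` — list(peaks = named list of peak data.frames/paths, bounds);
#'   `seed` — integer master seed.
#' @return A list of class `brine_report` with elements `meta`, `ages`,
#'   `interface`, `dom`; each stage carries a `status` field.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  report <- list(meta = list(package = "brinetrace",
                             version = as.character(utils::packageVersion("brinetrace")),
                             seed = config$seed))
  report$ages <- run_stage(function() stage_ages(config), "ages",
                           !is.null(config$tracers))
  report$interface <- run_stage(function() stage_interface(config), "interface",
                                !is.null(config$interface))
  report$dom <- run_stage(function() stage_dom(config), "dom",
                          !is.null(config$dom))
  class(report) <- "brine_report"
  report
}

run_stage <- function(fn, name, present) {
  if (!present) return(list(status = "skipped"))
  tryCatch(c(list(status = "ok"), fn()),
           error = function(e) list(status = "error",
                                    message = conditionMessage(e)))
}

resolve_profile <- function(x) {
  if (inherits(x, "tracer_profile")) x else read_tracer_profile(x)
}

resolve_params <- function(x) {
  if (inherits(x, "transport_params")) return(x)
  transport_params(Ds = x$Ds, Vs = x$Vs, C0 = x$C0,
                   Cbg = if (is.null(x$Cbg)) 0 else x$Cbg,
                   Rd = if (is.null(x$Rd)) 1 else x$Rd)
}

stage_ages <- function(config) {
  tracers <- config$tracers
  profs <- lapply(tracers, function(b) resolve_profile(b$profile))
  pars <- lapply(tracers, function(b) resolve_params(b$params))
  bounds <- config$t_bounds %||% c(1e8, 1e12)
  per <- lapply(seq_along(tracers), function(i) {
    est <- fit_age(profs[[i]], pars[[i]], t_bounds = bounds)
    if (!is.null(config$boot)) {
      b <- config$boot
      est <- bootstrap_age_ci(profs[[i]], pars[[i]],
                              n_boot = b$n_boot %||% 1000L,
                              seed = b$seed %||% config$seed %||% 1L,
                              level = b$level %||% 0.95,
                              t_bounds = bounds)
    }
    list(t_seconds = est$t_seconds, t_years = est$t_years, rss = est$rss,
         n_obs = est$n_obs, ci_years = est$ci_years)
  })
  names(per) <- names(tracers)
  joint <- if (length(tracers) > 1L) {
    est <- fit_age(profs, pars, t_bounds = bounds)
    list(t_seconds = est$t_seconds, t_years = est$t_years,
         rss = est$rss, per_tracer_rss = as.list(est$per_tracer_rss))
  } else NULL
  list(per_tracer = per, joint = joint)
}

stage_interface <- function(config) {
  ic <- config$interface
  prof <- resolve_profile(ic$profile)
  anchors <- if (is.null(ic$anchors)) hephaestus_anchors()
             else if (is.character(ic$anchors)) read_activity_anchors(ic$anchors)
             else ic$anchors
  curve <- fit_activity_curve(anchors)
  thr <- ic$aw_threshold %||% 0.585
  cross <- locate_threshold_depth(prof, curve, thr)
  lay <- assign_layer(prof$value)
  hab <- lapply(prof$value, function(m) classify_habitability(m, curve))
  list(aw_threshold = thr,
       threshold_depth_m = cross$depth_m,
       threshold_status = cross$status,
       samples = data.frame(depth_m = prof$depth_m, mg_mM = prof$value,
                            layer = lay,
                            aw = vapply(hab, `[[`, numeric(1), "aw"),
                            status = vapply(hab, `[[`, character(1), "status")))
}

stage_dom <- function(config) {
  dc <- config$dom
  bounds <- dc$bounds %||% element_bounds()
  peaks <- lapply(dc$peaks, function(p) {
    if (is.character(p)) read_peak_list(p) else p
  })
  assigned <- lapply(peaks, assign_formulas, bounds = bounds)
  summaries <- lapply(assigned, function(a) {
    vk <- van_krevelen(a)
    list(n_assigned = nrow(a),
         class_counts = as.list(table(a$cls)),
         chos_cho = class_ratio(a, "CHOS", "CHO")$ratio,
         chnos_chno = class_ratio(a, "CHNOS", "CHNO")$ratio,
         pct_highly_oxygenated = if (nrow(vk)) mean(vk$highly_oxygenated) * 100
                                 else NA_real_,
         sulfur_histogram = as.list(sulfur_histogram(a)))
  })
  comparisons <- NULL
  if (length(assigned) >= 2L) {
    nm <- names(assigned)
    combs <- utils::combn(seq_along(assigned), 2, simplify = FALSE)
    comparisons <- lapply(combs, function(ij) {
      u <- unique_shared_fraction(assigned[[ij[1]]], assigned[[ij[2]]])
      list(a = nm[ij[1]], b = nm[ij[2]],
           pct_unique = u$pct_unique, pct_shared = u$pct_shared)
    })
  }
  list(samples = summaries, comparisons = comparisons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report to JSON
#'
#' The report body is deterministic for a given config; the only volatile
#' fields (timestamp) live in the header so report bodies are diffable.
#'
#' @param report A `brine_report` from [run_pipeline()].
#' @param path Output path (`.json`).
#' @param timestamp Include a header timestamp (default TRUE; disable for
#'   byte-identical reruns).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, timestamp = TRUE) {
  stopifnot(inherits(report, "brine_report"))
  out <- unclass(report)
  out$meta$written <- if (timestamp) format(Sys.time(), tz = "UTC") else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}

#' @export
print.brine_report <- function(x, ...) {
  cat("<brine_report>\n")
  for (st in c("ages", "interface", "dom"))
    cat(sprintf("  %-10s %s\n", st, x[[st]]$status))
  if (identical(x$ages$status, "ok")) {
    for (nm in names(x$ages$per_tracer))
      cat(sprintf("    %s: %.0f yr\n", nm, x$ages$per_tracer[[nm]]$t_years))
  }
  invisible(x)
}
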