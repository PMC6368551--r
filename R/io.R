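## Delimited-text I/O: tracer profiles, transport-parameter configs,
## activity anchors, and mass-peak lists.

#' Write a tracer profile as CSV
#'
#' Two columns (`depth_m`, `value`) preceded by `# tracer=` and `# units=`
#' metadata comment lines.
#'
#' @param profile A [tracer_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracer_profile <- function(profile, path) {
  stopifnot(inherits(profile, "tracer_profile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# tracer=%s", attr(profile, "tracer")),
               sprintf("# units=%s", attr(profile, "units")),
               "depth_m,value"), con)
  write.table(as.data.frame(profile)[, c("depth_m", "value")], con,
              sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tracer profile CSV written by [write_tracer_profile()]
#'
#' @param path Input file path.
#' @return A [tracer_profile()].
#' @export
read_tracer_profile <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_tag <- function(tag, default) {
    hit <- grep(sprintf("^#\\s*%s=", tag), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(sprintf("^#\\s*%s=", tag), "", hit[1])
  }
  df <- read.table(text = lines[!grepl("^#", lines)], sep = ",", header = TRUE)
  if (!all(c("depth_m", "value") %in% names(df)))
    stop("read_tracer_profile: need columns depth_m, value", call. = FALSE)
  tracer_profile(df$depth_m, df$value,
                 tracer = get_tag("tracer", "tracer"),
                 units = get_tag("units", "unknown"))
}

#' Read transport parameters from a YAML config
#'
#' One named block per tracer, each with keys `Ds`, `Vs`, `C0`, `Cbg` and
#' optionally `Rd`, `t`. Example:
#' ```
#' hephaestus_mg:
#'   Ds: 2.4e-10
#'   Vs: 9.51e-11
#'   C0: 4720
#'   Cbg: 61
#' ```
#'
#' @param path YAML file path.
#' @return Named list; each element a list with `params`
#'   ([transport_params()]) and any extra keys (e.g. `t`).
#' @export
read_transport_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML only treats exponents with an explicit sign (2.4e-10) as numbers;
  # plain "2.2e10" arrives as a string, and whole numbers as integers
  num <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      y <- suppressWarnings(as.numeric(x))
      if (length(y) == length(x) && !anyNA(y)) return(y)
      return(x)
    }
    if (is.numeric(x)) as.numeric(x) else x
  }
  lapply(cfg, function(block) {
    if (!all(c("Ds", "Vs", "C0") %in% names(block)))
      stop("read_transport_config: each block needs Ds, Vs, C0", call. = FALSE)
    p <- transport_params(Ds = num(block$Ds), Vs = num(block$Vs),
                          C0 = num(block$C0),
                          Cbg = if (is.null(block$Cbg)) 0 else num(block$Cbg),
                          Rd = if (is.null(block$Rd)) 1 else num(block$Rd))
    extras <- lapply(block[setdiff(names(block), c("Ds", "Vs", "C0", "Cbg", "Rd"))],
                     num)
    c(list(params = p), extras)
  })
}

#' Write / read a mass-peak list (two-column delimited text)
#'
#' Columns `mz`, `intensity`; `#` lines are comments.
#'
#' @param peaks Data.frame with `mz`, `intensity`.
#' @param path File path.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_peak_list <- function(peaks, path) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# negative-mode centroided peak list", con)
  writeLines("mz\tintensity", con)
  write.table(format(peaks[, c("mz", "intensity")], digits = 12, trim = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path)
  df <- read.table(text = lines[!grepl("^#", lines)], sep = "\t", header = TRUE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("read_peak_list: need columns mz, intensity", call. = FALSE)
  if (any(df$mz <= 0)) stop("read_peak_list: mz must be > 0", call. = FALSE)
  df
}

#' Read activity anchors from CSV
#'
#' Columns `conc` (mol/L), `aw`, optional `source`.
#'
#' @param path CSV file path.
#' @return An [activity_anchors()] data.frame.
#' @export
read_activity_anchors <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, comment.char = "#")
  activity_anchors(df$conc, df$aw,
                   source = if ("source" %in% names(df)) df$source[1]
                            else "unspecified")
}
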