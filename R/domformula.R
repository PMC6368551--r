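## CHNOS molecular-formula assignment of negative-mode exact masses and the
## compound-class statistics of ultra-high-resolution DOM spectra.

# IUPAC monoisotopic masses, u (>= 10 significant digits)
ELEMENT_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)
PROTON_MASS <- 1.00727646677

formula_mass <- function(nC, nH, nN, nO, nS) {
  nC * ELEMENT_MASS[["C"]] + nH * ELEMENT_MASS[["H"]] + nN * ELEMENT_MASS[["N"]] +
    nO * ELEMENT_MASS[["O"]] + nS * ELEMENT_MASS[["S"]]
}

#' Element count bounds and filters for formula assignment
#'
#' Search space and plausibility filters for [decompose_mass()]. The default
#' bounds are standard marine-DOM practice for negative-mode FT-ICR spectra
#' of small (< 1000 u) compounds: C 1-60, H 1-120, N 0-3, O 0-40, S 0-3,
#' 0.3 <= H/C <= 2.5, 0 <= O/C <= 1.2, RDBE <= 20, and a 0.2 ppm matching
#' tolerance (internally calibrated spectra reach sub-0.1-ppm accuracy, so
#' 0.2 ppm leaves headroom). The RDBE cap is the usual plausibility window
#' for SPE-DOM below ~700 u: it rejects implausibly condensed aromatic
#' compositions that otherwise appear as near-isobaric CHNOS alternatives.
#'
#' @param C,H,N,O,S Length-2 integer vectors `c(min, max)` per element.
#' @param ppm_tol Matching tolerance, ppm, > 0.
#' @param hc_range,oc_range Allowed H/C and O/C intervals.
#' @param rdbe_max Upper rings-plus-double-bonds cap (RDBE >= 0 always
#'   applies); `Inf` disables it.
#' @return A list of class `element_bounds`.
#' @export
element_bounds <- function(C = c(1, 60), H = c(1, 120), N = c(0, 3),
                           O = c(0, 40), S = c(0, 3), ppm_tol = 0.2,
                           hc_range = c(0.3, 2.5), oc_range = c(0, 1.2),
                           rdbe_max = 20) {
  for (el in list(C = C, H = H, N = N, O = O, S = S)) {
    if (length(el) != 2L || el[1] < 0 || el[1] > el[2])
      stop("element_bounds: each element needs c(min, max) with 0 <= min <= max",
           call. = FALSE)
  }
  if (ppm_tol <= 0) stop("element_bounds: ppm_tol must be > 0", call. = FALSE)
  if (rdbe_max < 0) stop("element_bounds: rdbe_max must be >= 0", call. = FALSE)
  structure(list(C = as.integer(C), H = as.integer(H), N = as.integer(N),
                 O = as.integer(O), S = as.integer(S), ppm_tol = ppm_tol,
                 hc_range = hc_range, oc_range = oc_range,
                 rdbe_max = rdbe_max),
            class = "element_bounds")
}

#' Neutral monoisotopic mass from a measured m/z
#'
#' Negative-mode electrospray DOM ions are assumed singly charged,
#' deprotonated molecules; the neutral mass is `m/z + m(proton)`
#' (1.00727646677 u).
#'
#' @param mz Measured mass-to-charge, u, > proton mass (vectorised).
#' @param mode Ionization mode; only `"negative"` is supported.
#' @return Neutral monoisotopic mass(es), u.
#' @examples
#' neutral_mass_from_mz(179.0561116)  # 180.0633881 (glucose)
#' @export
neutral_mass_from_mz <- function(mz, mode = "negative") {
  if (!identical(mode, "negative"))
    stop("neutral_mass_from_mz: only negative ([M-H]-) mode is supported",
         call. = FALSE)
  if (anyNA(mz) || !all(is.finite(mz)) || any(mz <= PROTON_MASS))
    stop("neutral_mass_from_mz: mz must be finite and > the proton mass",
         call. = FALSE)
  mz + PROTON_MASS
}

# rings-plus-double-bond equivalents of a CcHhNnOoSs neutral
rdbe_of <- function(nC, nH, nN) nC - nH / 2 + nN / 2 + 1

#' Compound class of an elemental composition
#'
#' `CHO` (N = 0, S = 0), `CHNO` (N > 0, S = 0), `CHOS` (N = 0, S > 0),
#' `CHNOS` (N > 0, S > 0); compositions lacking carbon, hydrogen or oxygen
#' are `unclassified` (every class name contains O).
#'
#' @param counts Numeric vector `c(nC, nH, nN, nO, nS)` or a data.frame with
#'   columns `nC, nH, nN, nO, nS` (vectorised).
#' @return Character class label(s).
#' @examples
#' classify_class(c(6, 12, 0, 6, 0))   # "CHO"
#' classify_class(c(10, 15, 1, 4, 1))  # "CHNOS"
#' @export
classify_class <- function(counts) {
  if (is.data.frame(counts)) {
    df <- counts
  } else {
    stopifnot(length(counts) == 5L)
    df <- data.frame(nC = counts[1], nH = counts[2], nN = counts[3],
                     nO = counts[4], nS = counts[5])
  }
  cls <- ifelse(df$nC <= 0 | df$nH <= 0 | df$nO <= 0, "unclassified",
         ifelse(df$nN > 0 & df$nS > 0, "CHNOS",
         ifelse(df$nN > 0, "CHNO",
         ifelse(df$nS > 0, "CHOS", "CHO"))))
  as.character(cls)
}

# precompute the (C, N, O, S) heteroatom grid for a bounds object
cnos_grid <- function(bounds) {
  g <- expand.grid(nC = bounds$C[1]:bounds$C[2],
                   nN = bounds$N[1]:bounds$N[2],
                   nO = bounds$O[1]:bounds$O[2],
                   nS = bounds$S[1]:bounds$S[2],
                   KEEP.OUT.ATTRS = FALSE)
  g$base <- formula_mass(g$nC, 0, g$nN, g$nO, g$nS)
  g
}

#' Decompose a neutral mass into candidate CHNOS formulas
#'
#' Exhaustive bounded search for all elemental compositions whose exact
#' neutral monoisotopic mass lies within `ppm_tol` of `neutral`, filtered by
#' chemical plausibility: RDBE in `[0, rdbe_max]`, integer RDBE
#' (even-electron neutral molecule), and the H/C and O/C windows of
#' `bounds`. The heteroatom grid
#' (C, N, O, S) is enumerated and the admissible hydrogen counts for each
#' combination are derived from the mass window, so the search is complete
#' over the full 5-element box. Results are sorted by `|ppm_error|`, ties
#' broken by fewer heteroatoms (N + S), then lexicographically on the
#' counts.
#'
#' @param neutral Neutral monoisotopic mass, u, > 0 (scalar).
#' @param bounds An [element_bounds()] object.
#' @return A data.frame of class `formula_assignment` with columns
#'   `nC, nH, nN, nO, nS, neutral_mass, ppm_error, cls, hc, oc, rdbe`
#'   (zero rows when no composition matches).
#' @examples
#' hits <- decompose_mass(180.0633881, element_bounds(ppm_tol = 1))
#' hits[1, c("nC", "nH", "nN", "nO", "nS")]  # glucose: 6 12 0 6 0
#' @export
decompose_mass <- function(neutral, bounds = element_bounds()) {
  stopifnot(inherits(bounds, "element_bounds"))
  if (length(neutral) != 1L || !is.finite(neutral) || neutral <= 0)
    stop("decompose_mass: neutral must be a single mass > 0", call. = FALSE)
  n_cand <- prod(vapply(bounds[c("C", "H", "N", "O", "S")],
                        function(b) diff(b) + 1, numeric(1)))
  if (n_cand > 1e7)
    stop(sprintf(
      "decompose_mass: bounds span %.3g candidate compositions (> 1e7); narrow them",
      n_cand), call. = FALSE)

  g <- cnos_grid(bounds)
  w <- neutral * bounds$ppm_tol * 1e-6
  mH <- ELEMENT_MASS[["H"]]
  hlo <- pmax(bounds$H[1], ceiling((neutral - w - g$base) / mH))
  hhi <- pmin(bounds$H[2], floor((neutral + w - g$base) / mH))
  keep <- hhi >= hlo
  if (!any(keep)) return(empty_assignment())
  g <- g[keep, , drop = FALSE]; hlo <- hlo[keep]; hhi <- hhi[keep]
  # expand the (usually singleton) H window per heteroatom combination
  reps <- hhi - hlo + 1L
  idx <- rep.int(seq_len(nrow(g)), reps)
  out <- g[idx, c("nC", "nN", "nO", "nS", "base")]
  out$nH <- unlist(lapply(seq_along(hlo), function(i) hlo[i]:hhi[i]),
                   use.names = FALSE)
  out$neutral_mass <- out$base + out$nH * mH
  out$ppm_error <- (out$neutral_mass - neutral) / neutral * 1e6
  out$rdbe <- rdbe_of(out$nC, out$nH, out$nN)
  out$hc <- out$nH / out$nC
  out$oc <- out$nO / out$nC
  ok <- abs(out$ppm_error) <= bounds$ppm_tol &
    out$rdbe >= 0 & out$rdbe <= bounds$rdbe_max & out$rdbe %% 1 == 0 &
    out$hc >= bounds$hc_range[1] & out$hc <= bounds$hc_range[2] &
    out$oc >= bounds$oc_range[1] & out$oc <= bounds$oc_range[2]
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_assignment())
  out$cls <- classify_class(out)
  ord <- order(abs(out$ppm_error), out$nN + out$nS,
               out$nC, out$nH, out$nN, out$nO, out$nS)
  out <- out[ord, c("nC", "nH", "nN", "nO", "nS", "neutral_mass",
                    "ppm_error", "cls", "hc", "oc", "rdbe")]
  rownames(out) <- NULL
  class(out) <- c("formula_assignment", "data.frame")
  out
}

empty_assignment <- function() {
  structure(data.frame(nC = integer(), nH = integer(), nN = integer(),
                       nO = integer(), nS = integer(),
                       neutral_mass = numeric(), ppm_error = numeric(),
                       cls = character(), hc = numeric(), oc = numeric(),
                       rdbe = numeric()),
            class = c("formula_assignment", "data.frame"))
}

#' Assign formulas to a whole peak list
#'
#' Runs [neutral_mass_from_mz()] and [decompose_mass()] over a centroided
#' peak list and keeps the top-ranked candidate per peak (rank 1 after the
#' |ppm| / heteroatom-parsimony ordering). Peaks with no candidate within
#' tolerance are dropped.
#'
#' @param peaks Data.frame with columns `mz` and `intensity`.
#' @param bounds An [element_bounds()].
#' @return A `formula_assignment` data.frame with additional columns `mz`
#'   and `intensity`, one row per assigned peak.
#' @export
assign_formulas <- function(peaks, bounds = element_bounds()) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    hits <- decompose_mass(neutral_mass_from_mz(peaks$mz[i]), bounds)
    if (nrow(hits) == 0L) return(NULL)
    top <- hits[1, , drop = FALSE]
    top$mz <- peaks$mz[i]; top$intensity <- peaks$intensity[i]
    top
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- empty_assignment(); out$mz <- numeric(); out$intensity <- numeric()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("formula_assignment", "data.frame")
  out
}

unique_formula_key <- function(assignments) {
  paste(assignments$nC, assignments$nH, assignments$nN,
        assignments$nO, assignments$nS, sep = "_")
}

#' Ratio of unique-formula counts between two compound classes
#'
#' Count ratio `count(num_cls) / count(den_cls)` over unique assigned
#' formulas (not intensity-weighted), e.g. CHOS/CHO — the sulfurization
#' index of a DOM pool.
#'
#' @param assignments A `formula_assignment` data.frame.
#' @param num_cls,den_cls Class labels, e.g. `"CHOS"`, `"CHO"`.
#' @return A list: `ratio` (numeric, `NA` when undefined), `status`
#'   (`"ok"` or `"undefined"`), `n_num`, `n_den`.
#' @export
class_ratio <- function(assignments, num_cls, den_cls) {
  stopifnot(is.data.frame(assignments))
  uniq <- assignments[!duplicated(unique_formula_key(assignments)), , drop = FALSE]
  n_num <- sum(uniq$cls == num_cls)
  n_den <- sum(uniq$cls == den_cls)
  if (n_den == 0L)
    return(list(ratio = NA_real_, status = "undefined",
                n_num = n_num, n_den = n_den))
  list(ratio = n_num / n_den, status = "ok", n_num = n_num, n_den = n_den)
}

#' Van Krevelen coordinates of assigned formulas
#'
#' Per-assignment O/C and H/C atomic ratios with intensity and class, plus a
#' flag for highly oxygenated compositions (O/C > 0.6), the molecular series
#' characteristically depleted in euxinic brine DOM.
#'
#' @param assignments A `formula_assignment` data.frame (an `intensity`
#'   column is carried through when present, `NA` otherwise).
#' @return Data.frame with columns `oc`, `hc`, `intensity`, `cls`,
#'   `highly_oxygenated`.
#' @export
van_krevelen <- function(assignments) {
  stopifnot(is.data.frame(assignments))
  if (nrow(assignments) == 0L)
    return(data.frame(oc = numeric(), hc = numeric(), intensity = numeric(),
                      cls = character(), highly_oxygenated = logical()))
  data.frame(oc = assignments$nO / assignments$nC,
             hc = assignments$nH / assignments$nC,
             intensity = if ("intensity" %in% names(assignments))
               assignments$intensity else NA_real_,
             cls = assignments$cls,
             highly_oxygenated = assignments$nO / assignments$nC > 0.6)
}

#' Histogram of sulfur counts among S-containing formulas
#'
#' @param assignments A `formula_assignment` data.frame.
#' @return Named integer vector: count of unique S-containing formulas
#'   (classes CHOS and CHNOS) per sulfur count nS >= 1; empty when none.
#' @export
sulfur_histogram <- function(assignments) {
  stopifnot(is.data.frame(assignments))
  uniq <- assignments[!duplicated(unique_formula_key(assignments)), , drop = FALSE]
  s <- uniq$nS[uniq$cls %in% c("CHOS", "CHNOS") & uniq$nS >= 1]
  if (length(s) == 0L) return(integer(0))
  tab <- table(s)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Fraction of compounds unique to either of two samples
#'
#' Compares two formula (or mass) sets and reports the percentage of the
#' union unique to one sample, `(|A\B| + |B\A|) / |A u B| * 100`, and the
#' complementary shared percentage. Formula sets are matched by exact
#' elemental identity; bare mass lists are matched within `match_tol_ppm`
#' (greedy nearest-mass pairing).
#'
#' @param setA,setB `formula_assignment` data.frames (columns `nC..nS`) or
#'   numeric mass vectors; both non-empty.
#' @param match_tol_ppm Tolerance for mass-list matching, ppm.
#' @return A list: `pct_unique`, `pct_shared`, `n_union`, `n_shared`.
#' @examples
#' unique_shared_fraction(c(100, 200, 300), c(200, 300, 400))$pct_unique  # 50
#' @export
unique_shared_fraction <- function(setA, setB, match_tol_ppm = 1) {
  if (is.data.frame(setA) && is.data.frame(setB)) {
    a <- unique(unique_formula_key(setA))
    b <- unique(unique_formula_key(setB))
    if (length(a) == 0L || length(b) == 0L)
      stop("unique_shared_fraction: both sets must be non-empty", call. = FALSE)
    n_shared <- length(intersect(a, b))
    n_union <- length(union(a, b))
  } else if (is.numeric(setA) && is.numeric(setB)) {
    a <- sort(unique(setA)); b <- sort(unique(setB))
    if (length(a) == 0L || length(b) == 0L)
      stop("unique_shared_fraction: both sets must be non-empty", call. = FALSE)
    used <- logical(length(b)); n_shared <- 0L
    for (x in a) {
      d <- abs(b - x) / x * 1e6
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= match_tol_ppm) { used[j] <- TRUE; n_shared <- n_shared + 1L }
    }
    n_union <- length(a) + length(b) - n_shared
  } else {
    stop("unique_shared_fraction: sets must both be formula tables or both mass vectors",
         call. = FALSE)
  }
  list(pct_unique = (n_union - n_shared) / n_union * 100,
       pct_shared = n_shared / n_union * 100,
       n_union = n_union, n_shared = n_shared)
}
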