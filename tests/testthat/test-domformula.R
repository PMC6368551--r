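test_that("neutral mass restores the proton lost on deprotonation", {
  # glucose C6H12O6: exact neutral 180.0633881 u, [M-H]- at 179.0561116 u
  expect_equal(neutral_mass_from_mz(179.0561116486), 180.0633881154,
               tolerance = 1e-12)
  # arithmetic holds down to implausibly small masses; validity is the
  # caller's concern
  expect_equal(neutral_mass_from_mz(1.00727646678), 2.01455293355,
               tolerance = 1e-11)
  expect_error(neutral_mass_from_mz(1.00727646677), "proton")
  expect_error(neutral_mass_from_mz(-5), "proton")
  expect_error(neutral_mass_from_mz(179.05, mode = "positive"), "negative")
})

test_that("known masses decompose to their formulas at tight and loose tolerance", {
  glucose <- 180.0633881154
  hits1 <- decompose_mass(glucose, element_bounds(ppm_tol = 1))
  expect_true(any(hits1$nC == 6 & hits1$nH == 12 & hits1$nN == 0 &
                    hits1$nO == 6 & hits1$nS == 0))
  hits001 <- decompose_mass(glucose, element_bounds(ppm_tol = 0.01))
  expect_identical(nrow(hits001), 1L)
  expect_identical(unlist(hits001[1, c("nC", "nH", "nN", "nO", "nS")],
                          use.names = FALSE), c(6L, 12L, 0L, 6L, 0L))
  expect_identical(hits001$cls, "CHO")
  expect_equal(hits001$rdbe, 1)
  # a mass sitting in a formula desert returns nothing
  empty <- decompose_mass(180.000000, element_bounds(ppm_tol = 0.1))
  expect_identical(nrow(empty), 0L)
  # results ordered by |ppm|
  expect_true(!is.unsorted(abs(hits1$ppm_error)))
})

test_that("oversized search boxes are refused with a sizing diagnostic", {
  expect_error(decompose_mass(500, element_bounds(C = c(1, 200), H = c(1, 400),
                                                  N = c(0, 10), O = c(0, 80),
                                                  S = c(0, 10))),
               "candidate compositions")
  expect_error(decompose_mass(-1), "mass > 0")
})

test_that("decomposition equals naive exhaustive enumeration on random masses", {
  small <- element_bounds(C = c(1, 12), H = c(1, 24), N = c(0, 2),
                          O = c(0, 8), S = c(0, 2), ppm_tol = 5)
  masses <- withr::with_seed(7, runif(100, 80, 320))
  for (m in masses) {
    mine <- decompose_mass(m, small)
    oracle <- naive_decompose(m, small)
    expect_setequal(fkey(mine), fkey(oracle))
    if (nrow(mine) > 0) {
      o <- oracle[match(fkey(mine), fkey(oracle)), ]
      expect_equal(mine$ppm_error, o$ppm_error, tolerance = 1e-9)
    }
  }
})

test_that("every in-bounds formula is recovered from its own exact mass", {
  bounds <- element_bounds(ppm_tol = 0.2)
  fs <- random_formulas(1000, bounds, seed = 123, max_mass = 800)
  masses <- with(fs, 12 * nC + 1.0078250319 * nH + 14.0030740052 * nN +
                   15.9949146221 * nO + 31.97207069 * nS)
  found <- vapply(seq_len(nrow(fs)), function(i) {
    hits <- decompose_mass(masses[i], bounds)
    fkey(fs[i, ]) %in% fkey(hits)
  }, logical(1))
  expect_true(all(found))
})

test_that("compound classes follow the heteroatom pattern and require C, H, O", {
  expect_identical(classify_class(c(6, 12, 0, 6, 0)), "CHO")
  expect_identical(classify_class(c(10, 15, 1, 4, 0)), "CHNO")
  expect_identical(classify_class(c(10, 16, 0, 4, 1)), "CHOS")
  expect_identical(classify_class(c(10, 15, 1, 4, 1)), "CHNOS")
  expect_identical(classify_class(c(5, 10, 0, 0, 0)), "unclassified")
  expect_identical(classify_class(c(0, 10, 0, 2, 0)), "unclassified")
  # vectorised over assignment tables
  df <- data.frame(nC = c(6, 10, 5), nH = c(12, 15, 10), nN = c(0, 1, 0),
                   nO = c(6, 4, 0), nS = c(0, 1, 0))
  expect_identical(classify_class(df), c("CHO", "CHNOS", "unclassified"))
})

test_that("class ratios count unique formulas and flag empty denominators", {
  mk <- function(n, cls) {
    # distinct CHO vs CHOS formulas: sulfur count encodes the class
    data.frame(nC = 10 + seq_len(n), nH = 14, nN = 0, nO = 4,
               nS = if (cls == "CHOS") 1 else 0,
               cls = cls)
  }
  asg <- rbind(mk(6, "CHOS"), mk(3, "CHO"))
  r <- class_ratio(asg, "CHOS", "CHO")
  expect_identical(r$status, "ok")
  expect_identical(r$ratio, 2)
  # duplicated assignments (same formula twice) count once
  r2 <- class_ratio(rbind(asg, mk(6, "CHOS")), "CHOS", "CHO")
  expect_identical(r2$ratio, 2)
  # arithmetic mirroring the printed brine ratio
  r3 <- class_ratio(rbind(mk(211, "CHOS"), mk(100, "CHO")), "CHOS", "CHO")
  expect_identical(r3$ratio, 2.11)
  r0 <- class_ratio(mk(5, "CHOS"), "CHOS", "CHO")
  expect_identical(r0$status, "undefined")
  expect_true(is.na(r0$ratio))
})

test_that("van Krevelen coordinates and the high-oxygenation flag are per formula", {
  asg <- data.frame(nC = c(6, 10), nH = c(12, 10), nN = c(0, 0),
                    nO = c(6, 2), nS = c(0, 0), cls = c("CHO", "CHO"),
                    intensity = c(100, 50))
  vk <- van_krevelen(asg)
  expect_equal(vk$oc, c(1.0, 0.2))
  expect_equal(vk$hc, c(2.0, 1.0))
  expect_identical(vk$highly_oxygenated, c(TRUE, FALSE))
  expect_equal(vk$intensity, c(100, 50))
  expect_identical(nrow(van_krevelen(asg[0, ])), 0L)
})

test_that("sulfur histogram counts S atoms among S-bearing classes only", {
  asg <- data.frame(nC = c(6, 10, 11, 12, 7), nH = c(12, 16, 16, 18, 12),
                    nN = c(0, 0, 0, 1, 0), nO = c(6, 4, 4, 4, 3),
                    nS = c(0, 2, 1, 1, 2))
  asg$cls <- classify_class(asg)
  h <- sulfur_histogram(asg)
  expect_identical(h, c(`1` = 2L, `2` = 2L))
  s_free <- asg[asg$nS == 0, ]
  expect_identical(sulfur_histogram(s_free), integer(0))
  one <- asg[2, ]
  expect_identical(sulfur_histogram(one), c(`2` = 1L))
})

test_that("unique/shared fractions follow symmetric-difference set arithmetic", {
  A <- data.frame(nC = c(6, 7, 8), nH = c(12, 12, 14), nN = 0, nO = 4, nS = 0)
  B <- data.frame(nC = c(7, 8, 9), nH = c(12, 14, 16), nN = 0, nO = 4, nS = 0)
  u <- unique_shared_fraction(A, B)
  expect_equal(u$pct_unique, 50)
  expect_equal(u$pct_shared, 50)
  expect_identical(u$n_union, 4L)
  same <- unique_shared_fraction(A, A)
  expect_equal(same$pct_unique, 0)
  disj <- unique_shared_fraction(A, data.frame(nC = 20, nH = 30, nN = 1,
                                               nO = 5, nS = 1))
  expect_equal(disj$pct_unique, 100)
  # bare mass lists match within ppm tolerance
  m <- unique_shared_fraction(c(100, 200, 300), c(200 * (1 + 5e-7), 300, 400),
                              match_tol_ppm = 1)
  expect_equal(m$pct_unique, 50)
  expect_error(unique_shared_fraction(A[0, ], B), "non-empty")
})

test_that("jittered synthetic DOM peak lists are re-assigned almost perfectly", {
  # pool and mass accuracy emulate the study's spectra: S-rich small DOM,
  # sub-0.1-ppm internal calibration
  fs <- synthetic_dom_formulas(300, seed = 21)
  pk <- make_peak_list(fs, ppm_jitter = 0.1, seed = 22)
  truth <- attr(pk, "truth")
  asg <- assign_formulas(pk, element_bounds(ppm_tol = 1))
  idx <- match(round(asg$mz, 9), round(pk$mz, 9))
  correct <- vapply(seq_len(nrow(asg)), function(i) {
    all(asg[i, c("nC", "nH", "nN", "nO", "nS")] ==
          truth[idx[i], c("nC", "nH", "nN", "nO", "nS")])
  }, logical(1))
  expect_gte(sum(correct) / nrow(pk), 0.99)
})

test_that("synthetic DOM pools look like small processed organic matter", {
  fs <- synthetic_dom_formulas(400, seed = 31)
  mass <- with(fs, 12 * nC + 1.0078250319 * nH + 14.0030740052 * nN +
                 15.9949146221 * nO + 31.97207069 * nS)
  expect_true(all(mass < 1000))
  expect_lt(mean(mass), 500)
  cls <- classify_class(fs)
  expect_true(all(cls != "unclassified"))
  # sulfur-rich pool: S-bearing classes dominate
  expect_gt(mean(cls %in% c("CHOS", "CHNOS")), 0.5)
})
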