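test_that("fraction integration recovers analytic Gaussian areas", {
  tt <- seq(0, 20, by = 0.005)
  # two identical peaks: symmetry gives 0.5 / 0.5
  a <- dnorm(tt, 5, 0.3) + dnorm(tt, 15, 0.3)
  fr <- integrateFractions(Chromatogram(tt, a),
                           data.frame(start = c(2, 12),
                                      end = c(8, 18)),
                           baseline = "none")
  expect_equal(fr$fraction, c(0.5, 0.5), tolerance = 1e-6)
  # 60:40 planted areas
  a <- 60 * dnorm(tt, 5, 0.3) + 40 * dnorm(tt, 15, 0.3)
  fr <- integrateFractions(Chromatogram(tt, a),
                           data.frame(start = c(2, 12),
                                      end = c(8, 18)),
                           baseline = "none")
  expect_equal(fr$fraction, c(0.6, 0.4), tolerance = 1e-4)
  # single all-spanning fraction normalises to 1
  fr <- integrateFractions(Chromatogram(tt, a),
                           data.frame(start = 0, end = 20),
                           baseline = "none")
  expect_equal(fr$fraction, 1)
  # validation
  expect_error(integrateFractions(Chromatogram(tt, a),
                                  data.frame(start = c(2, 5),
                                             end = c(8, 12))),
               "overlap")
  expect_error(integrateFractions(Chromatogram(tt, a),
                                  data.frame(start = -5, end = 8)),
               "outside")
})

test_that("linear baseline removes an absorbance offset", {
  tt <- seq(0, 10, by = 0.005)
  a <- 50 * dnorm(tt, 5, 0.25) + 3          # constant offset
  fr0 <- integrateFractions(Chromatogram(tt, a),
                            data.frame(start = 2, end = 8),
                            baseline = "linear")
  expect_equal(fr0$area, 50, tolerance = 1e-3)
})

test_that("band and top3 splits partition their input", {
  expect_equal(bandSplit(0.4, c(0.5, 0.5)), c(0.2, 0.2))
  expect_equal(bandSplit(0.3, 1), 0.3)
  expect_equal(bandSplit(0.5, c(0.7, 0.2, 0.1)),
               c(0.35, 0.10, 0.05))
  expect_error(bandSplit(0.5, c(0.7, 0.2)), "sum to 1")

  s <- top3Split(0.30, data.frame(family = c("svSP", "PLA2"),
                                  top3 = c(2e9, 1e9)))
  expect_equal(unname(s), c(0.20, 0.10), tolerance = 1e-12)
  s <- top3Split(0.15, data.frame(family = "CTL", top3 = 5e8))
  expect_equal(s, c(CTL = 0.15))
  s <- top3Split(0.10, data.frame(family = c("DI", "KUN"),
                                  top3 = c(7, 7)))
  expect_equal(unname(s), c(0.05, 0.05))
  expect_error(top3Split(0.1, data.frame(family = "svSP", top3 = 0)),
               class = "venompep_degenerate_band")
  expect_error(top3Split(0.1, data.frame(family = "nonsense",
                                         top3 = 1)),
               "unknown toxin")
})

test_that("composition assembles the worked micro-example", {
  # F1 0.6 all svMP_PIII; F2 0.4 with two equal bands, the second
  # split 2:1 svSP:PLA2
  bands <- data.frame(fraction = c("F1", "F2", "F2"),
                      band = c("B1", "B2a", "B2b"),
                      share = c(1, 0.5, 0.5))
  asg <- data.frame(band = c("B1", "B2a", "B2b", "B2b"),
                    family = c("svMP_PIII", "CTL", "svSP", "PLA2"),
                    top3 = c(1e9, 1e9, 2e9, 1e9))
  vc <- composeVenom(c(F1 = 0.6, F2 = 0.4), bands, asg)
  p <- vc@percent
  expect_equal(unname(p["svMP_PIII"]), 60, tolerance = 1e-9)
  expect_equal(unname(p["CTL"]), 20, tolerance = 1e-9)
  expect_equal(unname(p["svSP"]), 13.3333, tolerance = 1e-3)
  expect_equal(unname(p["PLA2"]), 6.6667, tolerance = 1e-3)
  expect_equal(sum(p), 100, tolerance = 1e-9)
})

test_that("peptide and unassigned fractions route to their buckets", {
  vc <- composeVenom(c(F1 = 0.6, F2 = 0.4), bands = NULL,
                     assignments = NULL, peptide_fraction_ids = "F2")
  expect_equal(unname(vc@percent["peptides"]), 40)
  expect_equal(unname(vc@percent["unknown"]), 60)
  vc <- composeVenom(c(F1 = 1), NULL, NULL)
  expect_equal(unname(vc@percent["unknown"]), 100)
  # double assignment is an error
  bands <- data.frame(fraction = "F2", band = "B1", share = 1)
  expect_error(composeVenom(c(F1 = 0.6, F2 = 0.4), bands, NULL,
                            peptide_fraction_ids = "F2"),
               "both flagged")
  # degenerate band routed to unknown with a warning
  asg <- data.frame(band = "B1", family = "svSP", top3 = 0)
  expect_warning(
    vc <- composeVenom(c(F1 = 0.6, F2 = 0.4), bands, asg),
    "routed to unknown")
  expect_equal(unname(vc@percent["unknown"]), 100)
})

test_that("abundance is conserved and invariant at every stage", {
  set.seed(3)
  for (rep in 1:5) {
    sv <- simVenom(seed = 100 + rep)
    fr <- integrateFractions(sv$chromatogram, sv$boundaries,
                             baseline = "none")
    expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
    # band split partitions each fraction
    for (id in unique(sv$bands$fraction)) {
      sh <- sv$bands$share[sv$bands$fraction == id]
      f <- fr$fraction[fr$id == id]
      expect_equal(sum(bandSplit(f, sh)), f, tolerance = 1e-12)
    }
    vc <- composeVenom(fr, sv$bands, sv$assignments,
                       sv$peptide_fraction_ids)
    expect_equal(sum(vc@percent), 100, tolerance = 1e-9)
    # scaling all absorbances leaves the composition unchanged
    sc <- Chromatogram(sv$chromatogram@time,
                       sv$chromatogram@absorbance * 37.5)
    fr2 <- integrateFractions(sc, sv$boundaries, baseline = "none")
    vc2 <- composeVenom(fr2, sv$bands, sv$assignments,
                        sv$peptide_fraction_ids)
    expect_equal(vc2@percent, vc@percent, tolerance = 1e-9)
    # permuting fraction order leaves the composition unchanged
    perm <- sample(nrow(fr))
    vc3 <- composeVenom(fr[perm, ], sv$bands, sv$assignments,
                        sv$peptide_fraction_ids)
    expect_equal(vc3@percent, vc@percent, tolerance = 1e-9)
  }
})

test_that("composition class validates and summarises", {
  vc <- VenomComposition(c(svSP = 46, PLA2 = 18, VEGF = 11, KUN = 9,
                           peptides = 16))
  expect_error(validObject(
    methods::new("VenomComposition",
                 percent = c(svSP = 50, PLA2 = 20))),
    "sum to 100")
  tab <- compositionTable(vc)
  expect_identical(tab$family[1], "svSP")
  expect_identical(utils::tail(tab$family, 2),
                   c("peptides", "unknown"))
  vc2 <- VenomComposition(c(svMP_PI = 2, svMP_PIII = 12, DC = 8,
                            svSP = 78))
  expect_equal(svMPUmbrella(vc2), 22)
})
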