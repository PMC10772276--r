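test_that("embedded isotope table satisfies its invariants", {
  tab <- isotope_table()
  expect_true(all(c("C", "H", "D", "O", "N", "Cl", "Br") %in% names(tab)))
  expect_silent(validate_isotope_table(tab))
  bad <- tab
  bad$C$abundance <- c(0.9, 0.2)
  expect_error(validate_isotope_table(bad), "sum to 1")
})

test_that("formula parser reads Hill-like notation and rejects junk", {
  f <- parse_formula("C6H4Br2O")
  expect_identical(f[["C"]], 6L)
  expect_identical(f[["H"]], 4L)
  expect_identical(f[["Br"]], 2L)
  expect_identical(f[["O"]], 1L)
  expect_identical(parse_formula("C6H3DBr2O")[["D"]], 1L)
  expect_error(parse_formula("C6Xx2"), "Xx")
  expect_error(parse_formula(""), "empty")
})

test_that("convolution matches hand-enumerated two-atom envelopes", {
  # delta is the identity
  p <- isotope_pattern(100L, c(0.7, 0.2, 0.1))
  delta <- isotope_pattern(0L, 1.0)
  expect_equal(convolve_patterns(delta, p)$abundance, p$abundance)
  # Br2: enumerate the four isotope combinations by hand
  br <- isotope_pattern(79L, c(0.5069, 0, 0.4931))
  br2 <- convolve_patterns(br, br)
  expect_equal(br2$base_mz, 158L)
  expect_equal(br2$abundance[c(1, 3, 5)],
               c(0.5069^2, 2 * 0.5069 * 0.4931, 0.4931^2), tolerance = 1e-12)
  expect_equal(br2$abundance[c(2, 4)], c(0, 0))
  # C6 M+1: binomial closed form
  cpat <- isotope_pattern(12L, c(0.9893, 0.0107))
  acc <- cpat
  for (i in 1:5) acc <- convolve_patterns(acc, cpat)
  expect_equal(acc$abundance[2], 6 * 0.0107 * 0.9893^5, tolerance = 1e-12)
})

test_that("convolution is commutative and associative", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_pattern(); q <- random_pattern(); r <- random_pattern()
    pq <- convolve_patterns(p, q); qp <- convolve_patterns(q, p)
    expect_equal(pq$abundance, qp$abundance, tolerance = 1e-12)
    expect_identical(pq$base_mz, qp$base_mz)
    lhs <- convolve_patterns(convolve_patterns(p, q), r)
    rhs <- convolve_patterns(p, convolve_patterns(q, r))
    expect_equal(lhs$abundance, rhs$abundance, tolerance = 1e-12)
    # total abundance multiplies (sums are 1 here)
    expect_equal(sum(pq$abundance), sum(p$abundance) * sum(q$abundance),
                 tolerance = 1e-12)
  }
})

test_that("formula envelopes match exhaustive enumeration on small molecules", {
  for (f in c("H2O", "CHBr", "C2HCl", "CBr2", "C2H2O", "CHDO")) {
    enum <- enumerate_pattern(f)
    got <- pattern_for_formula(f, max_shift = length(enum) - 1)$abundance
    expect_equal(got[seq_along(enum)], enum / sum(enum), tolerance = 1e-12,
                 label = f)
  }
  # direct product: all-lightest species of water
  expect_equal(pattern_for_formula("H2O")$abundance[1],
               0.999885^2 * 0.99757, tolerance = 1e-12)
})

test_that("dibromophenol envelope shows the two-bromine M+2 signature", {
  p <- pattern_for_formula("C6H4Br2O")
  expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
  expect_true(all(p$abundance >= 0))
  expect_lt(p$tail, 1e-4)
  # M+2/M dominated by one 81Br substitution
  expect_equal(p$abundance[3] / p$abundance[1], 1.95, tolerance = 0.01)
})

test_that("single-isotope elements give delta patterns", {
  p <- pattern_for_formula("D2", max_shift = 3)
  expect_equal(p$abundance, c(1, 0, 0, 0))
  expect_equal(p$base_mz, 4L)
})

test_that("nominal molecular-ion m/z reproduces the printed product ions", {
  expect_identical(nominal_molecular_ion_mz("C6H4Br2O"), 250L)
  expect_identical(nominal_molecular_ion_mz("C6H3Cl3"), 180L)
  expect_identical(nominal_molecular_ion_mz("H2O"), 18L)
  expect_error(nominal_molecular_ion_mz("Qq2"), "Qq")
})

test_that("labelled envelope is the stated two-component mixture", {
  f <- "C6H4Br2O"
  expect_equal(labeled_pattern(f, 0)$abundance[1:7],
               pattern_for_formula(f)$abundance, tolerance = 1e-12)
  # fully labelled: pure singly-deuterated species, shifted one bin up
  full <- labeled_pattern(f, 1)
  pd <- pattern_for_formula("C6H3DBr2O")
  expect_equal(full$abundance[1], 0)
  expect_equal(full$abundance[2:8], pd$abundance, tolerance = 1e-12)
  # with hypothetical single-isotope C/H/O, a 50:50 label puts equal mass
  # in the first peak pair (no natural M+1 blur; Br only adds even shifts)
  tab <- pure_isotope_table()
  half <- labeled_pattern("C6H4Br2O", 0.5, tab = tab)
  u <- pattern_for_formula("C6H4Br2O", tab = tab)
  expect_equal(half$abundance[1], 0.5 * u$abundance[1], tolerance = 1e-12)
  expect_equal(half$abundance[1], half$abundance[2], tolerance = 1e-12)
  expect_equal(predicted_dd1(0.5, "C6H4Br2O", tab = tab), 0.5,
               tolerance = 1e-12)
  expect_error(labeled_pattern(f, 1.2), "dd_true")
  expect_error(labeled_pattern("Cl2", 0.5), "no H")
})

test_that("predicted DD1 carries the natural M+1 bias and is monotone", {
  f <- "C6H4Br2O"
  # at zero labelling, DD1 is the heavy-isotope M+1 fraction; check against
  # the enumeration-free closed form on isotope ratios
  r <- 6 * 0.0107 / 0.9893 + 4 * 0.000115 / 0.999885 + 0.00038 / 0.99757
  expect_equal(predicted_dd1(0, f), r / (1 + r), tolerance = 1e-4)
  expect_gte(predicted_dd1(1, f), 0.93)
  dd <- seq(0, 1, by = 0.1)
  vals <- vapply(dd, predicted_dd1, numeric(1), f = f)
  expect_true(all(diff(vals) > 0))
})

test_that("natural-abundance correction inverts the forward model", {
  f <- "C6H4Br2O"
  for (d in c(0.05, 0.4, 0.8, 0.99)) {
    expect_equal(as.numeric(correct_dd1_for_natural_abundance(
      predicted_dd1(d, f), f)), d, tolerance = 1e-9)
  }
  expect_warning(out <- correct_dd1_for_natural_abundance(0, f), "baseline")
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "below_baseline"))
  # exactly at the baseline: zero without a warning
  expect_silent(base <- correct_dd1_for_natural_abundance(
    predicted_dd1(0, f), f))
  expect_equal(as.numeric(base), 0)
})

test_that("pattern export table mirrors the envelope", {
  p <- pattern_for_formula("C6H3Cl3")
  d <- pattern_as_table(p)
  expect_equal(d$nominal_mz[1], 180L)
  expect_equal(d$rel_abundance, p$abundance)
})
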