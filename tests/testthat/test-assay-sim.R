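test_that("mixture fraction reproduces the assembled vial contents", {
  expect_equal(mixture_fraction(list(c(625, 0.80), c(375, 0))), 0.50)
  expect_equal(mixture_fraction(list(c(200, 0), c(800, 1.0))), 0.80)
  expect_equal(mixture_fraction(list(c(123, 0.37))), 0.37)
  # always within the component range
  set.seed(7)
  for (i in 1:20) {
    comp <- lapply(1:3, function(j) c(runif(1, 1, 1000), runif(1)))
    fr <- vapply(comp, `[`, numeric(1), 2)
    m <- mixture_fraction(comp)
    expect_gte(m, min(fr)); expect_lte(m, max(fr))
  }
  expect_error(mixture_fraction(list()), "empty")
  expect_error(mixture_fraction(list(c(-1, 0.5))), "positive")
})

test_that("cytoplasmic pool relaxes exponentially to the external value", {
  expect_equal(cytoplasm_fraction(0, 0.8, 0.5, 0.01), 0.8)
  expect_equal(cytoplasm_fraction(1234, 0.8, 0.5, 0), 0.8)
  k <- 0.0077
  expect_equal(cytoplasm_fraction(60 / k, 0, 0.8, k), 0.8, tolerance = 1e-12)
  # half-life
  expect_equal(cytoplasm_fraction(log(2) / k, 0, 0.8, k), 0.4,
               tolerance = 1e-12)
})

test_that("instantaneous deuteration implements the preference ratio", {
  expect_equal(instantaneous_dd(0.37, 1), 0.37)
  expect_equal(instantaneous_dd(0, 5), 0)
  expect_equal(instantaneous_dd(1, 5), 1)
  expect_equal(instantaneous_dd(0.8, 3), 0.8 / 1.4, tolerance = 1e-12)
  # decreasing in alpha on the open interval
  expect_gt(instantaneous_dd(0.5, 1), instantaneous_dd(0.5, 2))
})

test_that("cumulative product deuteration agrees with quadrature", {
  cond <- condition_preset("c1")
  # closed-form special case: alpha = 1, x from 0 to 1, k*t = 1
  cnd <- cond; cnd$x_in0 <- 0; cnd$x_ext <- 1
  expect_equal(cumulative_product_dd(1, exchange_params(k_ex = 1, alpha = 1), cnd),
               exp(-1), tolerance = 1e-9)
  set.seed(11)
  for (i in 1:15) {
    k <- 10^runif(1, -4, 0); a <- 10^runif(1, log10(0.2), 1)
    x0 <- runif(1); xe <- runif(1); t <- 10^runif(1, 0.5, 3.5)
    cnd <- cond; cnd$x_in0 <- x0; cnd$x_ext <- xe
    got <- cumulative_product_dd(t, exchange_params(k_ex = k, alpha = a), cnd)
    expect_equal(got, cumulative_dd_quadrature(t, k, a, x0, xe),
                 tolerance = 1e-8)
  }
  # crude extract: time-invariant at the mixture value
  c3 <- condition_preset("c3")
  prm <- exchange_params()
  expect_equal(cumulative_product_dd(c(10, 100, 1000), prm, c3),
               rep(instantaneous_dd(c3$x_ext, prm$alpha), 3))
  # fast exchange approaches the external limit
  cnd <- cond
  expect_equal(cumulative_product_dd(600, exchange_params(k_ex = 100, alpha = 1.9), cnd),
               instantaneous_dd(cnd$x_ext, 1.9), tolerance = 1e-3)
})

test_that("condition presets encode the four assay designs", {
  c1 <- condition_preset("c1"); c2 <- condition_preset("c2")
  c3 <- condition_preset("c3"); c4 <- condition_preset("c4")
  expect_equal(c1$x_in0, 0); expect_equal(c1$x_ext, 0.8)
  expect_equal(c2$x_in0, 0.8); expect_equal(c2$x_ext, 0.5)
  expect_false(c3$whole_cell); expect_equal(c3$x_ext, 0.2)
  expect_equal(c4$x_ext, 0.8)
  expect_equal(c2$cells_per_mL, 6.7e8)
  expect_equal(c3$cells_per_mL, 3.9e9)
  expect_error(assay_condition("bad", 200, 0, 0.5, 800, 1, 1e8,
                               whole_cell = FALSE, product = "C6H4Br2O"),
               "crude-extract")
  expect_error(condition_preset("c1", times_s = c(10, 10, 20)), "increasing")
})

test_that("zero-noise simulation round-trips the forward model exactly", {
  prm <- exchange_params()
  nm <- noise_model(cv = 0, seed = 3)
  for (id in c("c1", "c3")) {
    cond <- condition_preset(id)
    peaks <- simulate_assay(cond, prm, nm)
    tc <- dd_timecourse(peaks, cond$product)
    want <- predicted_dd1(cumulative_product_dd(cond$times_s, prm, cond),
                          cond$product)
    expect_equal(tc$dd1_mean, want, tolerance = 1e-9)
    expect_equal(tc$dd1_sd, rep(0, nrow(tc)))
  }
})

test_that("simulated whole-cell course rises while extracts stay flat", {
  prm <- exchange_params()
  nm <- noise_model(cv = 0, seed = 3)
  tc1 <- dd_timecourse(simulate_assay(condition_preset("c1"), prm, nm),
                       "C6H4Br2O")
  expect_true(all(diff(tc1$dd1_mean) > 0))
  tc3 <- dd_timecourse(simulate_assay(condition_preset("c3"), prm, nm),
                       "C6H4Br2O")
  expect_equal(diff(range(tc3$dd1_mean)), 0, tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  cond <- condition_preset("c2", times_s = c(10, 60, 300))
  prm <- exchange_params()
  a <- simulate_assay(cond, prm, noise_model(cv = 0.1, seed = 99))
  b <- simulate_assay(cond, prm, noise_model(cv = 0.1, seed = 99))
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(a, f1, row.names = FALSE); write.csv(b, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d <- simulate_assay(cond, prm, noise_model(cv = 0.1, seed = 100))
  expect_false(identical(a$area, d$area))
})

test_that("zero-noise product amount is linear in time and cell count", {
  prm <- exchange_params()
  nm <- noise_model(cv = 0, seed = 1)
  cond <- condition_preset("c4", times_s = c(100, 200, 400))
  peaks <- simulate_assay(cond, prm, nm)
  tot <- tapply(peaks$area, peaks$time_s, sum)
  expect_equal(tot[["200"]] / tot[["100"]], 2, tolerance = 1e-9)
  expect_equal(tot[["400"]] / tot[["100"]], 4, tolerance = 1e-9)
  cond2 <- condition_preset("c4", cells_per_mL = 2 * 3.9e9,
                            times_s = c(100, 200, 400))
  peaks2 <- simulate_assay(cond2, prm, nm)
  expect_equal(sum(peaks2$area) / sum(peaks$area), 2, tolerance = 1e-9)
})
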