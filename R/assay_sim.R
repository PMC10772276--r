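#' Describe one activity-assay condition
#'
#' A declarative description of one experimental condition of the
#' methyl-viologen dehalogenase activity assay: the pipetted components
#' (suspension or crude extract plus assay buffer, each with a D2O water
#' fraction), the cell density behind the enzyme load, whether the cell
#' membrane is intact, the product species, and the sampling design.
#'
#' For whole cells the cytoplasmic water pool starts at `cytoplasm_d2o` and
#' equilibrates with the external mixture; for crude extracts the pools are
#' merged, so `cytoplasm_d2o` must equal `suspension_d2o` and the labelling
#' fraction is the overall mixture fraction at all times.
#'
#' @param id Condition identifier (e.g. `"c1"`).
#' @param suspension_uL Volume of cell suspension or crude extract (µL).
#' @param suspension_d2o D2O fraction of the suspension water.
#' @param cytoplasm_d2o Initial cytoplasmic D2O fraction (whole cells).
#' @param buffer_uL Volume of activity assay buffer (µL).
#' @param buffer_d2o D2O fraction of the buffer.
#' @param cells_per_mL Cell density of the suspension (cells per mL).
#' @param whole_cell `TRUE` for intact cells, `FALSE` for crude extract.
#' @param product Product formula string (e.g. `"C6H4Br2O"`).
#' @param species Short product label used in peak tables (e.g. `"DBP"`).
#' @param times_s Sampling times in seconds, strictly increasing.
#' @param replicates Number of replicate vials (>= 1).
#' @return A list of class `assay_condition` with derived fields `x_in0`
#'   (initial labelling pool fraction) and `x_ext` (external/overall
#'   mixture fraction).
#' @export
assay_condition <- function(id, suspension_uL, suspension_d2o, cytoplasm_d2o,
                            buffer_uL, buffer_d2o, cells_per_mL,
                            whole_cell, product, species = product,
                            times_s = c(10, 20, 30, 60, 120, 300, 900, 2700),
                            replicates = 3L) {
  stopifnot(suspension_uL > 0, buffer_uL > 0, cells_per_mL > 0,
            replicates >= 1)
  fr <- c(suspension_d2o, cytoplasm_d2o, buffer_d2o)
  if (any(fr < 0 | fr > 1)) stop("D2O fractions must be in [0, 1]")
  if (any(diff(times_s) <= 0) || any(times_s <= 0))
    stop("sampling times must be positive and strictly increasing")
  if (!whole_cell && cytoplasm_d2o != suspension_d2o)
    stop("crude-extract conditions must have cytoplasm_d2o == suspension_d2o")
  x_ext <- mixture_fraction(list(c(suspension_uL, suspension_d2o),
                                 c(buffer_uL, buffer_d2o)))
  structure(list(
    id = id, suspension_uL = suspension_uL, suspension_d2o = suspension_d2o,
    cytoplasm_d2o = cytoplasm_d2o, buffer_uL = buffer_uL,
    buffer_d2o = buffer_d2o, cells_per_mL = cells_per_mL,
    whole_cell = isTRUE(whole_cell), product = product, species = species,
    times_s = as.numeric(times_s), replicates = as.integer(replicates),
    x_in0 = if (isTRUE(whole_cell)) cytoplasm_d2o else x_ext,
    x_ext = x_ext
  ), class = "assay_condition")
}

#' Shipped assay-condition presets
#'
#' The four experimental conditions of the tracing study, as assembled in
#' the vials:
#' * `c1` — intact cells grown in H2O (cytoplasm 0% D2O): 200 µL suspension
#'   (0% D2O, 2.9e8 cells/mL) + 800 µL D2O buffer, overall 80%.
#' * `c2` — intact cells grown in 80% D2O (cytoplasm 80%): 625 µL
#'   suspension (80%, 6.7e8 cells/mL) + 375 µL H2O buffer, overall 50%.
#' * `c3` — crude extract from H2O cells: 200 µL extract + 800 µL buffer
#'   (25% D2O), overall 20%; extract from 3.9e9 cells/mL.
#' * `c4` — crude extract from H2O cells: 200 µL extract + 800 µL D2O
#'   buffer, overall 80%; extract from 3.9e9 cells/mL.
#'
#' The product is dibromophenol (from tribromophenol), quantified as the
#' free phenol molecular ion at m/z 250.
#'
#' @param id One of `"c1"`, `"c2"`, `"c3"`, `"c4"`.
#' @param ... Overrides passed to [assay_condition()] (e.g. `times_s`).
#' @return An `assay_condition`.
#' @export
condition_preset <- function(id = c("c1", "c2", "c3", "c4"), ...) {
  id <- match.arg(id)
  args <- switch(id,
    c1 = list(id = "c1", suspension_uL = 200, suspension_d2o = 0,
              cytoplasm_d2o = 0, buffer_uL = 800, buffer_d2o = 1.0,
              cells_per_mL = 2.9e8, whole_cell = TRUE,
              times_s = c(30, 60, 120, 300, 600, 900, 1800, 2700)),
    c2 = list(id = "c2", suspension_uL = 625, suspension_d2o = 0.8,
              cytoplasm_d2o = 0.8, buffer_uL = 375, buffer_d2o = 0,
              cells_per_mL = 6.7e8, whole_cell = TRUE,
              times_s = c(10, 20, 30, 60, 120, 300, 900, 2700)),
    c3 = list(id = "c3", suspension_uL = 200, suspension_d2o = 0,
              cytoplasm_d2o = 0, buffer_uL = 800, buffer_d2o = 0.25,
              cells_per_mL = 3.9e9, whole_cell = FALSE,
              times_s = c(30, 60, 120, 300, 600, 900, 1800, 2700)),
    c4 = list(id = "c4", suspension_uL = 200, suspension_d2o = 0,
              cytoplasm_d2o = 0, buffer_uL = 800, buffer_d2o = 1.0,
              cells_per_mL = 3.9e9, whole_cell = FALSE,
              times_s = c(30, 60, 120, 300, 600, 900, 1800, 2700))
  )
  args$product <- "C6H4Br2O"
  args$species <- "DBP"
  over <- list(...)
  args[names(over)] <- over
  do.call(assay_condition, args)
}

#' Measurement noise model for simulated peak areas
#'
#' Multiplicative lognormal noise per extracted-ion peak, parameterized by
#' a coefficient of variation, plus the detector scale converting product
#' concentration to area counts. The lognormal is mean-1 so that expected
#' areas are unbiased.
#'
#' @param scale Area counts per µM of product at unit abundance.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Base random seed (integer).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(scale = 1e5, cv = 0.10, seed = 1L) {
  stopifnot(scale > 0, cv >= 0)
  structure(list(scale = scale, cv = cv, seed = as.integer(seed)),
            class = "noise_model")
}

avogadro <- 6.02214076e23

replicate_seed <- function(base, k) {
  # counter-based split so replicate k is reproducible independently
  as.integer((as.double(base) * 1000003 + 7919 * k) %% 2147483647)
}

#' Simulate a triplicate GC-MS peak-area table
#'
#' Forward-simulates extracted-ion peak areas for one assay condition.
#' Product accumulates linearly at `params$r` molecules per cell per
#' second; its deuteration at harvest time follows
#' [cumulative_product_dd()] (time-averaged over the equilibrating
#' cytoplasm for whole cells, the constant mixture value for crude
#' extracts); the isotopologue envelope comes from [labeled_pattern()];
#' and each bin's area is `scale * concentration_uM * abundance` perturbed
#' by mean-1 lognormal noise. Given the same seed the output is identical
#' across runs, and each replicate has its own reproducible substream.
#'
#' @param condition An [assay_condition()].
#' @param params An [exchange_params()].
#' @param noise A [noise_model()].
#' @param max_shift Highest isotopologue bin simulated (default 6).
#' @return A tibble with columns `sample_id`, `condition_id`, `replicate`,
#'   `time_s`, `species`, `mz_nominal`, `area`.
#' @export
simulate_assay <- function(condition, params, noise, max_shift = 6L) {
  stopifnot(inherits(condition, "assay_condition"))
  base_mz <- nominal_molecular_ion_mz(condition$product)
  cells <- cells_in_assay(condition$cells_per_mL, condition$suspension_uL)
  vol_L <- params$assay_volume_mL * 1e-3
  times <- condition$times_s
  dd_cum <- cumulative_product_dd(times, params, condition)
  sdlog <- if (noise$cv > 0) sqrt(log(1 + noise$cv^2)) else 0
  rows <- vector("list", condition$replicates)
  for (k in seq_len(condition$replicates)) {
    set.seed(replicate_seed(noise$seed, k))
    per_time <- vector("list", length(times))
    for (i in seq_along(times)) {
      t <- times[i]
      molecules <- params$r * cells * t
      conc_uM <- molecules / avogadro / vol_L * 1e6
      env <- labeled_pattern(condition$product, dd_cum[i], max_shift)
      nb <- length(env$abundance)
      fac <- if (sdlog > 0)
        exp(stats::rnorm(nb, mean = -sdlog^2 / 2, sd = sdlog)) else rep(1, nb)
      per_time[[i]] <- tibble::tibble(
        sample_id = sprintf("%s_t%06.0f_r%d", condition$id, t, k),
        condition_id = condition$id,
        replicate = k,
        time_s = t,
        species = condition$species,
        mz_nominal = env$base_mz + seq_len(nb) - 1L,
        area = noise$scale * conc_uM * env$abundance * fac
      )
    }
    rows[[k]] <- dplyr::bind_rows(per_time)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$time_s, .data$replicate, .data$mz_nominal)
}
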