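#' First-peak-pair deuteration degree
#'
#' The deuteration degree of a product ion at unit mass resolution is the
#' deuterated peak area over the sum of the protonated and deuterated
#' areas, `DD1 = B1 / (A1 + B1)`, where A1 is the extracted-ion area at the
#' nominal molecular-ion m/z and B1 the area one mass unit higher. Raw
#' areas are used as measured; no natural-abundance correction is applied
#' (see [correct_dd1_for_natural_abundance()] for the corrected variant).
#'
#' @param a1,b1 Peak areas (>= 0), vectorized.
#' @param sample Optional sample label used in error messages.
#' @return `b1 / (a1 + b1)`, in `[0, 1]`.
#' @export
dd1 <- function(a1, b1, sample = NULL) {
  if (any(a1 < 0) || any(b1 < 0)) stop("peak areas must be non-negative")
  bad <- a1 + b1 == 0
  if (any(bad)) {
    lab <- if (!is.null(sample)) paste0(" for sample ", sample[bad][1]) else ""
    stop("undefined DD1: A1 + B1 = 0", lab)
  }
  b1 / (a1 + b1)
}

#' Equilibrium reference deuteration of an assay
#'
#' The D2O fraction the assay water reaches when all pools are mixed — the
#' dashed reference line a DD1 time course is compared against: the
#' volume-weighted mixture of the suspension water and buffer components.
#'
#' @param condition An [assay_condition()].
#' @return The overall D2O fraction in `[0, 1]`.
#' @export
equilibrium_reference <- function(condition) {
  mixture_fraction(list(c(condition$suspension_uL, condition$suspension_d2o),
                        c(condition$buffer_uL, condition$buffer_d2o)))
}

#' DD1 time course from a peak table
#'
#' Computes per-replicate DD1 at every (condition, time), then aggregates
#' to mean and sample standard deviation (n - 1 denominator) across
#' replicates. A1 and B1 are selected by nominal m/z: the rounded
#' monoisotopic mass of the product formula and that value + 1. Areas of
#' co-eluting regioisomers (same formula, same envelope) sharing a
#' (sample, bin) are summed before the ratio.
#'
#' @param peaks A peak table as produced by [simulate_assay()] (columns
#'   `sample_id`, `condition_id`, `replicate`, `time_s`, `mz_nominal`,
#'   `area`).
#' @param product Product formula string used to locate A1/B1.
#' @param condition Optional [assay_condition()]; when given, the
#'   equilibrium reference fraction is attached to every row.
#' @return A tibble (one row per condition x time, sorted by time) with
#'   columns `condition_id`, `time_s`, `n`, `dd1_mean`, `dd1_sd` and,
#'   when a condition is supplied, `equilibrium_ref`.
#' @export
dd_timecourse <- function(peaks, product, condition = NULL) {
  base_mz <- nominal_molecular_ion_mz(product)
  sub <- dplyr::filter(peaks, .data$mz_nominal %in% c(base_mz, base_mz + 1L))
  per_sample <- sub |>
    dplyr::group_by(.data$condition_id, .data$time_s, .data$replicate,
                    .data$sample_id, .data$mz_nominal) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop") |>
    tidyr_pivot(base_mz)
  missing_a <- is.na(per_sample$a1); missing_b <- is.na(per_sample$b1)
  if (any(missing_a) || any(missing_b)) {
    i <- which(missing_a | missing_b)[1]
    bin <- if (missing_a[i]) base_mz else base_mz + 1L
    stop("sample ", per_sample$sample_id[i], " lacks the m/z ", bin, " bin")
  }
  per_sample$dd1 <- dd1(per_sample$a1, per_sample$b1, per_sample$sample_id)
  out <- per_sample |>
    dplyr::group_by(.data$condition_id, .data$time_s) |>
    dplyr::summarise(n = dplyr::n(),
                     dd1_mean = mean(.data$dd1),
                     dd1_sd = stats::sd(.data$dd1),
                     .groups = "drop") |>
    dplyr::arrange(.data$condition_id, .data$time_s)
  if (!is.null(condition))
    out$equilibrium_ref <- equilibrium_reference(condition)
  out
}

# reshape long (mz rows) to wide a1/b1 columns without importing tidyr
tidyr_pivot <- function(d, base_mz) {
  a <- dplyr::filter(d, .data$mz_nominal == base_mz)
  b <- dplyr::filter(d, .data$mz_nominal == base_mz + 1L)
  keys <- c("condition_id", "time_s", "replicate", "sample_id")
  out <- dplyr::full_join(
    dplyr::select(a, dplyr::all_of(keys), a1 = "area"),
    dplyr::select(b, dplyr::all_of(keys), b1 = "area"),
    by = keys)
  out
}

#' Replicate-level DD1 values
#'
#' Convenience accessor returning one DD1 per (condition, time, replicate),
#' the unit on which paired time-point tests operate.
#'
#' @inheritParams dd_timecourse
#' @return A tibble with columns `condition_id`, `time_s`, `replicate`,
#'   `dd1`, sorted by time then replicate.
#' @export
dd_replicates <- function(peaks, product) {
  base_mz <- nominal_molecular_ion_mz(product)
  sub <- dplyr::filter(peaks, .data$mz_nominal %in% c(base_mz, base_mz + 1L))
  per_sample <- sub |>
    dplyr::group_by(.data$condition_id, .data$time_s, .data$replicate,
                    .data$sample_id, .data$mz_nominal) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop") |>
    tidyr_pivot(base_mz)
  per_sample$dd1 <- dd1(per_sample$a1, per_sample$b1, per_sample$sample_id)
  per_sample |>
    dplyr::select("condition_id", "time_s", "replicate", "dd1") |>
    dplyr::arrange(.data$condition_id, .data$time_s, .data$replicate)
}

#' Apparent H-over-D preference factor from an observed deuteration
#'
#' Inverts [instantaneous_dd()]: given the D fraction `x_D` of the
#' proton-donating pool and the observed product deuteration `dd_obs`,
#' the apparent fractionation factor is
#' `alpha = x_D (1 - dd_obs) / (dd_obs (1 - x_D))`. `alpha = 1` means no
#' discrimination (`dd_obs = x_D`); `alpha > 1` means protons are favoured.
#'
#' @param dd_obs Observed deuteration fraction, strictly inside `(0, 1)`.
#' @param x_D D fraction of the donating pool, strictly inside `(0, 1)`.
#' @return The apparent preference factor (> 0).
#' @export
apparent_alpha <- function(dd_obs, x_D) {
  if (any(dd_obs <= 0 | dd_obs >= 1) || any(x_D <= 0 | x_D >= 1))
    stop("apparent_alpha is undefined at the boundaries 0 and 1")
  x_D * (1 - dd_obs) / (dd_obs * (1 - x_D))
}
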