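#' Number of cells pipetted into an assay
#'
#' @param cells_per_mL Cell density of the suspension (cells per mL).
#' @param suspension_uL Suspension volume used (µL).
#' @return Cell count `cells_per_mL * suspension_uL / 1000`.
#' @export
cells_in_assay <- function(cells_per_mL, suspension_uL) {
  stopifnot(cells_per_mL > 0, suspension_uL > 0)
  cells_per_mL * suspension_uL / 1000
}

#' Specific activity and turnover from an endpoint measurement
#'
#' Converts a measured product concentration after a fixed incubation into
#' per-cell and per-enzyme turnover figures:
#' * total rate (nmol/s) `= conc_uM * assay_vol_mL / time_s / 1000`
#'   (1 µM in 1 mL is 1 nmol);
#' * specific activity (nkat per cell) `= rate / cells`;
#' * k_cat per cell (molecules per cell per second)
#'   `= specific * 6.02214076e23 * 1e-9`;
#' * per-protein turnover (1/s) `= k_cat per cell / copies` when the enzyme
#'   copy number per cell is known.
#'
#' No dilution correction is applied for the quench acid (10 µL in 1 mL,
#' below 1%).
#'
#' @param conc_uM Product concentration at quench (µM).
#' @param time_s Incubation time (s, > 0).
#' @param assay_vol_mL Assay volume (mL), 1.0 for the standard vial.
#' @param cells Number of cells (or cell-equivalents of extract) in the
#'   assay; see [cells_in_assay()].
#' @param copies_per_cell Optional enzyme copies per cell.
#' @return A tibble with columns `rate_nmol_s`, `cells`,
#'   `specific_nkat_cell`, `kcat_cell`, and `kcat_protein` (NA when
#'   `copies_per_cell` is NULL).
#' @examples
#' activity(9.0, 10, 1.0, cells_in_assay(6.7e8, 625), copies_per_cell = 100)
#' @export
activity <- function(conc_uM, time_s, assay_vol_mL, cells,
                     copies_per_cell = NULL) {
  stopifnot(conc_uM >= 0, time_s > 0, assay_vol_mL > 0, cells > 0)
  # 1 uM * 1 mL = 1e-6 mol/L * 1e-3 L = 1e-9 mol = 1 nmol
  rate_nmol_s <- conc_uM * assay_vol_mL / time_s
  specific <- rate_nmol_s / cells
  kcat_cell <- specific * 1e-9 * avogadro
  kcat_protein <- if (is.null(copies_per_cell)) NA_real_ else {
    stopifnot(copies_per_cell > 0)
    kcat_cell / copies_per_cell
  }
  tibble::tibble(rate_nmol_s = rate_nmol_s, cells = cells,
                 specific_nkat_cell = specific, kcat_cell = kcat_cell,
                 kcat_protein = kcat_protein)
}

#' Batch activity table
#'
#' Applies [activity()] row-wise to a table of endpoint measurements.
#'
#' @param inputs A data frame with columns `condition_id`, `conc_uM`,
#'   `time_s`, `assay_vol_mL`, `susp_vol_uL`, `cell_density_per_mL` and
#'   optionally `copies_per_cell`.
#' @return The input keys joined with the [activity()] outputs.
#' @export
activity_table <- function(inputs) {
  need <- c("condition_id", "conc_uM", "time_s", "assay_vol_mL",
            "susp_vol_uL", "cell_density_per_mL")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(inputs)), function(i) {
    r <- inputs[i, ]
    copies <- if ("copies_per_cell" %in% names(inputs) &&
                  !is.na(r$copies_per_cell)) r$copies_per_cell else NULL
    res <- activity(r$conc_uM, r$time_s, r$assay_vol_mL,
                    cells_in_assay(r$cell_density_per_mL, r$susp_vol_uL),
                    copies)
    dplyr::bind_cols(tibble::tibble(condition_id = r$condition_id), res)
  })
  dplyr::bind_rows(rows)
}

#' Round to significant figures, half away from zero
#'
#' Reporting helper for "about" values (e.g. 1.29e6 -> 1e6 at one
#' significant figure). Ties round away from zero.
#'
#' @param x Numeric vector.
#' @param n_sig Number of significant figures (>= 1).
#' @return `x` rounded to `n_sig` significant figures.
#' @export
round_sig <- function(x, n_sig) {
  stopifnot(n_sig >= 1)
  vapply(x, function(xi) {
    if (xi == 0 || !is.finite(xi)) return(xi)
    m <- floor(log10(abs(xi)))
    fac <- 10^(n_sig - 1 - m)
    sign(xi) * floor(abs(xi) * fac + 0.5) / fac
  }, numeric(1))
}
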