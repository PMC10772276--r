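#' Embedded element isotope table
#'
#' Exact masses (Da) and natural abundances (IUPAC 2021 representative
#' values) for the elements needed to model halogenated dehalogenation
#' products at unit mass resolution: C, H, O, N, Cl, Br, plus "D" as a
#' pseudo-element (pure 2H) used for the deuterium-labelled position.
#'
#' @format A named list; each element is a data frame with columns
#'   `mass` (Da, strictly increasing) and `abundance` (fractions summing
#'   to 1).
#' @export
isotope_table <- function() {
  list(
    C  = data.frame(mass = c(12.0, 13.00335483507),
                    abundance = c(0.9893, 0.0107)),
    H  = data.frame(mass = c(1.00782503207, 2.01410177785),
                    abundance = c(0.999885, 0.000115)),
    # pseudo-element: a position known to carry deuterium
    D  = data.frame(mass = 2.01410177785, abundance = 1.0),
    O  = data.frame(mass = c(15.99491461957, 16.9991317565, 17.99915961287),
                    abundance = c(0.99757, 0.00038, 0.00205)),
    N  = data.frame(mass = c(14.00307400443, 15.00010889888),
                    abundance = c(0.99636, 0.00364)),
    Cl = data.frame(mass = c(34.968852682, 36.965902602),
                    abundance = c(0.7576, 0.2424)),
    Br = data.frame(mass = c(78.9183376, 80.9162897),
                    abundance = c(0.5069, 0.4931))
  )
}

#' Validate an element isotope table
#'
#' Checks the structural invariants every isotope table must satisfy:
#' abundances per element sum to 1 (within 1e-9) and are non-negative,
#' and masses are strictly increasing within an element.
#'
#' @param tab A named list of data frames as returned by [isotope_table()].
#' @return Invisibly, `tab`; errors describe the first violated invariant.
#' @export
validate_isotope_table <- function(tab) {
  stopifnot(is.list(tab), length(tab) >= 1, !is.null(names(tab)))
  for (el in names(tab)) {
    d <- tab[[el]]
    if (!all(c("mass", "abundance") %in% names(d)))
      stop("isotope table entry for '", el, "' lacks mass/abundance columns")
    if (any(d$abundance < 0))
      stop("negative abundance for element '", el, "'")
    if (abs(sum(d$abundance) - 1) > 1e-9)
      stop("abundances for element '", el, "' do not sum to 1")
    if (nrow(d) > 1 && any(diff(d$mass) <= 0))
      stop("masses for element '", el, "' are not strictly increasing")
  }
  invisible(tab)
}

#' Parse a molecular formula in Hill-like notation
#'
#' Parses strings such as `"C6H4Br2O"` or `"C6H3Cl3"` into named integer
#' counts. Element symbols are case-sensitive; `"D"` (deuterium at a
#' defined position) is accepted and counted separately from `"H"`.
#'
#' @param formula A single formula string.
#' @param tab Isotope table used to validate element symbols.
#' @return A named integer vector of atom counts.
#' @examples
#' parse_formula("C6H4Br2O")
#' @export
parse_formula <- function(formula, tab = isotope_table()) {
  if (is.numeric(formula) || !is.character(formula) || length(formula) != 1)
    stop("formula must be a single character string")
  if (!nzchar(formula)) stop("formula is empty")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(pieces)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  counts <- integer(0)
  for (p in pieces) {
    sym <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(tab))
      stop("unknown element symbol '", sym, "' in formula '", formula, "'")
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  if (sum(counts) < 1) stop("formula must contain at least one atom")
  counts
}

as_formula_counts <- function(f, tab = isotope_table()) {
  if (is.character(f)) return(parse_formula(f, tab))
  stopifnot(is.numeric(f), !is.null(names(f)))
  if (any(f < 0) || any(f != round(f))) stop("atom counts must be non-negative integers")
  if (sum(f) < 1) stop("formula must contain at least one atom")
  unknown <- setdiff(names(f)[f > 0], names(tab))
  if (length(unknown))
    stop("unknown element symbol '", unknown[[1]], "'")
  stats::setNames(as.integer(f), names(f))
}

#' Construct an isotope pattern
#'
#' An isotope pattern is a discrete distribution of relative abundance over
#' integer mass-shift bins 0, 1, 2, ... above a base nominal m/z.
#'
#' @param base_mz Integer nominal m/z of bin 0.
#' @param abundance Numeric vector of relative abundances for bins
#'   0, 1, 2, ...; non-negative.
#' @param tail Abundance mass discarded by truncation (default 0).
#' @return An object of class `isotope_pattern`.
#' @export
isotope_pattern <- function(base_mz, abundance, tail = 0) {
  stopifnot(length(base_mz) == 1, base_mz == round(base_mz))
  if (any(abundance < 0)) stop("pattern abundances must be non-negative")
  structure(list(base_mz = as.integer(base_mz),
                 abundance = as.numeric(abundance),
                 tail = as.numeric(tail)),
            class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> base m/z", x$base_mz, "\n")
  print(stats::setNames(round(x$abundance, 6), x$base_mz + seq_along(x$abundance) - 1L))
  if (x$tail > 0) cat("truncated tail mass:", format(x$tail, digits = 3), "\n")
  invisible(x)
}

#' Convolve two isotope patterns
#'
#' The envelope of a molecule is the convolution of the envelopes of its
#' parts: bin k of the result is `sum_i p_i * q_(k-i)`, and base m/z add.
#'
#' @param p,q Objects of class `isotope_pattern`.
#' @return An `isotope_pattern` of length `length(p) + length(q) - 1`.
#' @export
convolve_patterns <- function(p, q) {
  stopifnot(inherits(p, "isotope_pattern"), inherits(q, "isotope_pattern"))
  np <- length(p$abundance); nq <- length(q$abundance)
  out <- numeric(np + nq - 1L)
  for (i in seq_len(np)) {
    out[i:(i + nq - 1L)] <- out[i:(i + nq - 1L)] + p$abundance[i] * q$abundance
  }
  isotope_pattern(p$base_mz + q$base_mz, out, tail = p$tail + q$tail)
}

truncate_pattern <- function(p, max_shift) {
  n <- length(p$abundance)
  if (n - 1L <= max_shift) return(p)
  keep <- p$abundance[seq_len(max_shift + 1L)]
  tail_mass <- sum(p$abundance[(max_shift + 2L):n])
  isotope_pattern(p$base_mz, keep / sum(keep), tail = p$tail + tail_mass)
}

element_pattern <- function(el, tab) {
  d <- tab[[el]]
  bins <- as.integer(round(d$mass - d$mass[1]))
  ab <- numeric(max(bins) + 1L)
  for (i in seq_along(bins)) ab[bins[i] + 1L] <- ab[bins[i] + 1L] + d$abundance[i]
  isotope_pattern(round_half_away(d$mass[1]), ab)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Theoretical isotopologue envelope for a molecular formula
#'
#' Convolves per-element isotope patterns raised to their atom counts. Bin 0
#' is the all-lightest-isotope (monoisotopic) species. The pattern is
#' truncated at `max_shift` and renormalized; the discarded tail mass is
#' recorded in the result.
#'
#' @param f Formula string (Hill-like, e.g. `"C6H4Br2O"`) or named counts.
#' @param max_shift Highest retained mass-shift bin (default 6).
#' @param tab Isotope table.
#' @return An `isotope_pattern` whose `base_mz` is the nominal molecular-ion
#'   m/z of the monoisotopic species.
#' @examples
#' pattern_for_formula("C6H4Br2O")
#' @export
pattern_for_formula <- function(f, max_shift = 6L, tab = isotope_table()) {
  stopifnot(max_shift >= 1)
  validate_isotope_table(tab)
  counts <- as_formula_counts(f, tab)
  counts <- counts[counts > 0]
  # base m/z must round the summed monoisotopic mass, not the sum of
  # per-element roundings (H: 1.0078 * 4 rounds to 4, not 4 * 1)
  mono <- sum(vapply(names(counts),
                     function(el) tab[[el]]$mass[1] * counts[[el]], numeric(1)))
  acc <- isotope_pattern(0L, 1.0)
  for (el in names(counts)) {
    ep <- element_pattern(el, tab)
    ep$base_mz <- 0L
    for (i in seq_len(counts[[el]])) {
      acc <- convolve_patterns(acc, ep)
    }
  }
  # single truncation at the end: intermediate renormalization would
  # compound and bias the kept bins
  acc <- truncate_pattern(acc, max_shift)
  ab <- acc$abundance
  if (length(ab) < max_shift + 1L) ab <- c(ab, numeric(max_shift + 1L - length(ab)))
  isotope_pattern(round_half_away(mono), ab, tail = acc$tail)
}

#' Nominal molecular-ion m/z of a formula
#'
#' Sum of the lightest-isotope exact masses, rounded half away from zero to
#' the nearest integer — the unit-resolution m/z at which the monoisotopic
#' molecular ion is detected (e.g. 250 for dibromophenol C6H4Br2O, 180 for
#' trichlorobenzene C6H3Cl3).
#'
#' @inheritParams pattern_for_formula
#' @return Integer nominal m/z.
#' @export
nominal_molecular_ion_mz <- function(f, tab = isotope_table()) {
  counts <- as_formula_counts(f, tab)
  counts <- counts[counts > 0]
  mono <- sum(vapply(names(counts),
                     function(el) tab[[el]]$mass[1] * counts[[el]], numeric(1)))
  as.integer(round_half_away(mono))
}

substitute_h_with_d <- function(counts) {
  if (!("H" %in% names(counts)) || counts[["H"]] < 1)
    stop("formula has no H to label")
  counts[["H"]] <- counts[["H"]] - 1L
  counts[["D"]] <- (if ("D" %in% names(counts)) counts[["D"]] else 0L) + 1L
  counts
}

#' Envelope of a partially deuterium-labelled product
#'
#' The dehalogenation product carries exactly one labelable position (the
#' C–H bond formed by halogen replacement). A true deuteration fraction
#' `dd_true` gives the mixture
#' `(1 - dd_true) * pattern(f) + dd_true * pattern(f with one H -> D)`;
#' the deuterated species sits one bin higher.
#'
#' @inheritParams pattern_for_formula
#' @param dd_true Fraction of product molecules carrying D at the labelable
#'   position, in `[0, 1]`.
#' @return An `isotope_pattern` based at the unlabeled nominal m/z.
#' @export
labeled_pattern <- function(f, dd_true, max_shift = 6L, tab = isotope_table()) {
  if (dd_true < 0 || dd_true > 1) stop("dd_true must be in [0, 1]")
  counts <- as_formula_counts(f, tab)
  p_h <- pattern_for_formula(counts, max_shift, tab)
  counts_d <- substitute_h_with_d(counts)
  p_d <- pattern_for_formula(counts_d, max_shift, tab)
  # align: deuterated base m/z = unlabeled + 1
  n <- max_shift + 2L
  ab <- numeric(n)
  ab[seq_len(max_shift + 1L)] <- (1 - dd_true) * p_h$abundance
  ab[1L + seq_len(max_shift + 1L)] <- ab[1L + seq_len(max_shift + 1L)] +
    dd_true * p_d$abundance
  isotope_pattern(p_h$base_mz, ab,
                  tail = (1 - dd_true) * p_h$tail + dd_true * p_d$tail)
}

#' DD1 predicted from a true deuteration fraction
#'
#' Applies the first-peak-pair deuteration degree `B1 / (A1 + B1)` to the
#' theoretical labelled envelope: A1 is bin 0 (nominal molecular ion) and
#' B1 is bin 1. At `dd_true = 0` this returns the natural-abundance M+1
#' bias (heavy isotopes of C, H, O alone put mass in B1); it is strictly
#' increasing in `dd_true`.
#'
#' @inheritParams labeled_pattern
#' @return The DD1 fraction in `[0, 1]`.
#' @export
predicted_dd1 <- function(dd_true, f, max_shift = 6L, tab = isotope_table()) {
  vapply(dd_true, function(d) {
    p <- labeled_pattern(f, d, max_shift, tab)
    a1 <- p$abundance[1]; b1 <- p$abundance[2]
    b1 / (a1 + b1)
  }, numeric(1))
}

#' Correct an observed DD1 for natural M+1 abundance
#'
#' Numerically inverts [predicted_dd1()] to recover the true deuteration
#' fraction from an observed DD1, removing the natural-abundance bias of
#' the uncorrected first-peak-pair estimator. Observations below the
#' `dd_true = 0` baseline are clipped to 0 and flagged.
#'
#' @param dd1_obs Observed DD1 in `[0, 1]`.
#' @inheritParams labeled_pattern
#' @return The inferred `dd_true` in `[0, 1]`, with attribute
#'   `below_baseline` (logical) set when the observation lies below the
#'   natural-abundance floor.
#' @export
correct_dd1_for_natural_abundance <- function(dd1_obs, f, max_shift = 6L,
                                              tab = isotope_table()) {
  if (dd1_obs < 0 || dd1_obs > 1) stop("dd1_obs must be in [0, 1]")
  base <- predicted_dd1(0, f, max_shift, tab)
  if (dd1_obs <= base) {
    warn <- dd1_obs < base
    if (warn)
      warning("observed DD1 below the natural-abundance baseline; returning 0")
    return(structure(0, below_baseline = warn))
  }
  top <- predicted_dd1(1, f, max_shift, tab)
  if (dd1_obs >= top) return(structure(1, below_baseline = FALSE))
  root <- stats::uniroot(function(d) predicted_dd1(d, f, max_shift, tab) - dd1_obs,
                         interval = c(0, 1), tol = 1e-12)$root
  structure(min(max(root, 0), 1), below_baseline = FALSE)
}

#' Export an isotope pattern as a data frame
#'
#' @param p An `isotope_pattern`.
#' @return A tibble with columns `nominal_mz` and `rel_abundance`.
#' @export
pattern_as_table <- function(p) {
  stopifnot(inherits(p, "isotope_pattern"))
  tibble::tibble(nominal_mz = p$base_mz + seq_along(p$abundance) - 1L,
                 rel_abundance = p$abundance)
}
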