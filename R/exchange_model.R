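#' Exchange and discrimination parameters
#'
#' Parameters of the compartmental water-exchange and isotope-discrimination
#' model: first-order exchange of cytoplasmic water with the (effectively
#' infinite) external assay pool, an apparent H-over-D preference factor at
#' incorporation, and a constant per-cell product formation rate.
#'
#' Defaults encode the study conditions the generator emulates: a membrane
#' water-exchange half-life of 90 s (`k_ex = log(2)/90 ~ 7.7e-3` per second,
#' ~99% equilibration within 10 min), a preference factor `alpha = 1.9`
#' (protons favoured over deuterons roughly two-fold, putting the
#' 50%-D2O plateau near 35%), and a production rate of 1.3e6 product
#' molecules per cell per second.
#'
#' @param k_ex Water exchange rate across the membrane, per second (>= 0).
#' @param alpha Apparent H-over-D preference factor (> 0; 1 = none).
#' @param r Product formation rate, molecules per cell per second (>= 0).
#' @param assay_volume_mL Total assay volume in mL.
#' @return A list of class `exchange_params`.
#' @export
exchange_params <- function(k_ex = log(2) / 90, alpha = 1.9, r = 1.3e6,
                            assay_volume_mL = 1.0) {
  stopifnot(k_ex >= 0, alpha > 0, r >= 0, assay_volume_mL > 0)
  structure(list(k_ex = k_ex, alpha = alpha, r = r,
                 assay_volume_mL = assay_volume_mL),
            class = "exchange_params")
}

#' Volume-weighted D2O fraction of a mixture
#'
#' The overall heavy-water content of an assay vial assembled from pipetted
#' components, `sum(v_i f_i) / sum(v_i)`. Cytoplasmic water volume is
#' ignored (assay water volume >> total cytoplasm volume).
#'
#' @param components A data frame or list of `(volume_uL, d2o_fraction)`
#'   pairs; a list of length-2 numeric vectors is accepted.
#' @return The mixture D2O fraction, within `[min f, max f]`.
#' @examples
#' mixture_fraction(list(c(625, 0.80), c(375, 0)))  # 0.50
#' @export
mixture_fraction <- function(components) {
  if (is.data.frame(components)) {
    v <- components[[1]]; f <- components[[2]]
  } else {
    if (length(components) == 0) stop("component list is empty")
    v <- vapply(components, `[`, numeric(1), 1)
    f <- vapply(components, `[`, numeric(1), 2)
  }
  if (length(v) == 0) stop("component list is empty")
  if (any(v <= 0)) stop("component volumes must be positive")
  if (any(f < 0 | f > 1)) stop("D2O fractions must be in [0, 1]")
  sum(v * f) / sum(v)
}

#' Cytoplasmic D2O fraction over time
#'
#' First-order equilibration of the cytoplasmic water pool toward the
#' external pool, treated as an infinite reservoir:
#' `x(t) = x_ext + (x_in0 - x_ext) * exp(-k_ex * t)`.
#'
#' @param t Time in seconds (vectorized, >= 0).
#' @param x_in0 Initial cytoplasmic D2O fraction.
#' @param x_ext External (assay solution) D2O fraction.
#' @param k_ex Exchange rate, per second.
#' @return The cytoplasmic D2O fraction at each `t`.
#' @export
cytoplasm_fraction <- function(t, x_in0, x_ext, k_ex) {
  stopifnot(all(t >= 0), k_ex >= 0)
  x_ext + (x_in0 - x_ext) * exp(-k_ex * t)
}

#' Instantaneous product deuteration under H/D discrimination
#'
#' Fraction of newly formed product carrying D when the proton-donating
#' water pool has D fraction `x_D` and the machinery prefers H over D by
#' factor `alpha`: `x_D / (x_D + alpha * (1 - x_D))`. Equals `x_D` at
#' `alpha = 1` and decreases in `alpha`.
#'
#' @param x_D D fraction of the donating pool (vectorized, in `[0, 1]`).
#' @param alpha H-over-D preference factor (> 0).
#' @return The instantaneous deuteration fraction.
#' @export
instantaneous_dd <- function(x_D, alpha) {
  stopifnot(all(x_D >= 0 & x_D <= 1), alpha > 0)
  x_D / (x_D + alpha * (1 - x_D))
}

#' Time-averaged deuteration of accumulated product
#'
#' For whole cells producing at a constant rate while the cytoplasm
#' equilibrates, the deuteration of the product pool harvested at time `t`
#' is the time average
#' `(1/t) * integral_0^t instantaneous_dd(cytoplasm_fraction(tau), alpha) dtau`.
#' For crude extracts (no compartments) it equals
#' `instantaneous_dd(x_ext, alpha)` at every time.
#'
#' The integral is evaluated in closed form. With
#' `u(tau) = x_ext + c * exp(-k tau)` (`c = x_in0 - x_ext`) the integrand is
#' `(x_ext + c w) / (A + B w)` in `w = exp(-k tau)`, where
#' `A = alpha + (1 - alpha) x_ext` and `B = (1 - alpha) c`, whose
#' antiderivative is elementary.
#'
#' @param t Time in seconds (vectorized, > 0).
#' @param params An [exchange_params()] object (or list with `k_ex`, `alpha`).
#' @param condition An [assay_condition()] object supplying `x_in0`, `x_ext`
#'   and the whole-cell flag.
#' @return The cumulative product deuteration fraction at each `t`.
#' @export
cumulative_product_dd <- function(t, params, condition) {
  if (any(t <= 0)) stop("t must be positive")
  alpha <- params$alpha
  x_ext <- condition$x_ext
  if (!condition$whole_cell)
    return(rep(instantaneous_dd(x_ext, alpha), length(t)))
  k <- params$k_ex
  x0 <- condition$x_in0
  cc <- x0 - x_ext
  if (k == 0 || cc == 0)
    return(rep(instantaneous_dd(if (k == 0) x0 else x_ext, alpha), length(t)))
  A <- alpha + (1 - alpha) * x_ext
  B <- (1 - alpha) * cc
  vapply(t, function(ti) {
    w <- exp(-k * ti)
    if (abs(B) < 1e-14) {
      # alpha == 1: integrand is (x_ext + c w) / A
      int <- (x_ext * ti + cc * (1 - w) / k) / A
    } else {
      # int 1/(A + B w) dtau = tau/A + log((A + B w)/(A + B)) / (A k)
      inv_int <- ti / A + (log(A + B * w) - log(A + B)) / (A * k)
      int <- (cc / B) * ti + (x_ext - cc * A / B) * inv_int
    }
    int / ti
  }, numeric(1))
}
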