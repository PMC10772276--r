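#' Specification of an exchange-model fit
#'
#' Declares which parameters of the water-exchange model are free
#' (`k_ex`, `alpha`, `x_in0`), fixed values for the rest, per-parameter
#' bounds, the coarse initialization grid, and convergence controls.
#'
#' Default bounds span half-lives from ~10 s to ~3 h around the expected
#' ten-minute equilibration: `k_ex` in `[1e-4, 1]` /s (log grid of 25),
#' `alpha` in `[0.2, 10]` (log grid of 25), `x_in0` in `[0, 1]` (linear
#' grid of 11).
#'
#' @param free Character vector of free parameter names.
#' @param fixed Named list of values for parameters not in `free`.
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param grid_n Named list of grid sizes per parameter.
#' @param tol RSS improvement threshold declaring convergence.
#' @param max_eval Maximum model evaluations in the local refinement.
#' @return A list of class `fit_spec`.
#' @export
fit_spec <- function(free = c("k_ex", "alpha"),
                     fixed = list(),
                     bounds = list(k_ex = c(1e-4, 1),
                                   alpha = c(0.2, 10),
                                   x_in0 = c(0, 1)),
                     grid_n = list(k_ex = 25, alpha = 25, x_in0 = 11),
                     tol = 1e-10, max_eval = 2000) {
  free <- match.arg(free, c("k_ex", "alpha", "x_in0"), several.ok = TRUE)
  if (length(free) < 1) stop("at least one free parameter required")
  for (p in free) {
    b <- bounds[[p]]
    if (is.null(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("invalid bounds for ", p)
  }
  structure(list(free = free, fixed = fixed, bounds = bounds,
                 grid_n = grid_n, tol = tol, max_eval = max_eval),
            class = "fit_spec")
}

param_grid_values <- function(p, spec) {
  b <- spec$bounds[[p]]
  n <- spec$grid_n[[p]]
  if (p == "x_in0") seq(b[1], b[2], length.out = n)
  else exp(seq(log(b[1]), log(b[2]), length.out = n))
}

#' Fit the water-exchange model to a DD1 time course
#'
#' Recovers the exchange rate `k_ex`, the H-over-D preference factor
#' `alpha`, and optionally the initial cytoplasmic D2O fraction `x_in0`
#' from observed DD1 means by least squares against the forward model
#' `predicted_dd1(cumulative_product_dd(t), formula)`. A coarse grid
#' search over the bounds (log-spaced for rates and preference factors)
#' seeds a Nelder-Mead simplex refinement on box-transformed parameters,
#' so estimates always respect the bounds. Grid ties are broken toward
#' smaller `k_ex` (the smoother model). The objective weights replicate
#' means equally; an inverse-variance weighting is available but off by
#' default (triplicate standard deviations are unstable).
#'
#' @param tc A DD1 time course as from [dd_timecourse()] (columns
#'   `time_s`, `dd1_mean`), single condition, >= 3 time points.
#' @param condition The [assay_condition()] the course was measured under
#'   (supplies `x_ext`, the whole-cell flag, and the product formula).
#' @param spec A [fit_spec()].
#' @param weights Optional per-time weights (e.g. `1/sd^2`).
#' @return A list of class `exchange_fit`: `estimates` (named list),
#'   `rss`, `n_eval`, `converged`, `fitted` (tibble `time_s`, `dd1_fit`).
#' @export
fit_exchange_model <- function(tc, condition, spec = fit_spec(),
                               weights = NULL) {
  stopifnot(inherits(condition, "assay_condition"))
  times <- tc$time_s
  obs <- tc$dd1_mean
  if (length(times) < 3) stop("need at least 3 time points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  w <- if (is.null(weights)) rep(1, length(obs)) else weights
  non_ident <- length(unique(signif(obs, 12))) == 1 && length(spec$free) >= 2
  if (non_ident)
    warning("all DD1 means identical: parameters not jointly identifiable")

  # precompute envelope pieces: predicted DD1 is a Moebius function of the
  # true deuteration fraction
  ph <- pattern_for_formula(condition$product)$abundance
  pd <- pattern_for_formula(
    substitute_h_with_d(as_formula_counts(condition$product)))$abundance
  dd1_of_true <- function(d) {
    b1 <- (1 - d) * ph[2] + d * pd[1]
    a1 <- (1 - d) * ph[1]
    b1 / (a1 + b1)
  }

  n_eval <- 0L
  model_curve <- function(theta) {
    n_eval <<- n_eval + 1L
    params <- exchange_params(
      k_ex = theta[["k_ex"]], alpha = theta[["alpha"]])
    cond <- condition
    if ("x_in0" %in% names(theta)) cond$x_in0 <- theta[["x_in0"]]
    dd1_of_true(cumulative_product_dd(times, params, cond))
  }
  full_theta <- function(free_vals) {
    th <- list(k_ex = condition_default(spec, "k_ex"),
               alpha = condition_default(spec, "alpha"),
               x_in0 = condition$x_in0)
    th[names(spec$fixed)] <- spec$fixed
    th[names(free_vals)] <- as.list(free_vals)
    th
  }
  rss_of <- function(free_vals) {
    m <- model_curve(full_theta(free_vals))
    sum(w * (obs - m)^2)
  }

  # coarse grid
  grids <- lapply(stats::setNames(spec$free, spec$free),
                  param_grid_values, spec = spec)
  grid <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  rss_grid <- apply(grid, 1, function(row) rss_of(as.list(row)))
  best_idx <- which(rss_grid == min(rss_grid))
  if (length(best_idx) > 1 && "k_ex" %in% spec$free)
    best_idx <- best_idx[which.min(grid$k_ex[best_idx])]
  best <- as.list(grid[best_idx[1], , drop = FALSE])
  names(best) <- spec$free

  # box transform: theta = lo + (hi - lo) * plogis(z)
  lo <- vapply(spec$free, function(p) spec$bounds[[p]][1], numeric(1))
  hi <- vapply(spec$free, function(p) spec$bounds[[p]][2], numeric(1))
  to_z <- function(v) {
    fr <- pmin(pmax((unlist(v) - lo) / (hi - lo), 1e-8), 1 - 1e-8)
    stats::qlogis(fr)
  }
  from_z <- function(z) {
    v <- lo + (hi - lo) * stats::plogis(z)
    stats::setNames(as.list(v), spec$free)
  }
  obj <- function(z) rss_of(from_z(z))
  rss0 <- rss_of(best)
  if (length(spec$free) == 1) {
    opt <- stats::optim(to_z(best), obj, method = "Brent",
                        lower = stats::qlogis(1e-8),
                        upper = stats::qlogis(1 - 1e-8),
                        control = list(maxit = spec$max_eval))
  } else {
    opt <- stats::optim(to_z(best), obj, method = "Nelder-Mead",
                        control = list(maxit = spec$max_eval,
                                       reltol = 1e-12))
  }
  est <- from_z(opt$par)
  rss <- opt$value
  converged <- !non_ident && (opt$convergence == 0 ||
                              abs(rss0 - rss) < spec$tol)
  fitted <- model_curve(full_theta(est))
  structure(list(estimates = est, rss = rss, n_eval = n_eval,
                 converged = converged,
                 fitted = tibble::tibble(time_s = times, dd1_fit = fitted)),
            class = "exchange_fit")
}

condition_default <- function(spec, p) {
  if (!is.null(spec$fixed[[p]])) return(spec$fixed[[p]])
  defaults <- list(k_ex = log(2) / 90, alpha = 1.9, x_in0 = 0)
  defaults[[p]]
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("<exchange_fit>", if (x$converged) "converged" else "NOT converged", "\n")
  for (p in names(x$estimates))
    cat(sprintf("  %-5s = %.6g\n", p, x$estimates[[p]]))
  cat(sprintf("  RSS = %.3e over %d model evaluations\n", x$rss, x$n_eval))
  invisible(x)
}
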