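# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: envelopes by exhaustive enumeration
# over per-atom isotope assignments, integrals by adaptive quadrature,
# tail probabilities by integrating the explicit density.

# Exhaustive isotopologue envelope: abundance over nominal shift bins,
# enumerating every isotope assignment of every atom. Feasible for small
# molecules (<= ~8 atoms).
enumerate_pattern <- function(f, tab = deutrace::isotope_table()) {
  counts <- deutrace::parse_formula(f, tab)
  atoms <- rep(names(counts), counts)
  opts <- lapply(atoms, function(el) {
    d <- tab[[el]]
    list(shift = as.integer(round(d$mass - d$mass[1])),
         ab = d$abundance)
  })
  idx <- expand.grid(lapply(opts, function(o) seq_along(o$ab)),
                     KEEP.OUT.ATTRS = FALSE)
  shifts <- numeric(nrow(idx)); probs <- rep(1, nrow(idx))
  for (j in seq_along(opts)) {
    shifts <- shifts + opts[[j]]$shift[idx[[j]]]
    probs <- probs * opts[[j]]$ab[idx[[j]]]
  }
  ab <- vapply(0:max(shifts), function(s) sum(probs[shifts == s]), numeric(1))
  ab
}

# Two-sided Student-t p-value by numeric integration of the explicit
# density (gamma-function form), independent of pt().
t_pvalue_integrate <- function(t_stat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t_stat), Inf, rel.tol = 1e-10)$value
}

# Time-averaged instantaneous deuteration by adaptive quadrature -- the
# numeric route the closed form in the package must agree with.
cumulative_dd_quadrature <- function(t, k_ex, alpha, x_in0, x_ext) {
  f <- function(tau) {
    x <- x_ext + (x_in0 - x_ext) * exp(-k_ex * tau)
    x / (x + alpha * (1 - x))
  }
  stats::integrate(f, 0, t, rel.tol = 1e-10)$value / t
}

# Random small isotope pattern for algebraic property tests.
random_pattern <- function(n_bins = sample(2:5, 1)) {
  ab <- stats::runif(n_bins)
  deutrace::isotope_pattern(sample(10:200, 1), ab / sum(ab))
}

# Single-isotope table: hypothetical pure-light elements, used to expose
# the labelled-mixture arithmetic without natural-abundance blur.
pure_isotope_table <- function() {
  tab <- deutrace::isotope_table()
  tab$C <- data.frame(mass = 12.0, abundance = 1.0)
  tab$H <- data.frame(mass = 1.00782503207, abundance = 1.0)
  tab$O <- data.frame(mass = 15.99491461957, abundance = 1.0)
  tab
}
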