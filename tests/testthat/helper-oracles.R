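# Shared fixtures and independent oracles for the test suite.

default_ctx <- thermal_context(298)
barnase_elastic <- elastic_params(persistence_length = 0.8,
                                  monomer_length = 0.37,
                                  n_monomers = 110, dipole_length = 3)

# study configuration without the hairpin configuration warning
study_cfg <- function(seed = 1L) {
  suppressWarnings(make_study_defaults(seed = seed, warn = FALSE))$barnase
}

# Independent brute-force inverse of the WLC interpolation formula:
# scan a dense z grid and return the grid point whose force is closest.
oracle_relative_extension <- function(f, Lp = 0.8, ctx = default_ctx,
                                      ngrid = 1e4) {
  z <- seq(0, 1 - 1e-6, length.out = ngrid)
  fz <- (ctx$kBT / (4 * Lp)) * ((1 - z)^-2 + 4 * z - 1)
  vapply(f, function(fi) z[which.min(abs(fz - fi))], numeric(1))
}

# Quadrature CDF of rupture forces under a ramp: numerically integrate the
# hazard over force (independent of the closed-form survival used by the
# sampler). Returns a vectorized CDF function for use with ks.test.
oracle_rupture_cdf <- function(cfg, direction, step = 1e-3) {
  g <- seq(cfg$f_start, cfg$f_end, by = step)
  k <- if (direction == "unfold") {
    unfold_rate(g, cfg$be, cfg$ctx)
  } else {
    fold_rate(g, cfg$be, cfg$ctx)
  }
  h <- k / cfg$loading_rate
  cum <- c(0, cumsum(diff(g) * (head(h, -1) + tail(h, -1)) / 2))
  if (direction == "unfold") {
    # P(rupture force <= f) pulling up from f_start
    Fg <- 1 - exp(-cum)
    function(q) stats::approx(g, Fg, xout = q, yleft = 0, yright = 1)$y
  } else {
    # relaxing down from f_end: P(rupture force <= f) = survival down to f
    Fg <- exp(-(cum[length(cum)] - cum))
    function(q) stats::approx(g, Fg, xout = q, yleft = 0, yright = 1)$y
  }
}

# Histogram of the analytic rupture-force law on given edges: bin masses are
# quadrature-CDF differences, so the edge survivals of the histogram are the
# true survival up to quadrature error.
analytic_distribution <- function(cfg, direction, edges) {
  cdf <- oracle_rupture_cdf(cfg, direction, step = 5e-4)
  mass <- diff(cdf(edges))
  dens <- mass / diff(edges) / sum(mass)
  empirical_distribution(edges, dens, direction = direction)
}

# Detect the first transition of a generated trace the way the pipeline does.
detect_event <- function(gen, cfg, baseline, median_window = 11L) {
  trf <- median_filter(gen$trace, median_window)
  labels <- classify_states(trf, baseline, elastic = cfg$elastic, ctx = cfg$ctx)
  first_transition_force(labels, trf)
}
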