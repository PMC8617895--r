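# Densities, survival probabilities, the k = r rho / S identity and dwell
# rates from hopping traces.

test_that("rupture densities are normalized histograms on aligned bins", {
  s <- rupture_sample(rep(12.3, 10), "unfold", loading_rate = 6)
  d <- rupture_density(s, bin_width = 1)
  expect_equal(sum(d$density * diff(d$bin_edges)), 1, tolerance = 1e-12)
  expect_equal(max(d$density), 1)  # all mass in one 1-pN bin
  for (seed in 1:5) {
    set.seed(seed)
    s2 <- rupture_sample(rnorm(500, 18, 1.5), "unfold", 6)
    d2 <- rupture_density(s2)
    expect_equal(sum(d2$density * diff(d2$bin_edges)), 1, tolerance = 1e-9)
    expect_true(all(d2$density >= 0))
    expect_equal(sum(d2$counts), 500)
  }
  expect_error(rupture_sample(numeric(0), "unfold", 6), "at least one")
  expect_error(empirical_distribution(c(0, 1, 2), c(0.9, 0.3)), "integrate")
})

test_that("survival curves are proper, monotone and pinned at the sweep start", {
  cfg <- study_cfg()
  set.seed(31)
  su <- sample_rupture_forces(cfg, "unfold", 10000)
  sf <- sample_rupture_forces(cfg, "fold", 10000)
  du <- rupture_density(su); df_ <- rupture_density(sf)
  Pu <- survival_from_density(du)
  Pf <- survival_from_density(df_)
  expect_equal(Pu$P[1], 1)                      # lowest edge of the pull
  expect_equal(Pu$P[length(Pu$P)], 0)
  expect_true(all(diff(Pu$P) <= 0))
  expect_equal(Pf$P[length(Pf$P)], 1)           # highest edge of the relax
  expect_true(all(diff(Pf$P) >= 0))
  expect_true(all(Pu$P >= 0 & Pu$P <= 1))
  # against the closed-form survival of the generating hazard
  Struth <- function(f) {
    bx <- cfg$ctx$beta * cfg$be$x_dagger
    k0 <- exp(cfg$be$log_k0_unfold)
    exp(-(k0 / (cfg$loading_rate * bx)) * (exp(bx * f) - exp(bx * cfg$f_start)))
  }
  expect_lt(max(abs(Pu$P - Struth(Pu$force_pN))), 0.02)
})

test_that("rates_from_survival returns the generating hazard on analytic input", {
  cfg <- study_cfg()
  for (direction in c("unfold", "fold")) {
    dist <- analytic_distribution(cfg, direction,
                                  seq(cfg$f_start, 28, by = 0.05))
    surv <- survival_from_density(dist)
    rc <- rates_from_survival(dist, surv, cfg$loading_rate)
    truth <- if (direction == "unfold") unfold_rate(rc$force_pN, cfg$be) else
      fold_rate(rc$force_pN, cfg$be)
    # away from bins whose analytic mass is at double-precision roundoff
    sel <- stats::approx(dist$mids, dist$density, rc$force_pN)$y * 0.05 > 1e-9
    expect_lt(max(abs(rc$rate_per_s / truth - 1)[sel]), 0.01)
  }
})

test_that("bins beyond the survival and count thresholds are absent", {
  set.seed(77)
  s <- rupture_sample(rnorm(400, 18, 1.2), "unfold", 6)
  d <- rupture_density(s)
  surv <- survival_from_density(d)
  rc <- rates_from_survival(d, surv, 6, min_P = 0.05, min_count = 5,
                            events = s$forces, n_boot = 50, seed = 1)
  # recompute the retention rule independently
  P_far <- tail(surv$P, -1)
  kept_mids <- d$mids[d$density > 0 & P_far >= 0.05 & d$counts >= 5]
  expect_equal(rc$force_pN, kept_mids)
  expect_true(all(rc$n_events >= 5))
  expect_true(all(rc$rate_per_s > 0))
  expect_true(all(is.finite(rc$se_log_rate)))
  expect_error(rates_from_survival(d, surv, -6), "positive")
})

test_that("the density mode sits where the hazard equals r beta x", {
  cfg <- study_cfg()
  set.seed(55)
  su <- sample_rupture_forces(cfg, "unfold", 10000)
  d <- rupture_density(su, bin_width = 0.5)
  f_mode <- d$mids[which.max(d$counts)]
  # k(f*) = r beta x_dagger at the mode of the rupture density
  target <- cfg$loading_rate * cfg$ctx$beta * cfg$be$x_dagger
  f_star <- (log(target) - cfg$be$log_k0_unfold) /
    (cfg$ctx$beta * cfg$be$x_dagger)
  expect_lt(abs(f_mode - f_star), 0.5)
})

test_that("dwell rates invert mean lifetimes and censor trace ends", {
  # alternating exact 1-s dwells sampled at 100 Hz
  n_dwell <- 20
  lab <- rep(rep(c("N", "U"), n_dwell), each = 100)
  tt <- seq_along(lab) / 100
  rates <- dwell_rates_from_labels(lab, tt)
  expect_equal(rates$k_unfold, 1, tolerance = 1e-6)
  expect_equal(rates$k_fold, 1, tolerance = 1e-6)
  # first and last dwells are censored
  expect_equal(rates$n_dwell_N + rates$n_dwell_U, 2 * n_dwell - 2)
  # simulated telegraph process with hairpin-like rates, truth labels
  beta <- default_ctx$beta
  be_hop <- be_params(4, 4, log(2) - beta * 15 * 4, log(5) + beta * 15 * 4)
  hop <- generate_hopping_trace(be_hop, f_level = 15, duration = 150,
                                sampling_rate = 200, noise_sigma = 0,
                                seed = 9)
  r2 <- dwell_rates_from_labels(hop$state, hop$time)
  expect_lt(abs(r2$k_unfold / 2 - 1), 0.15)
  expect_lt(abs(r2$k_fold / 5 - 1), 0.15)
  expect_error(dwell_rates_from_labels(rep("N", 100), 1:100 / 10),
               "no completed dwells")
  expect_error(dwell_rates_from_labels(c("N", "U", "U", "U", "N"), (1:5) / 10),
               "\"N\" has no completed dwells")
})
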