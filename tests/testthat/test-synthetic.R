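# Synthetic-data generator: closed-form rupture sampling, FDC traces with
# ground truth, telegraph hopping traces and the study defaults.

test_that("the inverse-CDF transform matches the quadrature CDF", {
  cfg <- study_cfg()
  u <- c(1, 0.999, seq(0.99, 0.01, by = -0.01), 1e-3, 1e-5)
  # u = 1 is the immediate-rupture boundary: the ramp start
  expect_equal(rupture_quantile(1, cfg$be, "unfold",
                                cfg$f_start, cfg$f_end, cfg$loading_rate,
                                cfg$ctx), cfg$f_start)
  expect_equal(rupture_quantile(1, cfg$be, "fold",
                                cfg$f_start, cfg$f_end, cfg$loading_rate,
                                cfg$ctx), cfg$f_end)
  # deterministic sup-norm check of the transform against quadrature:
  # S(f) = u, so the quadrature CDF evaluated at the quantile must be 1 - u
  fu <- rupture_quantile(u, cfg$be, "unfold", cfg$f_start, cfg$f_end,
                         cfg$loading_rate, cfg$ctx)
  cdf_u <- oracle_rupture_cdf(cfg, "unfold", step = 5e-4)
  expect_lt(max(abs(cdf_u(fu) - (1 - u))), 1e-6)
  ff <- rupture_quantile(u, cfg$be, "fold", cfg$f_start, cfg$f_end,
                         cfg$loading_rate, cfg$ctx)
  cdf_f <- oracle_rupture_cdf(cfg, "fold", step = 5e-4)
  expect_lt(max(abs(cdf_f(ff) - u)), 1e-6)
  # quantiles are monotone in u
  expect_true(all(diff(fu) > 0))
  expect_error(rupture_quantile(0, cfg$be, "unfold"), "\\(0, 1\\]")
})

test_that("rupture sampling is seed-deterministic and windowed", {
  cfg <- study_cfg()
  s1 <- sample_rupture_forces(cfg, "unfold", 500, seed = 12)
  s2 <- sample_rupture_forces(cfg, "unfold", 500, seed = 12)
  expect_identical(s1$forces, s2$forces)
  expect_true(all(s1$forces >= cfg$f_start & s1$forces <= cfg$f_end))
  expect_gte(attr(s1, "n_clipped"), 0)
})

test_that("noiseless FDC traces have exact branch geometry", {
  cfg <- study_cfg()
  cfg$noise_sigma <- 0
  set.seed(14)
  g <- generate_fdc_trace(cfg, "unfold")
  idx <- g$truth$true_index
  pre <- seq_len(idx)
  # folded-branch slope equals the effective stiffness exactly
  slopes <- diff(g$trace$force[pre]) / diff(g$trace$lambda[pre])
  expect_equal(slopes, rep(cfg$k_eff, idx - 1L), tolerance = 1e-12)
  # force at the recorded transition sample equals the sampled rupture force
  # (up to the force step of one sample, r / sampling rate)
  expect_lt(abs(g$trace$force[idx] - g$truth$sampled_force),
            2 * cfg$loading_rate / cfg$sampling_rate)
  # the post-transition branch is offset by the released-extension jump
  post1 <- idx + 1L
  f_N <- cfg$k_eff * g$trace$lambda[post1]
  expect_equal(g$trace$force[post1],
               f_N - cfg$k_eff * released_extension(f_N, cfg$elastic, cfg$ctx),
               tolerance = 1e-10)
})

test_that("the folding jump with default stiffness is ~0.5 pN near 3 pN", {
  cfg <- study_cfg()
  jump3 <- cfg$k_eff * released_extension(3, cfg$elastic, cfg$ctx)
  expect_gt(jump3, 0.4)
  expect_lt(jump3, 0.7)
})

test_that("hopping traces alternate exponential dwells on two levels", {
  beta <- default_ctx$beta
  be_hop <- be_params(4, 4, log(2) - beta * 15 * 4, log(5) + beta * 15 * 4)
  h0 <- generate_hopping_trace(be_hop, 15, duration = 30, sampling_rate = 500,
                               noise_sigma = 0, force_jump = 1, seed = 4)
  expect_setequal(unique(h0$force), c(15, 14))
  expect_setequal(unique(h0$state), c("N", "U"))
  h1 <- generate_hopping_trace(be_hop, 15, duration = 30, sampling_rate = 500,
                               noise_sigma = 0.2, seed = 4)
  h2 <- generate_hopping_trace(be_hop, 15, duration = 30, sampling_rate = 500,
                               noise_sigma = 0.2, seed = 4)
  expect_identical(h1$force, h2$force)
  expect_identical(h1$state, h2$state)
})

test_that("study defaults encode the barnase construct and flag the hairpin", {
  expect_warning(defs <- make_study_defaults(seed = 2), "hairpin")
  b <- defs$barnase
  expect_equal(b$elastic$n_monomers, 110)
  expect_equal(b$elastic$persistence_length, 0.8)
  expect_equal(b$elastic$monomer_length, 0.37)
  expect_equal(b$elastic$dipole_length, 3)
  expect_equal(b$loading_rate, 6)
  expect_equal(b$ctx$temperature, 298)
  expect_equal(defs$hairpin$n_monomers, 44)
  expect_null(defs$hairpin$elastic)
  # the chosen prefactors put the coexistence force at 9 pN
  expect_equal(coexistence_force(b$be, b$ctx), 9.0, tolerance = 0.01)
})
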