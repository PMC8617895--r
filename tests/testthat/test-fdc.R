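# Force-distance-curve processing: median filter, folded baseline,
# state classification and first-transition extraction.

make_line_trace <- function(n = 2000, k = 0.05, noise = 0, seed = 1,
                            direction = "unfold") {
  set.seed(seed)
  tt <- seq(0, by = 1e-3, length.out = n)
  lambda <- 20 + 580 * tt / max(tt)
  force <- k * lambda + rnorm(n, 0, noise)
  pulling_trace(tt, lambda, force, direction)
}

test_that("median filter: identity, spike removal, idempotence on ramps", {
  tr <- make_line_trace(500)
  expect_identical(median_filter(tr, 1L), tr)
  const <- pulling_trace(1:100 / 100, rep(1, 100), rep(5, 100), "unfold")
  expect_equal(median_filter(const, 5L)$force, rep(5, 100))
  spiked <- const
  spiked$force[50] <- 10
  expect_equal(median_filter(spiked, 5L)$force, rep(5, 100))
  # idempotent on monotone segments
  ramp <- make_line_trace(300)
  expect_equal(median_filter(ramp, 11L)$force, ramp$force)
  expect_error(median_filter(tr, 4L), "odd")
})

test_that("folded baseline recovers the effective stiffness", {
  tr <- make_line_trace(1000, k = 0.05)
  bl <- fit_folded_baseline(tr)
  expect_equal(bl$k_eff, 0.05, tolerance = 1e-12)
  expect_equal(bl$sigma, 0, tolerance = 1e-12)
  tr2 <- make_line_trace(1000, k = 0.05, noise = 0.2, seed = 42)
  bl2 <- fit_folded_baseline(tr2, region = range(tr2$lambda))
  expect_lt(abs(bl2$k_eff / 0.05 - 1), 0.01)
  expect_lt(abs(bl2$sigma / 0.2 - 1), 0.15)
  expect_error(fit_folded_baseline(tr, region = c(-10, -5)), "too few")
})

test_that("noiseless two-branch traces are classified exactly", {
  cfg <- study_cfg()
  cfg$noise_sigma <- 0
  set.seed(5)
  g <- generate_fdc_trace(cfg, "unfold")
  bl <- fit_folded_baseline(g$trace)
  labels <- classify_states(g$trace, bl, elastic = cfg$elastic, ctx = cfg$ctx)
  truth <- rep("U", length(g$trace$force))
  truth[seq_len(g$truth$true_index)] <- "N"
  expect_identical(labels$state, truth)
  expect_equal(nrow(labels$transitions), 1L)
  expect_true(all(labels$posterior_N %in% c(0, 1)))
})

test_that("an all-folded trace yields no unfolded labels or transitions", {
  tr <- make_line_trace(1200, noise = 0.1, seed = 3)
  trf <- median_filter(tr, 11L)
  bl <- fit_folded_baseline(trf, region = range(trf$lambda))
  labels <- classify_states(trf, bl, elastic = barnase_elastic)
  expect_true(all(labels$state == "N"))
  expect_equal(nrow(labels$transitions), 0L)
  ft <- first_transition_force(labels, trf)
  expect_true(is.na(ft$force_pN))
  expect_false(ft$censored)
})

test_that("zero noise with off-model residuals is flagged as degenerate", {
  tr <- make_line_trace(600)
  bl <- fit_folded_baseline(tr)
  bl$sigma <- 0                        # exactly noiseless model
  tr$force <- tr$force - 0.1           # residuals at neither component mean
  expect_error(classify_states(tr, bl, expected_jump = 0.5), "degenerate")
})

test_that("classification is invariant to a lambda offset with intercept fit", {
  cfg <- study_cfg()
  set.seed(8)
  g <- generate_fdc_trace(cfg, "unfold")
  trf <- median_filter(g$trace, 11L)
  bl <- fit_folded_baseline(trf, intercept = TRUE)
  lab1 <- classify_states(trf, bl, elastic = cfg$elastic, ctx = cfg$ctx)
  shifted <- trf
  shifted$lambda <- shifted$lambda + 123.4
  bl2 <- fit_folded_baseline(shifted, intercept = TRUE)
  lab2 <- classify_states(shifted, bl2, elastic = cfg$elastic, ctx = cfg$ctx)
  expect_identical(lab1$state, lab2$state)
})

test_that("embedded transitions are recovered at the right force", {
  cfg <- study_cfg()
  set.seed(17)
  for (i in 1:5) {
    gu <- generate_fdc_trace(cfg, "unfold")
    bl <- fit_folded_baseline(median_filter(gu$trace, 11L))
    ft <- detect_event(gu, cfg, bl)
    expect_lt(abs(ft$force_pN - gu$truth$true_force), 0.2)
    gf <- generate_fdc_trace(cfg, "fold")
    ftf <- detect_event(gf, cfg, bl)
    expect_lt(abs(ftf$force_pN - gf$truth$true_force), 0.2)
  }
})

test_that("folding events below the cutoff are censored, not dropped", {
  cfg <- study_cfg()
  cfg$noise_sigma <- 0.05
  set.seed(23)
  g <- generate_fdc_trace(cfg, "fold", rupture_force = 1.4)
  bl <- structure(list(k_eff = cfg$k_eff, intercept = 0, sigma = 0.04,
                       n = 1000, region = NULL), class = "folded_baseline")
  ft <- detect_event(g, cfg, bl)
  expect_true(ft$censored)
  expect_lt(ft$force_pN, 2)
})
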