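# Bell-Evans rate laws, log-linear fitting, coexistence force and the
# moving-transition-state folding prediction.

be_demo <- be_params(x_dagger = 3, x_star = 8,
                     log_k0_unfold = -13.8, log_k0_fold = 10.2)

test_that("rate laws have the defining log-slopes and limits", {
  beta <- default_ctx$beta
  f <- seq(0, 30, by = 2.5)
  lku <- log(unfold_rate(f, be_demo))
  lkf <- log(fold_rate(f, be_demo))
  expect_equal(diff(lku) / diff(f), rep(beta * 3, length(f) - 1))
  expect_equal(diff(lkf) / diff(f), rep(-beta * 8, length(f) - 1))
  expect_equal(fold_rate(0, be_demo), exp(10.2))
  # symmetric zero-force case: equal prefactors -> equal rates at f = 0
  sym <- be_params(3, 8, -2, -2)
  expect_equal(unfold_rate(0, sym), fold_rate(0, sym))
  # log-space evaluation never overflows on the working force range
  expect_true(all(is.finite(unfold_rate(seq(0, 50, 0.5), be_demo))))
  expect_true(all(is.finite(log(fold_rate(seq(0, 50, 0.5), be_demo)))))
})

test_that("closed-form coexistence force equals the numeric root", {
  sets <- list(be_demo,
               be_params(1.2, 4.5, -5, 3),
               be_params(0.5, 0.7, -1, 2),
               be_params(10, 2, -20, 4))
  for (p in sets) {
    fc <- coexistence_force(p)
    expect_equal(unfold_rate(fc, p), fold_rate(fc, p),
                 tolerance = 1e-9)
    root <- uniroot(function(f) {
      (p$log_k0_unfold + default_ctx$beta * f * p$x_dagger) -
        (p$log_k0_fold - default_ctx$beta * f * p$x_star)
    }, c(-100, 100), tol = 1e-12)$root
    expect_equal(fc, root, tolerance = 1e-9)
  }
  expect_equal(coexistence_force(be_params(3, 8, -2, -2)), 0)
  expect_error(be_params(0, 8, 1, 1), "positive")
})

test_that("fit_be recovers exact model-generated rates and validates input", {
  truth <- be_params(2.7, 7.5, -12.4, 9.1)
  fu <- seq(15, 24, by = 1)
  ff <- seq(2, 6.5, by = 0.5)
  ru <- data.frame(force_pN = fu, rate_per_s = unfold_rate(fu, truth))
  rf <- data.frame(force_pN = ff, rate_per_s = fold_rate(ff, truth))
  # summary.lm warns about the (deliberately) perfect fit
  fit <- suppressWarnings(fit_be(ru, rf))
  expect_equal(fit$params$x_dagger, 2.7, tolerance = 1e-10)
  expect_equal(fit$params$x_star, 7.5, tolerance = 1e-10)
  expect_equal(fit$params$log_k0_unfold, -12.4, tolerance = 1e-8)
  expect_equal(fit$params$log_k0_fold, 9.1, tolerance = 1e-8)
  expect_equal(fit$coexistence_force, coexistence_force(truth),
               tolerance = 1e-8)
  expect_equal(fit$x_m_exp, fit$params$x_dagger + fit$params$x_star)
  expect_error(fit_be(ru[1, , drop = FALSE], rf), "insufficient")
  bad <- ru; bad$rate_per_s[2] <- -1
  expect_error(fit_be(bad, rf), "positive")
})

test_that("fit_be parameter recovery from simulated ruptures", {
  cfg <- study_cfg()
  set.seed(202)
  su <- sample_rupture_forces(cfg, "unfold", 2000)
  sf <- sample_rupture_forces(cfg, "fold", 2000)
  fit <- fit_be(extract_rates(su, n_boot = 100, seed = 1),
                extract_rates(sf, n_boot = 100, seed = 2))
  expect_lt(abs(fit$params$x_dagger / cfg$be$x_dagger - 1), 0.1)
  expect_lt(abs(fit$params$x_star / cfg$be$x_star - 1), 0.1)
})

test_that("moving-TS fold prediction reduces to fixed-TS and is concave", {
  cfg <- study_cfg()
  grid <- seq(2, 25, by = 0.25)
  # constant x*: identical to the Bell-Evans folding branch
  const_profile <- data.frame(force_pN = grid, x_star_nm = 8)
  anchor_f <- 4
  anchor_k <- fold_rate(anchor_f, cfg$be)
  pred <- predicted_fold_rate_moving_ts(grid, const_profile, anchor_f, anchor_k)
  expect_equal(pred$rate_per_s, fold_rate(grid, cfg$be), tolerance = 1e-10)
  # anchor is reproduced exactly
  expect_equal(pred$rate_per_s[pred$force_pN == anchor_f], anchor_k)
  # increasing x*(f) makes ln k concave in f
  prof <- ts_profile(3, barnase_elastic, f_grid = grid)
  pred2 <- predicted_fold_rate_moving_ts(grid, prof, anchor_f, anchor_k)
  d2 <- diff(diff(log(pred2$rate_per_s)))
  expect_true(all(d2 < 0))
  # direct-substitution variant also anchors correctly
  pred3 <- predicted_fold_rate_moving_ts(grid, prof, anchor_f, anchor_k,
                                         method = "direct")
  expect_equal(pred3$rate_per_s[pred3$force_pN == anchor_f], anchor_k,
               tolerance = 1e-12)
  expect_error(predicted_fold_rate_moving_ts(grid, prof, 30, anchor_k),
               "outside")
})

test_that("per-molecule fits average with standard statistical error", {
  truth <- be_params(3, 8, -13, 10)
  mk <- function(eps) {
    fu <- seq(15, 24, by = 1); ff <- seq(2.5, 6.5, by = 0.5)
    suppressWarnings(fit_be(
      data.frame(force_pN = fu,
                 rate_per_s = unfold_rate(fu, truth) * exp(eps * fu / 20)),
      data.frame(force_pN = ff, rate_per_s = fold_rate(ff, truth))))
  }
  fits <- lapply(c(-0.02, 0, 0.02), mk)
  avg <- average_be_fits(fits)
  expect_equal(avg$estimate[avg$parameter == "x_dagger"], 3, tolerance = 0.05)
  expect_true(all(is.finite(avg$se)))
  expect_equal(avg$n_molecules, rep(3L, 4))
})
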