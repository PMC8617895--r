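# Bell-Evans force-dependent kinetics: rate laws, log-linear fitting of
# extracted rate curves, the coexistence force, and the moving-transition-state
# prediction of the folding branch.

#' Bell-Evans kinetic parameters
#'
#' In the Bell-Evans picture the barrier at the transition state (TS) sits at
#' fixed distances \code{x_dagger} from the native state N and \code{x_star}
#' from the unfolded state U, and force tilts the landscape linearly:
#' \deqn{k_\rightarrow(f) = k_0^\rightarrow e^{\beta f x^\dagger}, \qquad
#'       k_\leftarrow(f) = k_0^\leftarrow e^{-\beta f x^*}.}
#' The attempt rate and the barrier heights enter only through the two
#' zero-force log-prefactors \code{log_k0_unfold} (\eqn{\ln k_a - \beta
#' \Delta G^\dagger}) and \code{log_k0_fold} (\eqn{\ln k_a - \beta(\Delta G^* -
#' \Delta G_0)}); they are not separately identifiable from rate-vs-force data
#' and the package stores only the identifiable combinations.
#'
#' @param x_dagger Distance from TS to N (nm), > 0.
#' @param x_star Distance from TS to U (nm), > 0.
#' @param log_k0_unfold Natural log of the zero-force unfolding rate (ln 1/s).
#' @param log_k0_fold Natural log of the zero-force folding rate (ln 1/s).
#' @return An object of class \code{"be_params"}.
#' @export
be_params <- function(x_dagger, x_star, log_k0_unfold, log_k0_fold) {
  chk <- function(x, nm, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (positive && x <= 0)) {
      stop(sprintf("`%s` must be a single finite%s number", nm,
                   if (positive) " positive" else ""), call. = FALSE)
    }
    x
  }
  structure(
    list(
      x_dagger = chk(x_dagger, "x_dagger", positive = TRUE),
      x_star = chk(x_star, "x_star", positive = TRUE),
      log_k0_unfold = chk(log_k0_unfold, "log_k0_unfold"),
      log_k0_fold = chk(log_k0_fold, "log_k0_fold")
    ),
    class = "be_params"
  )
}

#' @export
print.be_params <- function(x, ...) {
  cat(sprintf(
    "Bell-Evans parameters: x_dagger = %.3g nm, x_star = %.3g nm, ln k0 = %.3g (unfold) / %.3g (fold)\n",
    x$x_dagger, x$x_star, x$log_k0_unfold, x$log_k0_fold))
  invisible(x)
}

#' Bell-Evans unfolding rate
#'
#' \eqn{k_\rightarrow(f) = \exp(\log k_0^\rightarrow + \beta f x^\dagger)};
#' strictly increasing in force. Evaluated in log space so large exponents
#' never overflow intermediates.
#'
#' @param f Force(s) in pN.
#' @param params A [be_params()] object.
#' @param ctx A [thermal_context()].
#' @return Rate(s) in 1/s.
#' @export
unfold_rate <- function(f, params, ctx = thermal_context()) {
  stopifnot(inherits(params, "be_params"))
  exp(params$log_k0_unfold + ctx$beta * f * params$x_dagger)
}

#' Bell-Evans folding rate
#'
#' \eqn{k_\leftarrow(f) = \exp(\log k_0^\leftarrow - \beta f x^*)};
#' strictly decreasing in force.
#'
#' @inheritParams unfold_rate
#' @return Rate(s) in 1/s.
#' @export
fold_rate <- function(f, params, ctx = thermal_context()) {
  stopifnot(inherits(params, "be_params"))
  exp(params$log_k0_fold - ctx$beta * f * params$x_star)
}

#' Coexistence force of a Bell-Evans parameter set
#'
#' The force at which unfolding and folding rates are equal,
#' \eqn{k_\rightarrow(f_c) = k_\leftarrow(f_c)}, in closed form:
#' \deqn{f_c = \frac{\log k_0^\leftarrow - \log k_0^\rightarrow}
#'                  {\beta (x^\dagger + x^*)}.}
#'
#' @inheritParams unfold_rate
#' @return The coexistence force fc in pN.
#' @export
coexistence_force <- function(params, ctx = thermal_context()) {
  stopifnot(inherits(params, "be_params"))
  denom <- ctx$beta * (params$x_dagger + params$x_star)
  if (denom <= 0) {
    stop("degenerate model: x_dagger + x_star must be positive", call. = FALSE)
  }
  (params$log_k0_fold - params$log_k0_unfold) / denom
}

branch_fit <- function(tab, branch) {
  if (!is.data.frame(tab) || !all(c("force_pN", "rate_per_s") %in% names(tab))) {
    stop(sprintf("%s rates must be a data frame with columns force_pN and rate_per_s",
                 branch), call. = FALSE)
  }
  ok <- is.finite(tab$force_pN) & is.finite(tab$rate_per_s)
  tab <- tab[ok, , drop = FALSE]
  if (any(tab$rate_per_s <= 0)) {
    stop(sprintf("%s rates must be strictly positive", branch), call. = FALSE)
  }
  if (nrow(tab) < 2L) {
    stop(sprintf("insufficient data: need at least 2 finite %s rate points",
                 branch), call. = FALSE)
  }
  d <- data.frame(lk = log(tab$rate_per_s), f = tab$force_pN)
  w <- NULL
  if ("se_log_rate" %in% names(tab)) {
    se <- tab$se_log_rate
    if (all(is.finite(se)) && all(se > 0)) w <- 1 / se^2
  }
  fit <- if (is.null(w)) stats::lm(lk ~ f, data = d) else {
    d$w <- w
    stats::lm(lk ~ f, data = d, weights = w)
  }
  cf <- summary(fit)$coefficients
  list(intercept = cf[1, 1], intercept_se = cf[1, 2],
       slope = cf[2, 1], slope_se = cf[2, 2],
       rss = sum(stats::residuals(fit)^2), n = nrow(d), weighted = !is.null(w))
}

#' Fit the Bell-Evans model to extracted rate curves
#'
#' Fits straight lines to \eqn{\ln k} versus force separately on the
#' unfolding and folding branches (weighted least squares with weights
#' \eqn{1/\mathrm{se}^2} when a finite positive \code{se_log_rate} column is
#' present, ordinary least squares otherwise). The slopes give
#' \eqn{\beta x^\dagger} and \eqn{-\beta x^*}; the intercepts give the
#' zero-force log-prefactors; the coexistence force follows in closed form.
#'
#' @param unfold,fold Data frames with columns \code{force_pN},
#'   \code{rate_per_s} and optionally \code{se_log_rate}, as produced by
#'   [extract_rates()].
#' @param ctx A [thermal_context()].
#' @return An object of class \code{"be_fit"}: a list with \code{params}
#'   (a [be_params()]), \code{se} (standard errors of the four parameters),
#'   \code{coexistence_force} (pN), \code{x_m_exp} (\eqn{x^\dagger + x^*},
#'   nm) and per-branch \code{diagnostics} (residual sum of squares, points
#'   used, whether weights were applied).
#' @export
fit_be <- function(unfold, fold, ctx = thermal_context()) {
  bu <- branch_fit(unfold, "unfold")
  bf <- branch_fit(fold, "fold")
  x_dagger <- bu$slope / ctx$beta
  x_star <- -bf$slope / ctx$beta
  if (x_dagger <= 0 || x_star <= 0) {
    stop("fitted slopes have the wrong sign: unfolding rates must increase and folding rates decrease with force",
         call. = FALSE)
  }
  params <- be_params(x_dagger, x_star, bu$intercept, bf$intercept)
  structure(
    list(
      params = params,
      se = list(x_dagger = bu$slope_se / ctx$beta,
                x_star = bf$slope_se / ctx$beta,
                log_k0_unfold = bu$intercept_se,
                log_k0_fold = bf$intercept_se),
      coexistence_force = coexistence_force(params, ctx),
      x_m_exp = x_dagger + x_star,
      diagnostics = list(unfold = bu, fold = bf),
      ctx = ctx
    ),
    class = "be_fit"
  )
}

#' @export
print.be_fit <- function(x, ...) {
  cat("Bell-Evans fit\n")
  cat(sprintf("  x_dagger (TS-N distance): %.2f +/- %.2f nm\n",
              x$params$x_dagger, x$se$x_dagger))
  cat(sprintf("  x_star   (TS-U distance): %.2f +/- %.2f nm\n",
              x$params$x_star, x$se$x_star))
  cat(sprintf("  x_m_exp = x_dagger + x_star: %.2f nm\n", x$x_m_exp))
  cat(sprintf("  coexistence force fc: %.2f pN\n", x$coexistence_force))
  cat(sprintf("  points used: %d (unfold), %d (fold)\n",
              x$diagnostics$unfold$n, x$diagnostics$fold$n))
  invisible(x)
}

#' Average Bell-Evans fits across molecules
#'
#' Combines per-molecule fits into a single estimate per parameter, with the
#' standard statistical error across molecules (sd / sqrt(n)).
#'
#' @param fits A list of [fit_be()] results.
#' @return A data frame with one row per parameter (\code{x_dagger},
#'   \code{x_star}, \code{coexistence_force}, \code{x_m_exp}) and columns
#'   \code{estimate}, \code{se}, \code{n_molecules}.
#' @export
average_be_fits <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "be_fit")))
  pull <- function(fun) vapply(fits, fun, numeric(1))
  vals <- list(
    x_dagger = pull(function(f) f$params$x_dagger),
    x_star = pull(function(f) f$params$x_star),
    coexistence_force = pull(function(f) f$coexistence_force),
    x_m_exp = pull(function(f) f$x_m_exp)
  )
  n <- length(fits)
  data.frame(
    parameter = names(vals),
    estimate = vapply(vals, mean, numeric(1)),
    se = vapply(vals, function(v) if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
                numeric(1)),
    n_molecules = n,
    row.names = NULL
  )
}

#' Folding-rate prediction with a force-dependent transition state
#'
#' When the TS-to-U distance varies with force, the Bell-Evans folding branch
#' generalizes to
#' \deqn{\ln k_\leftarrow(f) = \ln k_\leftarrow(f_a) -
#'       \beta \int_{f_a}^{f} x^*(f')\,df'}
#' anchored at a force \eqn{f_a} where the rate is known. The integral form is
#' thermodynamically consistent (the local log-slope is always
#' \eqn{-\beta x^*(f)}) and reduces exactly to the fixed-TS law when
#' \eqn{x^*} is constant. The alternative \code{method = "direct"} substitutes
#' \eqn{x^*(f)} into the fixed-TS expression,
#' \eqn{\ln k_\leftarrow(f) = \ln k_\leftarrow(f_a) - \beta (f x^*(f) -
#' f_a x^*(f_a))}.
#'
#' With \eqn{x^*(f)} increasing in force - the Leffler-Hammond direction -
#' both forms give a concave \eqn{\ln k_\leftarrow} versus force, i.e. a
#' curvature in the log-rate plot instead of a straight line.
#'
#' @param f_grid Forces (pN) at which to evaluate the prediction; must lie
#'   within the force range of \code{profile}.
#' @param profile A [ts_profile()] data frame providing \code{x_star_nm}
#'   versus \code{force_pN}.
#' @param anchor_force Force (pN) at which the folding rate is pinned; must
#'   lie within the profile grid.
#' @param anchor_rate Folding rate (1/s) at \code{anchor_force}.
#' @param ctx A [thermal_context()].
#' @param method \code{"integral"} (default) or \code{"direct"}; see Details.
#' @return A data frame with columns \code{force_pN}, \code{rate_per_s} and
#'   \code{direction = "fold"}.
#' @export
predicted_fold_rate_moving_ts <- function(f_grid, profile, anchor_force,
                                          anchor_rate,
                                          ctx = thermal_context(),
                                          method = c("integral", "direct")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(profile),
            all(c("force_pN", "x_star_nm") %in% names(profile)))
  rng <- range(profile$force_pN)
  if (anchor_force < rng[1] || anchor_force > rng[2]) {
    stop(sprintf("anchor force %.3g pN lies outside the profile grid [%.3g, %.3g]",
                 anchor_force, rng[1], rng[2]), call. = FALSE)
  }
  if (any(f_grid < rng[1]) || any(f_grid > rng[2])) {
    stop("all forces in `f_grid` must lie within the profile grid", call. = FALSE)
  }
  if (!is.finite(anchor_rate) || anchor_rate <= 0) {
    stop("`anchor_rate` must be a positive rate", call. = FALSE)
  }
  xs_of <- function(f) {
    stats::approx(profile$force_pN, profile$x_star_nm, xout = f)$y
  }
  if (method == "direct") {
    lnk <- log(anchor_rate) -
      ctx$beta * (f_grid * xs_of(f_grid) - anchor_force * xs_of(anchor_force))
  } else {
    g <- sort(unique(c(anchor_force, f_grid, profile$force_pN[
      profile$force_pN >= min(c(f_grid, anchor_force)) &
        profile$force_pN <= max(c(f_grid, anchor_force))])))
    xs <- xs_of(g)
    cum <- c(0, cumsum(diff(g) * (utils::head(xs, -1) + utils::tail(xs, -1)) / 2))
    at <- function(f) cum[match(f, g)]
    lnk <- log(anchor_rate) - ctx$beta * (at(f_grid) - at(anchor_force))
  }
  data.frame(force_pN = f_grid, rate_per_s = exp(lnk), direction = "fold")
}
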