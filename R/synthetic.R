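# Synthetic two-state pulling and hopping data: closed-form rupture-force
# sampling under a force ramp, full noisy force-distance traces with embedded
# ground truth, and telegraph hopping traces.

#' Configuration of a simulated pulling experiment
#'
#' Collects the kinetic, elastic and instrumental parameters of a simulated
#' constant-loading-rate pulling experiment. Defaults mirror a typical
#' optical-tweezers protein experiment: a 6 pN/s ramp between ~1 pN and
#' ~30 pN recorded at 1 kHz, an effective trap-plus-construct stiffness of
#' 0.05 pN/nm, and 0.2 pN Gaussian force noise per sample.
#'
#' @param be A [be_params()] set generating the rupture kinetics.
#' @param elastic An [elastic_params()] set for the released chain.
#' @param ctx A [thermal_context()].
#' @param loading_rate Ramp rate r in pN/s (default 6).
#' @param f_start,f_end Ramp force window in pN (defaults 1 and 30).
#' @param k_eff Effective stiffness of trap plus construct (pN/nm).
#' @param noise_sigma Gaussian force noise per sample (pN).
#' @param sampling_rate Acquisition rate (Hz).
#' @param n_cycles Number of pull-relax cycles to simulate.
#' @param seed Root seed; mandatory so every simulated data set is
#'   reproducible.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(be, elastic, ctx = thermal_context(),
                              loading_rate = 6, f_start = 1, f_end = 30,
                              k_eff = 0.05, noise_sigma = 0.2,
                              sampling_rate = 1000, n_cycles = 100L, seed) {
  stopifnot(inherits(be, "be_params"), inherits(elastic, "elastic_params"),
            inherits(ctx, "thermal_context"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("`seed` is mandatory and must be a single number", call. = FALSE)
  }
  if (loading_rate <= 0) stop("`loading_rate` must be positive", call. = FALSE)
  if (f_start >= f_end) stop("`f_start` must be below `f_end`", call. = FALSE)
  if (f_start <= 0) stop("`f_start` must be positive", call. = FALSE)
  if (k_eff <= 0) stop("`k_eff` must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative", call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  if (n_cycles < 1L) stop("`n_cycles` must be at least 1", call. = FALSE)
  structure(
    list(be = be, elastic = elastic, ctx = ctx, loading_rate = loading_rate,
         f_start = f_start, f_end = f_end, k_eff = k_eff,
         noise_sigma = noise_sigma, sampling_rate = sampling_rate,
         n_cycles = as.integer(n_cycles), seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Inverse-CDF transform for rupture forces under a force ramp
#'
#' For a Bell-Evans hazard under a deterministic ramp at rate r the survival
#' of the initial state has a closed form, e.g. for unfolding from the ramp
#' start \eqn{f_0}:
#' \deqn{S(f) = \exp\left[-\frac{k_0^\rightarrow}{r\beta x^\dagger}
#'   \left(e^{\beta f x^\dagger} - e^{\beta f_0 x^\dagger}\right)\right],}
#' which inverts analytically. This function maps uniform deviates
#' \code{u = S(f)} to rupture forces, so \code{u = 1} returns the ramp start
#' (immediate rupture boundary). Sampling in the force domain avoids any
#' time-stepping error. The returned forces are not clipped to the ramp
#' window; [sample_rupture_forces()] applies the clipping.
#'
#' @param u Uniform deviates in (0, 1\].
#' @param be A [be_params()] set.
#' @param direction \code{"unfold"} (ramp up from \code{f_start}) or
#'   \code{"fold"} (ramp down from \code{f_end}).
#' @param f_start,f_end Ramp force window (pN).
#' @param loading_rate Ramp rate r (pN/s).
#' @param ctx A [thermal_context()].
#' @return Rupture forces in pN (unclipped).
#' @export
rupture_quantile <- function(u, be, direction = c("unfold", "fold"),
                             f_start = 1, f_end = 30, loading_rate = 6,
                             ctx = thermal_context()) {
  direction <- match.arg(direction)
  stopifnot(inherits(be, "be_params"))
  if (any(u <= 0) || any(u > 1)) stop("`u` must lie in (0, 1]", call. = FALSE)
  beta <- ctx$beta
  if (direction == "unfold") {
    bx <- beta * be$x_dagger
    k0 <- exp(be$log_k0_unfold)
    log(exp(bx * f_start) - (loading_rate * bx / k0) * log(u)) / bx
  } else {
    bx <- beta * be$x_star
    k0 <- exp(be$log_k0_fold)
    -log(exp(-bx * f_end) - (loading_rate * bx / k0) * log(u)) / bx
  }
}

#' Sample first-rupture forces of a simulated ramp
#'
#' Draws \code{n} rupture forces by the inverse-CDF transform of
#' [rupture_quantile()]. Events falling outside the ramp window (molecules
#' that would rupture beyond \code{f_end}, or fold below \code{f_start})
#' are clipped to the window boundary and their count reported in the
#' \code{"n_clipped"} attribute of the result.
#'
#' @param cfg A [simulation_config()].
#' @param direction \code{"unfold"} or \code{"fold"}.
#' @param n Number of events to draw.
#' @param seed Optional seed; when \code{NULL} the current RNG stream is
#'   used (callers that orchestrate several draws seed once upstream).
#' @return A [rupture_sample()] with attribute \code{"n_clipped"}.
#' @export
sample_rupture_forces <- function(cfg, direction = c("unfold", "fold"), n,
                                  seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  direction <- match.arg(direction)
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  f <- rupture_quantile(u, cfg$be, direction, cfg$f_start, cfg$f_end,
                        cfg$loading_rate, cfg$ctx)
  clipped <- f < cfg$f_start | f > cfg$f_end
  f <- pmin(pmax(f, cfg$f_start), cfg$f_end)
  out <- rupture_sample(f, direction, cfg$loading_rate,
                        window = c(cfg$f_start, cfg$f_end),
                        molecule_id = "simulated")
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Generate one noisy force-distance trace with ground truth
#'
#' Builds a full pulling (or relaxing) cycle: the trap position is ramped so
#' that the folded-branch force \eqn{f_N = k_{eff}\lambda} changes at the
#' loading rate; the unfolded branch sits below it by the first-order force
#' jump \eqn{k_{eff}\, x_{m,th}(f_N)} (released extension at the local
#' baseline force); the molecule switches branch at a rupture force drawn
#' from the closed-form sampler; Gaussian noise is added per sample. The
#' ground-truth record stores the noiseless pre-transition force and the
#' last pre-transition sample index.
#'
#' The first-order jump approximation sidesteps a self-consistent
#' trap-plus-WLC force balance; it is accurate enough to exercise event
#' detection, which is its purpose.
#'
#' @param cfg A [simulation_config()].
#' @param direction \code{"unfold"} or \code{"fold"}.
#' @param cycle_id Cycle identifier stored in the trace.
#' @param rupture_force Optional fixed rupture force (pN); when \code{NULL}
#'   one is drawn from the current RNG stream.
#' @return A list with \code{trace} (a [pulling_trace()]) and \code{truth}
#'   (cycle id, direction, true force, true index, the sampled rupture
#'   force, and whether a transition occurs inside the window).
#' @export
generate_fdc_trace <- function(cfg, direction = c("unfold", "fold"),
                               cycle_id = 1L, rupture_force = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  direction <- match.arg(direction)
  dt <- 1 / cfg$sampling_rate
  tt <- seq(0, (cfg$f_end - cfg$f_start) / cfg$loading_rate, by = dt)
  f_N <- if (direction == "unfold") {
    cfg$f_start + cfg$loading_rate * tt
  } else {
    cfg$f_end - cfg$loading_rate * tt
  }
  lambda <- f_N / cfg$k_eff
  jump <- cfg$k_eff * released_extension(f_N, cfg$elastic, cfg$ctx)
  f_U <- f_N - jump
  if (is.null(rupture_force)) {
    rupture_force <- rupture_quantile(stats::runif(1), cfg$be, direction,
                                      cfg$f_start, cfg$f_end,
                                      cfg$loading_rate, cfg$ctx)
  }
  if (direction == "unfold") {
    idx <- which(f_N >= rupture_force)[1]
    pre <- f_N
    post <- f_U
  } else {
    idx <- which(f_U <= rupture_force)[1]
    pre <- f_U
    post <- f_N
  }
  has_event <- !is.na(idx) && idx > 1L
  force <- pre
  true_index <- NA_integer_
  true_force <- NA_real_
  if (has_event) {
    force[idx:length(force)] <- post[idx:length(force)]
    true_index <- idx - 1L
    true_force <- pre[true_index]
  }
  if (cfg$noise_sigma > 0) {
    force <- force + stats::rnorm(length(force), 0, cfg$noise_sigma)
  }
  trace <- pulling_trace(tt, lambda, force, direction,
                         loading_rate = cfg$loading_rate,
                         sampling_rate = cfg$sampling_rate,
                         molecule_id = "simulated", cycle_id = cycle_id)
  truth <- list(cycle_id = cycle_id, direction = direction,
                true_force = true_force, true_index = true_index,
                sampled_force = rupture_force, has_event = has_event)
  list(trace = trace, truth = truth)
}

#' Generate a two-state telegraph hopping trace
#'
#' Simulates an equilibrium hopping recording at a clamped trap position:
#' the molecule alternates between N and U with exponential dwell times of
#' hazards \code{unfold_rate(f_level)} and \code{fold_rate(f_level)}, the
#' force takes one of two levels separated by \code{force_jump}, and
#' Gaussian noise is added per sample.
#'
#' @param be A [be_params()] set.
#' @param f_level Clamped force level of the N branch (pN).
#' @param duration Trace duration (s).
#' @param sampling_rate Acquisition rate (Hz).
#' @param noise_sigma Gaussian force noise (pN).
#' @param force_jump Force separation between N and U levels (pN); U sits
#'   below N.
#' @param ctx A [thermal_context()].
#' @param seed Optional seed.
#' @return A list with \code{time}, \code{force} and the true per-sample
#'   \code{state} ("N"/"U").
#' @export
generate_hopping_trace <- function(be, f_level, duration,
                                   sampling_rate = 1000, noise_sigma = 0.2,
                                   force_jump = 1, ctx = thermal_context(),
                                   seed = NULL) {
  stopifnot(inherits(be, "be_params"))
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ku <- unfold_rate(f_level, be, ctx)
  kf <- fold_rate(f_level, be, ctx)
  dwells <- numeric(0)
  states <- character(0)
  total <- 0
  state <- "N"
  while (total <= duration) {
    block <- 256L
    for (i in seq_len(block)) {
      d <- stats::rexp(1, rate = if (state == "N") ku else kf)
      dwells <- c(dwells, d)
      states <- c(states, state)
      total <- total + d
      state <- if (state == "N") "U" else "N"
      if (total > duration) break
    }
  }
  tt <- seq(0, duration, by = 1 / sampling_rate)
  dwell_idx <- findInterval(tt, cumsum(dwells)) + 1L
  dwell_idx[dwell_idx > length(states)] <- length(states)
  lab <- states[dwell_idx]
  force <- ifelse(lab == "N", f_level, f_level - force_jump)
  if (noise_sigma > 0) force <- force + stats::rnorm(length(force), 0, noise_sigma)
  list(time = tt, force = force, state = lab)
}

#' Label a hopping trace by thresholding the filtered force
#'
#' Median-filters the force, splits it into two clusters (2-means on the
#' filtered values), labels the high-force cluster N and the low-force
#' cluster U, and debounces short runs.
#'
#' Defaults are deliberately lighter than for pulling-trace classification:
#' hopping levels are separated by many noise standard deviations, so
#' misclassification is negligible even with a short filter, while every
#' extra sample of filtering or debounce erases genuine short dwells and
#' biases the mean dwell time upward (missed-event bias).
#'
#' @param force Force samples (pN).
#' @param median_window Median filter window (odd samples).
#' @param debounce Minimum run length in samples.
#' @return Character vector of "N"/"U" labels per sample.
#' @export
label_hopping_trace <- function(force, median_window = 5L, debounce = 5L) {
  if (median_window > 1L) {
    force <- as.numeric(stats::runmed(force, median_window, endrule = "median"))
  }
  km <- stats::kmeans(force, centers = 2L, nstart = 2L)
  high <- which.max(km$centers)
  lab <- ifelse(km$cluster == high, "N", "U")
  debounce_labels(lab, debounce)
}

#' Default study configurations (barnase and DNA hairpin)
#'
#' Returns the simulation configuration used throughout the package for the
#' 110-amino-acid protein barnase (persistence length 0.8 nm, 0.37 nm per
#' amino acid, 3 nm N-C dipole, 6 pN/s ramp), plus a skeleton entry for a
#' 44-nucleotide DNA hairpin whose elastic parameters must be supplied by
#' the user (single-stranded DNA elasticity is construct- and
#' buffer-dependent, so the package ships no numbers for it).
#'
#' The kinetic prefactors of barnase are package choices, not measured
#' values: they are chosen so that the Bell-Evans distances are 3 nm (TS-N)
#' and 8 nm (TS-U) and the most probable rupture forces fall at 21 pN
#' (unfolding) and 4 pN (folding), inside the experimentally reported
#' 16-23 pN and < 5 pN ranges; with these choices the coexistence force is
#' 9.0 pN.
#'
#' @param seed Root seed stored in the barnase configuration.
#' @param warn Emit the configuration warning for the incomplete hairpin
#'   entry (default \code{TRUE}).
#' @return A list with elements \code{barnase} (a [simulation_config()]) and
#'   \code{hairpin} (an incomplete skeleton with \code{n_monomers = 44} and
#'   \code{elastic = NULL}).
#' @export
make_study_defaults <- function(seed = 1L, warn = TRUE) {
  ctx <- thermal_context(298)
  elastic <- elastic_params(persistence_length = 0.8, monomer_length = 0.37,
                           n_monomers = 110, dipole_length = 3)
  r <- 6
  x_dagger <- 3
  x_star <- 8
  f_mode_unfold <- 21
  f_mode_fold <- 4
  # place the density modes: at the mode, hazard = r * beta * x
  log_k0_unfold <- log(r * ctx$beta * x_dagger) - ctx$beta * x_dagger * f_mode_unfold
  log_k0_fold <- log(r * ctx$beta * x_star) + ctx$beta * x_star * f_mode_fold
  be <- be_params(x_dagger, x_star, log_k0_unfold, log_k0_fold)
  barnase <- simulation_config(be, elastic, ctx, loading_rate = r, seed = seed)
  hairpin <- structure(
    list(n_monomers = 44, elastic = NULL, ctx = ctx,
         note = "supply persistence_length, monomer_length and dipole_length for the ssDNA construct"),
    class = "incomplete_config"
  )
  if (warn) {
    warning("hairpin elastic parameters are not set; supply them before simulating the hairpin",
            call. = FALSE)
  }
  list(barnase = barnase, hairpin = hairpin)
}
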