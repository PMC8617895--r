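# Event detection on force-distance curves: median filtering, folded-baseline
# fitting, two-component Gaussian (Bayesian) state classification and
# first-transition force extraction.

#' A single pulling cycle (force-distance curve)
#'
#' One recording of a pulling ramp: per-sample time, trap-pipette distance
#' lambda and force, with the ramp direction and acquisition metadata.
#'
#' @param time Sample times in seconds; strictly increasing.
#' @param lambda Trap-pipette distance in nm.
#' @param force Measured force in pN.
#' @param direction \code{"unfold"} (force increasing) or \code{"fold"}.
#' @param loading_rate Loading rate in pN/s (optional metadata).
#' @param sampling_rate Acquisition rate in Hz (optional metadata).
#' @param molecule_id,cycle_id Optional identifiers.
#' @return An object of class \code{"pulling_trace"}.
#' @export
pulling_trace <- function(time, lambda, force,
                          direction = c("unfold", "fold"),
                          loading_rate = NA_real_, sampling_rate = NA_real_,
                          molecule_id = NA_character_, cycle_id = NA_integer_) {
  direction <- match.arg(direction)
  n <- length(time)
  if (n < 2L || length(lambda) != n || length(force) != n) {
    stop("`time`, `lambda` and `force` must be equal-length vectors (n >= 2)",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), lambda = as.numeric(lambda),
         force = as.numeric(force), direction = direction,
         loading_rate = loading_rate, sampling_rate = sampling_rate,
         molecule_id = molecule_id, cycle_id = cycle_id),
    class = "pulling_trace"
  )
}

#' @export
print.pulling_trace <- function(x, ...) {
  cat(sprintf(
    "Pulling trace (%s): %d samples, %.3g-%.3g s, force %.2f-%.2f pN\n",
    x$direction, length(x$time), min(x$time), max(x$time),
    min(x$force), max(x$force)))
  invisible(x)
}

#' Running-median filter of the force channel
#'
#' Replaces the force channel by a running median of odd window length;
#' the window shrinks symmetrically at the trace ends. A window of 1 is the
#' identity. The default of 11 samples corresponds to ~11 ms at the usual
#' 1 kHz acquisition rate.
#'
#' @param trace A [pulling_trace()].
#' @param window Odd window length in samples.
#' @return The trace with the filtered force channel.
#' @export
median_filter <- function(trace, window = 11L) {
  stopifnot(inherits(trace, "pulling_trace"))
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (window == 1L) return(trace)
  trace$force <- as.numeric(stats::runmed(trace$force, k = window,
                                          endrule = "median"))
  trace
}

#' Fit the folded-branch baseline f(lambda) = k lambda
#'
#' Least-squares fit of the folded branch to a line through the origin (or
#' with a free intercept), giving the effective stiffness of trap plus
#' molecular construct, together with a robust (MAD-based) residual scale
#' used as the noise level in state classification.
#'
#' @param trace A [pulling_trace()] (typically median-filtered).
#' @param region Lambda bounds \code{c(lo, hi)} of the fitting region. The
#'   default takes the lowest 20% of the lambda range, which on an unfolding
#'   trace is far below any rupture.
#' @param intercept Fit a free intercept as well (default \code{FALSE}).
#'   With an intercept the classification becomes invariant to adding a
#'   constant to lambda.
#' @param min_samples Minimum number of samples required in the region.
#' @return An object of class \code{"folded_baseline"}: a list with
#'   \code{k_eff} (pN/nm), \code{intercept} (pN), \code{sigma} (pN, MAD of
#'   residuals), \code{n} and \code{region}.
#' @export
fit_folded_baseline <- function(trace, region = NULL, intercept = FALSE,
                                min_samples = 10L) {
  stopifnot(inherits(trace, "pulling_trace"))
  if (is.null(region)) {
    r <- range(trace$lambda)
    region <- c(r[1], r[1] + 0.2 * diff(r))
  }
  sel <- trace$lambda >= region[1] & trace$lambda <= region[2]
  if (sum(sel) < min_samples) {
    stop(sprintf("too few samples (%d < %d) in the baseline region",
                 sum(sel), min_samples), call. = FALSE)
  }
  d <- data.frame(f = trace$force[sel], l = trace$lambda[sel])
  fit <- if (intercept) stats::lm(f ~ l, data = d) else stats::lm(f ~ 0 + l, data = d)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(
    list(k_eff = unname(if (intercept) cf[2] else cf[1]),
         intercept = unname(if (intercept) cf[1] else 0),
         sigma = stats::mad(res), n = sum(sel), region = region),
    class = "folded_baseline"
  )
}

debounce_labels <- function(lab, m) {
  if (m <= 1L) return(lab)
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < m)
    if (length(short) == 0L) break
    i <- short[1]
    r$values[i] <- if (i == 1L) r$values[i + 1L] else r$values[i - 1L]
    lab <- inverse.rle(r)
  }
  lab
}

#' Classify trace samples into native (N) and unfolded (U)
#'
#' Computes the residual of each sample from the folded baseline,
#' \eqn{\Delta_i = (k_{eff}\lambda_i + b) - f_i}, and scores it under a
#' two-component Gaussian model with equal priors: the N component is
#' centered at 0, the U component at the expected force jump at the local
#' baseline force, both with the baseline noise scale. The per-sample
#' posterior probability of N gives the label (maximum posterior); runs of a
#' new state shorter than \code{debounce} samples are merged back, so a
#' transition must be sustained to count.
#'
#' The default debounce of 51 samples is deliberately several times the
#' default median-filter window: filtered noise is correlated over one
#' window, so excursions shorter than the window are pure noise and a
#' debounce below it would accept them as transitions.
#'
#' @param trace A median-filtered [pulling_trace()].
#' @param baseline A [fit_folded_baseline()] result.
#' @param expected_jump The expected force jump between branches: either a
#'   single number (pN) or a function of the local baseline force returning
#'   pN. When \code{NULL} and \code{elastic} is given, defaults to the
#'   first-order jump \code{k_eff * released_extension(f)}.
#' @param elastic Optional [elastic_params()] used to build the default
#'   \code{expected_jump}.
#' @param ctx A [thermal_context()].
#' @param debounce Minimum run length (samples) for a state change.
#' @return An object of class \code{"state_labels"}: a list with
#'   \code{state} (character vector of "N"/"U"), \code{posterior_N} and a
#'   \code{transitions} data frame (\code{index}, \code{from}, \code{to});
#'   \code{index} is the first sample of the new state.
#' @export
classify_states <- function(trace, baseline, expected_jump = NULL,
                            elastic = NULL, ctx = thermal_context(),
                            debounce = 51L) {
  stopifnot(inherits(trace, "pulling_trace"),
            inherits(baseline, "folded_baseline"))
  f_base <- baseline$intercept + baseline$k_eff * trace$lambda
  if (is.null(expected_jump)) {
    if (is.null(elastic)) {
      stop("supply `expected_jump` or `elastic` to build the default jump model",
           call. = FALSE)
    }
    k_eff <- baseline$k_eff
    expected_jump <- function(f) {
      k_eff * released_extension(pmax(f, 1e-6), elastic, ctx)
    }
  }
  jump <- if (is.function(expected_jump)) expected_jump(f_base) else
    rep(expected_jump, length(f_base))
  if (any(!is.finite(jump)) || any(jump <= 0)) {
    stop("`expected_jump` must evaluate to positive force jumps", call. = FALSE)
  }
  delta <- f_base - trace$force
  sigma <- baseline$sigma
  if (sigma <= 0) {
    tol <- 1e-9 * max(1, max(abs(delta)))
    at_mean <- abs(delta) < tol | abs(delta - jump) < tol
    if (!all(at_mean)) {
      stop("degenerate model: baseline sigma is zero but residuals are not at the component means",
           call. = FALSE)
    }
    post_N <- as.numeric(abs(delta) < abs(delta - jump))
  } else {
    lpN <- stats::dnorm(delta, mean = 0, sd = sigma, log = TRUE)
    lpU <- stats::dnorm(delta, mean = jump, sd = sigma, log = TRUE)
    post_N <- 1 / (1 + exp(lpU - lpN))
  }
  lab <- ifelse(post_N >= 0.5, "N", "U")
  lab <- debounce_labels(lab, debounce)
  n <- length(lab)
  chg <- which(lab[-1] != lab[-n]) + 1L
  transitions <- data.frame(index = chg,
                            from = lab[pmax(chg - 1L, 1L)],
                            to = lab[chg])
  structure(list(state = lab, posterior_N = post_N, transitions = transitions),
            class = "state_labels")
}

#' Force of the first transition along a trace
#'
#' For an unfolding trace the rupture force is the force of the native
#' branch at the first N to U transition; for a folding trace it is the
#' force of the unfolded branch at the first U to N transition. Folding
#' forces below \code{fold_cutoff} are flagged as censored: such events are
#' detectable but not all of them are, so they must not enter force
#' densities. A trace with no matching transition returns \code{NA} with
#' \code{censored = FALSE}.
#'
#' A running median smears the force step over half its window, so samples
#' adjacent to the transition are biased toward the other branch (the
#' median there degenerates into an extreme order statistic of the
#' pre-transition samples). The rupture force is therefore estimated by a
#' short linear fit of the pre-transition branch, excluding the smeared
#' zone, extrapolated to the transition sample; on a noiseless trace this
#' reproduces the branch force exactly.
#'
#' @param labels A [classify_states()] result.
#' @param trace The (median-filtered) trace the labels refer to.
#' @param direction \code{"unfold"} or \code{"fold"}; defaults to the trace
#'   direction.
#' @param fold_cutoff Censoring cutoff for folding forces (pN, default 2).
#' @param smear Samples adjacent to the transition excluded from the branch
#'   fit (default 5, half the default median window).
#' @param fit_len Number of pre-transition samples in the branch fit.
#' @return A list with \code{force_pN} (NA when no transition),
#'   \code{censored} and \code{index} (the first sample of the new state).
#' @export
first_transition_force <- function(labels, trace,
                                   direction = trace$direction,
                                   fold_cutoff = 2,
                                   smear = 5L, fit_len = 40L) {
  stopifnot(inherits(labels, "state_labels"),
            inherits(trace, "pulling_trace"))
  direction <- match.arg(direction, c("unfold", "fold"))
  want_from <- if (direction == "unfold") "N" else "U"
  want_to <- if (direction == "unfold") "U" else "N"
  tr <- labels$transitions
  hit <- which(tr$from == want_from & tr$to == want_to)
  if (length(hit) == 0L) {
    return(list(force_pN = NA_real_, censored = FALSE, index = NA_integer_))
  }
  i <- tr$index[hit[1]]
  j_hi <- i - 1L - smear
  j_lo <- max(1L, j_hi - fit_len + 1L)
  if (j_hi - j_lo >= 1L) {
    d <- data.frame(tt = trace$time[j_lo:j_hi], ff = trace$force[j_lo:j_hi])
    cf <- stats::coef(stats::lm(ff ~ tt, data = d))
    force <- unname(cf[1] + cf[2] * trace$time[max(i - 1L, 1L)])
  } else {
    force <- trace$force[max(i - 1L, 1L)]
  }
  censored <- direction == "fold" && force < fold_cutoff
  list(force_pN = force, censored = censored, index = i)
}
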