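# Polymer elasticity: worm-like-chain interpolation (forward and inverse),
# the freely-jointed-chain dipole of the folded core, and conversions between
# extensions and monomer counts.

#' Worm-like-chain interpolation force at a given relative extension
#'
#' Evaluates the inextensible WLC interpolation formula
#' \deqn{f(z) = \frac{k_B T}{4 L_p}\left[(1-z)^{-2} + 4z - 1\right]}
#' where \eqn{z = X/L} is the extension relative to the contour length.
#'
#' @param z Relative extension(s) in \[0, 1).
#' @param persistence_length Persistence length Lp (nm).
#' @param ctx A [thermal_context()].
#' @return Force(s) in pN.
#' @export
wlc_force <- function(z, persistence_length = 0.8, ctx = thermal_context()) {
  if (any(!is.finite(z)) || any(z < 0) || any(z >= 1)) {
    stop("relative extension `z` must lie in [0, 1)", call. = FALSE)
  }
  (ctx$kBT / (4 * persistence_length)) * ((1 - z)^-2 + 4 * z - 1)
}

#' Invert the WLC interpolation formula for the relative extension
#'
#' Solves \eqn{f = (k_B T / 4 L_p)[(1-z)^{-2} + 4z - 1]} for the relative
#' extension \eqn{z \in (0, 1)} at each force. The right-hand side is strictly
#' increasing in z on (0, 1), so the root is found by bisection on
#' \code{[0, 1 - 1e-12]}, which converges unconditionally; the equivalent
#' cubic has spurious roots outside (0, 1) that are never visited.
#'
#' @param f Force(s) in pN; strictly positive.
#' @param persistence_length Persistence length Lp (nm).
#' @param ctx A [thermal_context()].
#' @param tol Absolute tolerance on z for the bisection (default 1e-12).
#' @param max_iter Maximum bisection iterations.
#' @return Relative extension(s) z in (0, 1), strictly increasing in f.
#'
#' @examples
#' relative_extension(6.43)  # ~0.5 for Lp = 0.8 nm at 298 K
#' @export
relative_extension <- function(f, persistence_length = 0.8,
                               ctx = thermal_context(),
                               tol = 1e-12, max_iter = 200L) {
  if (length(f) == 0L) return(numeric(0))
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("force must be finite and strictly positive", call. = FALSE)
  }
  a <- ctx$kBT / (4 * persistence_length)
  lo <- rep(0, length(f))
  hi <- rep(1 - 1e-12, length(f))
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    below <- a * ((1 - mid)^-2 + 4 * mid - 1) < f
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("WLC inversion did not converge within `max_iter` iterations",
         call. = FALSE)
  }
  (lo + hi) / 2
}

#' Extension of the unfolded chain at a given force (WLC)
#'
#' @param f Force(s) in pN; strictly positive.
#' @param params An [elastic_params()] object.
#' @param ctx A [thermal_context()].
#' @return Extension(s) X(f) in nm, bounded by the contour length.
#' @export
wlc_extension <- function(f, params, ctx = thermal_context()) {
  stopifnot(inherits(params, "elastic_params"))
  if (params$n_monomers == 0) return(rep(0, length(f)))
  relative_extension(f, params$persistence_length, ctx) * contour_length(params)
}

#' Convert an extension into a number of monomers at a given force
#'
#' Inverts [wlc_extension()] in its chain-length argument: at force \code{f}
#' each monomer contributes \code{z(f) * monomer_length} of extension, so an
#' extension \code{x} corresponds to \code{x / (z(f) * monomer_length)}
#' monomers. Counts are real-valued; rounding, if any, is left to reporting.
#'
#' When \code{dipole_length} is supplied, the orientation extension of the
#' folded-core dipole at force \code{f} is added to \code{x} before the
#' conversion. This alternative convention treats the measured transition-state
#' distance as excluding the dipole contribution; the default leaves \code{x}
#' untouched.
#'
#' @param f Force(s) in pN; strictly positive.
#' @param extension Molecular extension x in nm; non-negative.
#' @param persistence_length Persistence length Lp (nm).
#' @param monomer_length Contour length per monomer (nm).
#' @param ctx A [thermal_context()].
#' @param dipole_length Optional dipole length (nm); when given, the FJC
#'   dipole extension at \code{f} is added to \code{extension}.
#' @return Real-valued monomer count(s).
#'
#' @examples
#' # x* = 8 nm at the most probable folding force of 3 pN -> ~70 amino acids
#' monomers_from_extension(3, 8)
#' @export
monomers_from_extension <- function(f, extension, persistence_length = 0.8,
                                    monomer_length = 0.37,
                                    ctx = thermal_context(),
                                    dipole_length = NULL) {
  if (any(!is.finite(extension)) || any(extension < 0)) {
    stop("`extension` must be non-negative", call. = FALSE)
  }
  z <- relative_extension(f, persistence_length, ctx)
  x <- extension
  if (!is.null(dipole_length)) {
    x <- x + fjc_dipole_extension(f, dipole_length, ctx)
  }
  x / (z * monomer_length)
}

#' Orientation extension of the folded-core dipole (FJC single segment)
#'
#' The folded molecule is modeled as one orientable segment of fixed length
#' \code{d0} (a single Kuhn segment of a freely-jointed chain). Its average
#' extension along the force axis is the Langevin function,
#' \deqn{x_d(f) = d_0\left[\coth(\beta f d_0) - \frac{1}{\beta f d_0}\right].}
#' The limit at zero force is handled analytically (series expansion of the
#' Langevin function for \eqn{\beta f d_0 < 10^{-4}}, avoiding cancellation),
#' and \eqn{x_d \to d_0} as \eqn{f \to \infty}.
#'
#' @param f Force(s) in pN; non-negative.
#' @param dipole_length Dipole length d0 (nm).
#' @param ctx A [thermal_context()].
#' @return Dipole extension(s) in nm, in \[0, d0).
#' @export
fjc_dipole_extension <- function(f, dipole_length, ctx = thermal_context()) {
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("force must be non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(dipole_length), length(dipole_length) == 1L,
            dipole_length > 0)
  x <- ctx$beta * f * dipole_length
  out <- numeric(length(x))
  small <- x < 1e-4
  # Langevin L(x) = coth(x) - 1/x ; series x/3 - x^3/45 near 0
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xb <- x[!small]
  out[!small] <- 1 / tanh(xb) - 1 / xb
  dipole_length * out
}

#' Theoretical released extension upon unfolding
#'
#' The extension gained when the molecule unfolds at force \code{f}: the WLC
#' extension of the released chain minus the orientation extension of the
#' folded-core dipole just before the rip,
#' \eqn{x_{m,th}(f) = X(f) - x_d(f)}.
#'
#' @param f Force(s) in pN; strictly positive.
#' @param params An [elastic_params()] object.
#' @param ctx A [thermal_context()].
#' @return Released extension(s) in nm.
#'
#' @examples
#' # Barnase at its coexistence force (~9 pN): ~21 nm
#' barnase <- elastic_params(0.8, 0.37, 110, 3)
#' released_extension(9, barnase)
#' @export
released_extension <- function(f, params, ctx = thermal_context()) {
  stopifnot(inherits(params, "elastic_params"))
  wlc_extension(f, params, ctx) -
    fjc_dipole_extension(f, params$dipole_length, ctx)
}
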