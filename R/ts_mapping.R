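# Force-dependent transition-state mapping: amino acids to the barrier from
# either side, TS-to-U distance, per-monomer extension and mechanical
# fragility.

#' Force-dependent transition-state profile
#'
#' Maps a constant TS-to-N distance \code{x_dagger} into amino-acid units
#' across a force grid with the WLC model: the number of monomers unfolded at
#' the TS is \eqn{n_{aa}^\dagger(f) = x^\dagger / (z(f) d_{aa})}, the
#' complement \eqn{n_{aa}^*(f) = N - n_{aa}^\dagger(f)} counts monomers
#' between TS and U, the TS-to-U distance follows as
#' \eqn{x^*(f) = n_{aa}^*(f)\, d_{aa}\, z(f)}, and the mechanical fragility
#' is \eqn{\mu(f) = (x^\dagger - x^*(f)) / (x^\dagger + x^*(f))}.
#'
#' Because \eqn{z(f)} increases with force, \eqn{n_{aa}^\dagger} decreases
#' and \eqn{n_{aa}^*}, \eqn{x^*} and \eqn{-\mu} increase: the TS moves toward
#' the native state in monomer units as force rises (the Leffler-Hammond
#' direction), while the product \eqn{n_{aa}^\dagger(f) \cdot z(f) d_{aa}}
#' stays pinned at \code{x_dagger} by construction.
#'
#' Grid points where \eqn{n_{aa}^\dagger} would exceed the total monomer
#' count (too low a force for the assumed \code{x_dagger}) are truncated
#' from the profile with a warning naming the offending forces, never
#' clamped silently.
#'
#' @param x_dagger Constant TS-to-N distance (nm), > 0.
#' @param elastic An [elastic_params()] object.
#' @param ctx A [thermal_context()].
#' @param f_grid Positive, sorted force grid (pN). The default 2-25 pN in
#'   0.1 pN steps spans the force range accessible to pulling experiments on
#'   a protein such as barnase.
#' @param include_dipole Add the folded-core dipole extension to
#'   \code{x_dagger} before the monomer conversion (alternative convention;
#'   default \code{FALSE}).
#' @return A data frame of class \code{"ts_profile"} with columns
#'   \code{force_pN}, \code{naa_dagger}, \code{naa_star}, \code{x_star_nm},
#'   \code{x1aa_nm} (extension per monomer, \eqn{z(f) d_{aa}}) and
#'   \code{mu}; the constant \code{x_dagger} is stored as an attribute.
#' @export
ts_profile <- function(x_dagger, elastic, ctx = thermal_context(),
                       f_grid = seq(2, 25, by = 0.1),
                       include_dipole = FALSE) {
  stopifnot(inherits(elastic, "elastic_params"))
  if (!is.numeric(x_dagger) || length(x_dagger) != 1L || x_dagger <= 0) {
    stop("`x_dagger` must be a single positive distance (nm)", call. = FALSE)
  }
  if (length(f_grid) < 1L || any(f_grid <= 0) || is.unsorted(f_grid, strictly = TRUE)) {
    stop("`f_grid` must be a strictly increasing grid of positive forces",
         call. = FALSE)
  }
  naa_dagger <- monomers_from_extension(
    f_grid, x_dagger, elastic$persistence_length, elastic$monomer_length, ctx,
    dipole_length = if (include_dipole) elastic$dipole_length else NULL)
  bad <- naa_dagger > elastic$n_monomers
  if (any(bad)) {
    warning(sprintf(
      "naa_dagger exceeds the %g available monomers at %d grid forces (up to %.2f pN); truncating the profile",
      elastic$n_monomers, sum(bad), max(f_grid[bad])), call. = FALSE)
    f_grid <- f_grid[!bad]
    naa_dagger <- naa_dagger[!bad]
    if (length(f_grid) == 0L) {
      stop("no grid forces remain: `x_dagger` is too large for this force range",
           call. = FALSE)
    }
  }
  z <- relative_extension(f_grid, elastic$persistence_length, ctx)
  naa_star <- elastic$n_monomers - naa_dagger
  x1aa <- z * elastic$monomer_length
  x_star <- naa_star * x1aa
  out <- data.frame(
    force_pN = f_grid,
    naa_dagger = naa_dagger,
    naa_star = naa_star,
    x_star_nm = x_star,
    x1aa_nm = x1aa,
    mu = (x_dagger - x_star) / (x_dagger + x_star)
  )
  attr(out, "x_dagger_const") <- x_dagger
  attr(out, "include_dipole") <- include_dipole
  class(out) <- c("ts_profile", "data.frame")
  out
}

#' Mechanical fragility versus force
#'
#' Extracts the fragility \eqn{\mu(f) = (x^\dagger - x^*) / (x^\dagger +
#' x^*)} from a transition-state profile. Positive values mean compliant
#' response (TS closer to U), negative values brittle (TS closer to N);
#' under Leffler-Hammond TS movement it decreases monotonically with force.
#'
#' @param ts A [ts_profile()].
#' @return A data frame with columns \code{force_pN} and \code{mu}.
#' @export
fragility_profile <- function(ts) {
  stopifnot(inherits(ts, "ts_profile"))
  data.frame(force_pN = ts$force_pN, mu = ts$mu)
}

#' Total monomer count between N and U through the transition state
#'
#' Converts both transition-state distances into monomers at the same force
#' and sums them: \eqn{n_{aa}^{tot} = n_{aa}^\dagger + n_{aa}^*}. For a true
#' two-state folder evaluated at a common force this should approach the
#' total number of monomers of the chain.
#'
#' @param f Force (pN) at which both conversions are evaluated.
#' @param x_dagger,x_star TS distances (nm); non-negative.
#' @param elastic An [elastic_params()] object.
#' @param ctx A [thermal_context()].
#' @param include_dipole Add the dipole extension to each distance before
#'   conversion (default \code{FALSE}).
#' @return Real-valued total monomer count.
#' @export
total_monomers <- function(f, x_dagger, x_star, elastic,
                           ctx = thermal_context(), include_dipole = FALSE) {
  stopifnot(inherits(elastic, "elastic_params"))
  d0 <- if (include_dipole) elastic$dipole_length else NULL
  monomers_from_extension(f, x_dagger, elastic$persistence_length,
                          elastic$monomer_length, ctx, dipole_length = d0) +
    monomers_from_extension(f, x_star, elastic$persistence_length,
                            elastic$monomer_length, ctx, dipole_length = d0)
}
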