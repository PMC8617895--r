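#' Thermal context for force-spectroscopy calculations
#'
#' Bundles the temperature with the thermal energy scale used throughout the
#' package. All forces are in pN, lengths in nm and energies in pN nm, so
#' \code{kBT} is computed with the Boltzmann constant
#' \eqn{k_B = 0.0138065} pN nm/K and \code{beta} is its inverse.
#'
#' @param temperature Temperature in kelvin. Defaults to room temperature
#'   (298 K), the condition of typical optical-tweezers pulling experiments.
#'
#' @return An object of class \code{"thermal_context"}: a list with elements
#'   \code{temperature} (K), \code{kBT} (pN nm) and \code{beta} (1/(pN nm)).
#'
#' @examples
#' ctx <- thermal_context()
#' ctx$kBT            # ~4.114 pN nm at 298 K
#' ctx$beta * ctx$kBT # exactly 1
#'
#' @export
thermal_context <- function(temperature = 298) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)", call. = FALSE)
  }
  kBT <- 0.0138065 * temperature
  structure(
    list(temperature = temperature, kBT = kBT, beta = 1 / kBT),
    class = "thermal_context"
  )
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf("Thermal context: T = %g K, kBT = %.6g pN nm\n", x$temperature, x$kBT))
  invisible(x)
}

#' Elastic parameters of the stretched polymer
#'
#' Describes the released polypeptide (or nucleic-acid) chain as an
#' inextensible worm-like chain of \code{n_monomers} monomers of length
#' \code{monomer_length}, plus the folded core modeled as a single orientable
#' dipole (a freely-jointed-chain Kuhn segment) of length \code{dipole_length}.
#'
#' For barnase the defaults used throughout the examples are a persistence
#' length of 0.8 nm, 110 amino acids of 0.37 nm each (contour length
#' 40.7 nm) and a 3 nm N-C termini dipole.
#'
#' @param persistence_length Persistence length Lp of the unfolded chain (nm).
#' @param monomer_length Contour length per monomer (nm per amino acid or
#'   nucleotide).
#' @param n_monomers Number of monomers released upon full unfolding. May be
#'   zero (an empty chain), in which case all extensions are zero.
#' @param dipole_length Length of the folded-core dipole (nm); for a protein,
#'   the N-C termini distance.
#'
#' @return An object of class \code{"elastic_params"}.
#'
#' @seealso [wlc_extension()], [released_extension()]
#' @export
elastic_params <- function(persistence_length, monomer_length, n_monomers,
                           dipole_length) {
  num1 <- function(x, nm, allow_zero = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (if (allow_zero) x < 0 else x <= 0)) {
      stop(sprintf("`%s` must be a single %s number", nm,
                   if (allow_zero) "non-negative" else "strictly positive"),
           call. = FALSE)
    }
    x
  }
  structure(
    list(
      persistence_length = num1(persistence_length, "persistence_length"),
      monomer_length = num1(monomer_length, "monomer_length"),
      n_monomers = num1(n_monomers, "n_monomers", allow_zero = TRUE),
      dipole_length = num1(dipole_length, "dipole_length")
    ),
    class = "elastic_params"
  )
}

#' Contour length of the unfolded chain
#'
#' @param params An [elastic_params()] object.
#' @return Contour length \code{n_monomers * monomer_length} in nm.
#' @export
contour_length <- function(params) {
  stopifnot(inherits(params, "elastic_params"))
  params$n_monomers * params$monomer_length
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf(
    "Elastic parameters: Lp = %g nm, %g monomers x %g nm (L = %g nm), dipole %g nm\n",
    x$persistence_length, x$n_monomers, x$monomer_length,
    x$n_monomers * x$monomer_length, x$dipole_length))
  invisible(x)
}
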