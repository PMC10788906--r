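#' Physical constants used throughout the package
#'
#' Single source of truth for unit conversions. All modules pull constants
#' from here so that, e.g., the Coulomb constant used for surface potentials
#' and the Planck constant used in the Landau-Zener expression can never
#' drift apart.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{k_e}{Coulomb constant, 14.399645 V Angstrom / e.}
#'   \item{h}{Planck constant, 4.135667696e-15 eV s.}
#'   \item{k_B}{Boltzmann constant, 8.617333262e-5 eV / K.}
#' }
#' @export
#' @examples
#' phys_constants$k_e
phys_constants <- list(
  k_e = 14.399645,        # V * Angstrom / e
  h   = 4.135667696e-15,  # eV * s
  k_B = 8.617333262e-5    # eV / K
)

# Bondi van der Waals radii (Angstrom) for the elements this package meets.
# Overridable per element through the fragment-map config.
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Re = 2.05, Cu = 1.40
)

#' Bondi van der Waals radius lookup
#'
#' @param element Character vector of element symbols.
#' @param overrides Optional named numeric vector of per-element overrides in
#'   Angstrom (e.g. `c(Re = 2.1)`).
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, overrides = NULL) {
  tab <- .bondi_radii
  if (!is.null(overrides)) tab[names(overrides)] <- overrides
  r <- unname(tab[element])
  if (anyNA(r)) {
    stop("no van der Waals radius known for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "),
         "; supply an override", call. = FALSE)
  }
  r
}
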