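#' Physical constants and unit conversions
#'
#' All coordinates inside the package are Angstrom; energies are kcal/mol
#' unless stated otherwise. Every unit conversion used anywhere in the
#' package lives in this one table so that generator/estimator pairs are
#' guaranteed to share the same factors.
#'
#' @format A named list:
#' \describe{
#'   \item{kB_J}{Boltzmann constant, J/K (CODATA exact value).}
#'   \item{kB_erg}{Boltzmann constant, erg/K.}
#'   \item{ke_kcal}{Coulomb constant, kcal mol^-1 Angstrom e^-2.}
#'   \item{A2ps_to_cm2s}{Multiply a diffusion coefficient in Angstrom^2/ps
#'     by this to obtain cm^2/s.}
#'   \item{dyncm_factor}{Multiply kB_erg*T*<A>/(N*Var(A)) (areas in
#'     Angstrom^2) by this to obtain dyn/cm.}
#'   \item{nm_to_A}{Nanometre to Angstrom.}
#' }
#' @export
mtConstants <- list(
  kB_J          = 1.380649e-23,
  kB_erg        = 1.380649e-16,
  ke_kcal       = 332.0636,
  A2ps_to_cm2s  = 1e-4,
  dyncm_factor  = 1e16,
  nm_to_A       = 10
)

#' Standard van der Waals radii by element
#'
#' Bondi-style radii (Angstrom) used by the occupancy-grid crack detector
#' when the input carries no per-atom radius column. Overridable per call.
#'
#' @format Named numeric vector (element symbol -> radius, Angstrom).
#' @export
mtVdwRadii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8)

#' Standard atomic masses by element
#'
#' @format Named numeric vector (element symbol -> mass, g/mol).
#' @export
mtMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
              P = 30.973762, S = 32.06)

# Element symbol from an atom name: leading letters, preferring a known
# two-letter match, else the first letter. "C214" -> "C", "H91" -> "H".
guessElement <- function(name) {
  lead <- sub("^[0-9]*", "", name)
  first <- toupper(substr(lead, 1L, 1L))
  ifelse(first %in% names(mtMasses), first, "C")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
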