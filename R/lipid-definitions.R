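#' Construct a lipid definition
#'
#' A lipid definition names, per residue type, the atoms the analyses need:
#' the head atom used for leaflet assignment and thickness (typically P),
#' the director anchor scheme, and the carbon/hydrogen name pairs used for
#' the acyl-chain order parameter.
#'
#' Two director schemes are recognised:
#' \describe{
#'   \item{midpoint_tail}{director = normalised vector from the midpoint of
#'     \code{midpointAtoms} (e.g. P and C2) to the centre of mass of
#'     \code{tailAtoms} (the last three carbons of the two acyl chains).
#'     Used for PC, SM and glycolipids (on their ceramide tails).}
#'   \item{two_atom}{director = normalised vector from the first to the
#'     second atom of \code{anchorAtoms} (e.g. C3 -> C17 for cholesterol).}
#' }
#'
#' @param resname residue name, e.g. "DPPC".
#' @param category one of "PC", "SM", "cholesterol", "glycolipid".
#' @param headAtom head atom name for leaflet/thickness logic.
#' @param scheme director scheme, "midpoint_tail" or "two_atom".
#' @param midpointAtoms character(2) for the midpoint_tail scheme.
#' @param tailAtoms terminal tail carbon names (midpoint_tail scheme).
#' @param anchorAtoms character(2) for the two_atom scheme.
#' @param chPairs list of character(2) C/H atom-name pairs for S_CD;
#'   must be nonempty for non-cholesterol lipids.
#' @param densityAnchor atom used in lateral density maps (defaults to the
#'   head atom).
#' @return a "LipidDefinition" list.
#' @export
lipidDefinition <- function(resname, category,
                            headAtom = "P",
                            scheme = c("midpoint_tail", "two_atom"),
                            midpointAtoms = c("P", "C2"),
                            tailAtoms = character(),
                            anchorAtoms = character(),
                            chPairs = list(),
                            densityAnchor = headAtom) {
  scheme <- match.arg(scheme)
  category <- match.arg(category, c("PC", "SM", "cholesterol", "glycolipid"))
  if (scheme == "midpoint_tail") {
    if (length(midpointAtoms) != 2L || length(tailAtoms) < 1L)
      stop("midpoint_tail scheme needs 2 midpoint atoms and >= 1 tail atom")
  } else if (length(anchorAtoms) != 2L) {
    stop("two_atom scheme needs exactly 2 anchor atoms")
  }
  if (category != "cholesterol" && length(chPairs) == 0L)
    stop("non-cholesterol lipids need at least one C-H pair for S_CD")
  structure(list(resname = resname, category = category,
                 headAtom = headAtom, scheme = scheme,
                 midpointAtoms = midpointAtoms, tailAtoms = tailAtoms,
                 anchorAtoms = anchorAtoms, chPairs = chPairs,
                 densityAnchor = densityAnchor),
            class = "LipidDefinition")
}

#' Default lipid definitions for the five-component neuronal membrane model
#'
#' Covers DPPC, POPC, PSM, cholesterol (CHL1) and the ganglioside GM1 with
#' the atom naming used by the synthetic bilayer generator: phospholipid
#' pseudo-lipids carry P, C2, two chains whose last three carbons are
#' C14/C15/C16 and C24/C25/C26, and H atoms paired with the sn-1 terminal
#' carbons; cholesterol carries O3, C3 and C17. For real CHARMM-named
#' trajectories, supply definitions with the force-field atom names via
#' \code{\link{readLipidDefinitions}}.
#'
#' @return named list of \code{\link{lipidDefinition}} objects.
#' @export
defaultLipidDefinitions <- function() {
  phos <- function(resname, category)
    lipidDefinition(resname, category, headAtom = "P",
                    scheme = "midpoint_tail",
                    midpointAtoms = c("P", "C2"),
                    tailAtoms = c("C14", "C15", "C16", "C24", "C25", "C26"),
                    chPairs = list(c("C14", "H14"), c("C15", "H15"),
                                   c("C16", "H16")))
  list(
    DPPC = phos("DPPC", "PC"),
    POPC = phos("POPC", "PC"),
    PSM  = phos("PSM", "SM"),
    CHL1 = lipidDefinition("CHL1", "cholesterol", headAtom = "O3",
                           scheme = "two_atom",
                           anchorAtoms = c("C3", "C17"),
                           densityAnchor = "O3"),
    GM1  = phos("GM1", "glycolipid")
  )
}

#' Read lipid definitions from a YAML config
#'
#' The file maps residue names to blocks with keys \code{category},
#' \code{head_atom}, \code{scheme}, \code{midpoint_atoms}, \code{tail_atoms},
#' \code{anchor_atoms}, \code{ch_pairs} (list of 2-element lists) and
#' optional \code{density_anchor}.
#'
#' @param path YAML file path.
#' @return named list of LipidDefinition objects.
#' @export
readLipidDefinitions <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(rn) {
    b <- raw[[rn]]
    lipidDefinition(
      resname = rn, category = b$category,
      headAtom = b$head_atom %||% "P",
      scheme = b$scheme %||% "midpoint_tail",
      midpointAtoms = as.character(b$midpoint_atoms %||% c("P", "C2")),
      tailAtoms = as.character(b$tail_atoms %||% character()),
      anchorAtoms = as.character(b$anchor_atoms %||% character()),
      chPairs = lapply(b$ch_pairs %||% list(), as.character),
      densityAnchor = b$density_anchor %||% b$head_atom %||% "P")
  })
  names(out) <- names(raw)
  out
}

#' Write lipid definitions to YAML
#' @param defs named list of LipidDefinition objects.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLipidDefinitions <- function(defs, path) {
  raw <- lapply(defs, function(d) list(
    category = d$category, head_atom = d$headAtom, scheme = d$scheme,
    midpoint_atoms = d$midpointAtoms, tail_atoms = d$tailAtoms,
    anchor_atoms = d$anchorAtoms, ch_pairs = d$chPairs,
    density_anchor = d$densityAnchor))
  yaml::write_yaml(raw, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
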