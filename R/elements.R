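# Element data shared by the parser and the descriptor code.
#
# Z    : atomic number
# Zv   : valence-electron count of the neutral atom
# valences : allowed total bond orders for implicit-hydrogen filling,
#            in increasing order (SMILES "normal valence" model)

.elements <- list(
  H  = list(Z = 1L,  Zv = 1L, valences = 1L),
  B  = list(Z = 5L,  Zv = 3L, valences = 3L),
  C  = list(Z = 6L,  Zv = 4L, valences = 4L),
  N  = list(Z = 7L,  Zv = 5L, valences = c(3L, 5L)),
  O  = list(Z = 8L,  Zv = 6L, valences = 2L),
  F  = list(Z = 9L,  Zv = 7L, valences = 1L),
  P  = list(Z = 15L, Zv = 5L, valences = c(3L, 5L)),
  S  = list(Z = 16L, Zv = 6L, valences = c(2L, 4L, 6L)),
  Cl = list(Z = 17L, Zv = 7L, valences = 1L),
  Br = list(Z = 35L, Zv = 7L, valences = 1L),
  I  = list(Z = 53L, Zv = 7L, valences = 1L)
)

.element_info <- function(symbol) {
  info <- .elements[[symbol]]
  if (is.null(info)) {
    stop("unknown element '", symbol, "'", call. = FALSE)
  }
  info
}

#' Default van der Waals volume table
#'
#' Per-element atomic van der Waals volumes scaled so that carbon equals 1,
#' used by the mean-volume descriptor `Mv`. Volumes are \eqn{(r/r_C)^3} with
#' Bondi radii for the heavy elements (N 1.55, O 1.52, F 1.47, S 1.80,
#' Cl 1.75, Br 1.85, I 1.98, P 1.80 angstrom; carbon 1.70) and the revised
#' Rowland--Taylor hydrogen radius of 1.09 angstrom. The hydrogen entry
#' matters: `Mv` averages over all atoms *including* implicit hydrogens, so
#' in a typical organic molecule more than half of the terms are hydrogens.
#'
#' Pass a modified copy to [mean_vdw_volume()] or [compute_descriptors()] to
#' change the convention.
#'
#' @return A tibble with columns `element`, `radius` (angstrom) and `volume`
#'   (carbon-scaled).
#' @export
#' @examples
#' vdw_volume_table()
vdw_volume_table <- function() {
  radii <- c(
    H = 1.09, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, P = 1.80, B = 1.92
  )
  tibble::tibble(
    element = names(radii),
    radius = unname(radii),
    volume = unname((radii / radii[["C"]])^3)
  )
}

#' Default electronegativity weights for valence charge indices
#'
#' Diagonal weights of the electronegativity-modified adjacency matrix used
#' by the valence variants of the Galvez charge indices. The weight is the
#' Pauling electronegativity of the element minus that of carbon, so carbon
#' carries 0 and the plain and valence indices coincide on pure carbon
#' skeletons. This weighting is a package convention: the original
#' descriptor software does not document its table, and no shipped model
#' uses the valence charge indices.
#'
#' @return A named numeric vector of diagonal weights, carbon-referenced.
#' @export
electronegativity_weights <- function() {
  en <- c(
    H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
    P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66
  )
  en - en[["C"]]
}
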