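#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues, in the fixed alphabetical (one-letter) order
#' used throughout the package for composition and entropy vectors.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() AA_ORDER

AA_ORDER <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Kyte-Doolittle hydropathy (J Mol Biol 157:105, standard GRAVY scale)
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
  M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Average residue masses (Da); free amino acid = residue + one water
RESIDUE_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)
WATER_MASS <- 18.01528

# EMBOSS pKa set (as used by the EMBOSS iep/pepstats tools)
PKA_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

#' Named residue property scale
#'
#' A property scale maps each of the 20 canonical residues to a real value.
#' Built-in scales: `"kyte_doolittle"` hydropathy (the GRAVY scale).
#'
#' @param name Scale name, or a named numeric vector covering all 20
#'   canonical residues to use as a custom scale.
#' @return Named numeric vector of length 20 (class `property_scale`).
#' @examples
#' property_scale("kyte_doolittle")[["W"]]
#' @export
property_scale <- function(name = "kyte_doolittle") {
  if (is.numeric(name)) {
    vals <- name
  } else {
    vals <- switch(name,
      kyte_doolittle = KYTE_DOOLITTLE,
      stop("unknown property scale: ", name, call. = FALSE)
    )
  }
  if (!setequal(names(vals), AA_ORDER)) {
    stop("property scale must key exactly the 20 canonical residues",
         call. = FALSE)
  }
  structure(vals[AA_ORDER], class = c("property_scale", "numeric"))
}

# Three-group CTD alphabets (Dubchak-style property groupings).
# Each maps every canonical residue to group 1, 2 or 3.
ctd_group_defs <- list(
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    g2 = c("P", "A", "T", "G", "S"),
    g3 = c("H", "Q", "R", "K", "N", "E", "D")
  ),
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")
  ),
  charge = list(
    g1 = c("K", "R", "H"),
    g2 = c("A", "N", "C", "Q", "G", "I", "L", "M", "F", "P", "S", "T",
           "W", "Y", "V"),
    g3 = c("D", "E")
  ),
  solvent_accessibility = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
    g2 = c("R", "K", "Q", "E", "N", "D"),
    g3 = c("M", "S", "P", "T", "H", "Y")
  ),
  secondary_structure = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),
    g3 = c("G", "N", "P", "S", "D")
  )
)

#' Reduced (grouped) residue alphabets
#'
#' Returns a named integer vector mapping each canonical residue to a group
#' index. Built-in three-group property alphabets: `"polarity"`,
#' `"polarizability"`, `"charge"`, `"solvent_accessibility"`,
#' `"secondary_structure"` (helix/strand/coil propensity); plus the
#' five-group `"chemical"` alphabet (aliphatic/aromatic/polar/acidic/basic)
#' and the trivial 20-group `"identity"` alphabet.
#'
#' @param name Alphabet name.
#' @return Named integer vector over the 20 residues, with a `groups`
#'   attribute giving group labels.
#' @export
reduced_alphabet <- function(name = "charge") {
  if (identical(name, "identity")) {
    map <- stats::setNames(seq_along(AA_ORDER), AA_ORDER)
    attr(map, "groups") <- AA_ORDER
    return(map)
  }
  if (identical(name, "chemical")) {
    defs <- list(
      aliphatic = c("A", "G", "I", "L", "P", "V"),
      aromatic = c("F", "W", "Y"),
      polar = c("C", "M", "N", "Q", "S", "T"),
      acidic = c("D", "E"),
      basic = c("H", "K", "R")
    )
  } else if (name %in% names(ctd_group_defs)) {
    defs <- ctd_group_defs[[name]]
  } else {
    stop("unknown reduced alphabet: ", name, call. = FALSE)
  }
  map <- integer(20)
  names(map) <- AA_ORDER
  for (i in seq_along(defs)) map[defs[[i]]] <- i
  if (any(map == 0)) {
    stop("reduced alphabet does not cover all 20 residues", call. = FALSE)
  }
  attr(map, "groups") <- names(defs)
  map
}

# Swiss-Prot-like background residue frequencies (release statistics,
# normalised to sum exactly to 1); used by the synthetic generator.
BACKGROUND_FREQS <- local({
  f <- c(
    A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86,
    G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
    M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
    S = 6.65, T = 5.36, V = 6.86, W = 1.10, Y = 2.92
  )
  f / sum(f)
})

#' Background residue frequencies
#'
#' Swiss-Prot-like average residue frequencies used as the default
#' background composition by the synthetic proteome generator.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function() BACKGROUND_FREQS
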