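# Amino-acid property tables used by the structure and feature modules.
# Volumes are Zamyatnin (1972) residue volumes in cubic Angstrom; maximal
# accessible surface areas are the theoretical Gly-X-Gly extended-tripeptide
# values of Tien et al. (2013), in square Angstrom.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

AA_VOLUME <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

AA_MAX_ASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  Q = 225, E = 223, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174)

# Aromatic set includes His, which acts as an uncharged pi partner here.
AA_AROMATIC <- c("F", "Y", "W", "H")

AA_POLAR <- c("R", "N", "D", "C", "Q", "E", "H", "K", "S", "T", "Y")

AA_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0)

# Van der Waals radii (Angstrom) by element for surface calculations.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, ZN = 1.39)
VDW_DEFAULT <- 1.70

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x Character vector of residue codes.
#' @return Character vector of converted codes; unknown codes become `NA`.
#' @examples
#' aa_three_to_one("CYS")
#' aa_one_to_three("F")
#' @export
aa_three_to_one <- function(x) {
  AA1[match(toupper(x), AA3)]
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  AA3[match(toupper(x), AA1)]
}

#' Physico-chemical change descriptors for an amino-acid substitution
#'
#' Describes the change a missense substitution makes to side-chain volume,
#' polarity, aromaticity and formal charge. Aromaticity counts Phe, Tyr, Trp
#' and His as aromatic; `aromatic_change` is `TRUE` iff exactly one of the
#' two residues is aromatic.
#'
#' @param wt,mut One-letter codes of the wild-type and mutant residues
#'   (vectorized, recycled to common length).
#' @return A data frame with columns `wt`, `mut`, `delta_volume` (mutant
#'   minus wild-type residue volume, cubic Angstrom), `polarity_change`,
#'   `aromatic_change` and `charge_change` (logicals).
#' @examples
#' substitution_descriptor("F", "A")
#' @export
substitution_descriptor <- function(wt, mut) {
  wt <- toupper(wt)
  mut <- toupper(mut)
  n <- max(length(wt), length(mut))
  wt <- rep_len(wt, n)
  mut <- rep_len(mut, n)
  bad <- !(wt %in% AA1) | !(mut %in% AA1)
  if (any(bad)) {
    stop("unknown amino-acid code(s): ",
         paste(unique(c(wt[bad], mut[bad])), collapse = ", "))
  }
  if (any(wt == mut)) {
    stop("wild-type and mutant residues must differ")
  }
  data.frame(
    wt = wt,
    mut = mut,
    delta_volume = unname(AA_VOLUME[mut] - AA_VOLUME[wt]),
    polarity_change = (wt %in% AA_POLAR) != (mut %in% AA_POLAR),
    aromatic_change = (wt %in% AA_AROMATIC) != (mut %in% AA_AROMATIC),
    charge_change = unname(AA_CHARGE[wt] != AA_CHARGE[mut]),
    stringsAsFactors = FALSE)
}
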